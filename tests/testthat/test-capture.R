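mk_pair <- function(id, ls, le, rs, re, seq_id = "ref") {
  data.frame(read_id = paste0(id, c(".f", ".r")), subclone_id = id,
             seq_id = seq_id, start = c(ls, rs), end = c(le, re),
             strand = c("+", "-"), mate_id = paste0(id, c(".r", ".f")),
             library_id = "lib1", role = c("fwd", "rev"),
             stringsAsFactors = FALSE)
}

mk_gap <- function(start, end, kind = "internal") {
  data.frame(sequence_id = "ref", start = start, end = end,
             size = end - start, left_contig = "a", right_contig = "b",
             kind = kind, spanning_subclones = NA_integer_, status = "unset",
             stringsAsFactors = FALSE)
}

test_that("spanning subclones are counted from opposite-side mates", {
  gap <- mk_gap(50000, 52000)
  pairs <- rbind(mk_pair("s1", 48500, 49300, 52600, 53400),
                 mk_pair("s2", 40000, 40800, 43000, 43800),  # both left
                 mk_pair("s3", 53000, 53800, 56000, 56800))  # both right
  n <- count_spanning_subclones(gap, pairs)
  expect_equal(as.integer(n), 1L)
  expect_equal(attr(n, "spans"), 4900L)
})

test_that("the capture rule separates captured from uncaptured gaps", {
  gap <- mk_gap(50000, 52000)
  rule <- capture_rule(min_spanning_pairs = 2, k_sd = 3)
  # three ~4.9 kb spans against a 4000 +/- 400 library (bound 5200): captured
  close3 <- rbind(mk_pair("s1", 48500, 49300, 52600, 53400),
                  mk_pair("s2", 48600, 49400, 52700, 53500),
                  mk_pair("s3", 48400, 49200, 52500, 53300))
  g <- classify_gaps(gap, close3, rule, insert_mean = 4000, insert_sd = 400)
  expect_equal(g$status, "captured")
  expect_equal(g$spanning_subclones, 3L)

  # a single qualifying spanning subclone is not enough
  g1 <- classify_gaps(gap, close3[1:2, ], rule, insert_mean = 4000,
                      insert_sd = 400)
  expect_equal(g1$status, "uncaptured")
  expect_equal(g1$spanning_subclones, 1L)

  # two spanning subclones whose spans exceed the bound do not qualify
  wide2 <- rbind(mk_pair("s1", 44000, 44800, 52200, 53000),
                 mk_pair("s2", 44100, 44900, 52300, 53100))
  g2 <- classify_gaps(gap, wide2, rule, insert_mean = 4000, insert_sd = 400)
  expect_equal(g2$status, "uncaptured")
  expect_equal(g2$spanning_subclones, 0L)

  # terminal gaps are never classified
  gt <- classify_gaps(mk_gap(0, 1000, kind = "terminal"), close3, rule,
                      insert_mean = 4000, insert_sd = 400)
  expect_equal(gt$status, "unset")

  expect_error(classify_gaps(gap, close3, rule), "insert")
})

test_that("classification agrees with a brute-force double loop", {
  rule <- capture_rule()
  max_span <- 4000 + 3 * 400
  for (s in 1:200) {
    set.seed(s)
    G <- 30000
    gs <- sample(5000:20000, 1); ge <- gs + sample(50:4000, 1)
    gap <- mk_gap(gs, ge)
    n <- sample(5:40, 1)
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      ins <- sample(1700:9000, 1)
      st <- sample.int(G - ins, 1)
      mk_pair(sprintf("s%03d", i), st, st + 800, st + ins - 800, st + ins)
    }))
    res <- classify_gaps(gap, pairs, rule, insert_mean = 4000, insert_sd = 400)
    orc <- oracle_spanning(list(start = gs, end = ge), pairs, max_span)
    expect_equal(res$spanning_subclones, as.integer(orc[["qualifying"]]),
                 info = sprintf("seed %d", s))
    expect_equal(res$status == "captured", orc[["qualifying"]] >= 2,
                 info = sprintf("seed %d", s))
    expect_equal(as.integer(count_spanning_subclones(gap, pairs)),
                 as.integer(orc[["spanning"]]))
  }
})

test_that("capture status is deterministic in gap geometry", {
  # gaps far smaller than the insert under dense unbiased coverage: captured
  n_cap <- 0L; n_gap <- 0L
  for (s in 1:12) {
    G <- 120000L
    p <- simulate_shotgun(G, redundancy = 4, seed = 300 + s)
    gaps <- coverage_gaps(p, G)
    gaps <- gaps[gaps$start > 0 & gaps$end < G, , drop = FALSE]
    if (nrow(gaps) == 0) next
    g <- classify_gaps(do.call(rbind, lapply(seq_len(nrow(gaps)), function(i) {
      mk_gap(gaps$start[i], gaps$end[i])
    })), p)
    n_gap <- n_gap + nrow(g)
    n_cap <- n_cap + sum(g$status == "captured")
  }
  expect_gt(n_gap, 20)
  expect_gte(n_cap / n_gap, 0.95)

  # gaps larger than insert_mean + 3 sd are always uncaptured
  bias <- bias_model(data.frame(start = 50000, end = 57000, viability = 0))
  for (s in 1:5) {
    p <- simulate_shotgun(120000L, redundancy = 8, bias = bias, seed = 400 + s)
    gaps <- coverage_gaps(p, 120000L)
    big <- gaps[gaps$end - gaps$start > 5200, , drop = FALSE]
    expect_gte(nrow(big), 1)
    g <- classify_gaps(do.call(rbind, lapply(seq_len(nrow(big)), function(i) {
      mk_gap(big$start[i], big$end[i])
    })), p)
    expect_true(all(g$status == "uncaptured"))
  }
})

test_that("uncaptured burden tallies assemblies and rates", {
  manifest <- data.frame(bac_id = sprintf("b%02d", 1:10), species = "sp1",
                         region = "r1", finished_length = 1e5)
  # 3 assemblies with >= 2 uncaptured gaps
  unc <- c(2, 3, 2, 1, 1, 0, 0, 0, 0, 0)
  gaps <- do.call(rbind, lapply(1:10, function(i) {
    k <- unc[i] + 1
    g <- do.call(rbind, lapply(seq_len(k), function(j) mk_gap(j * 1000, j * 1000 + 100)))
    g$status <- c(rep("uncaptured", unc[i]), "captured")
    g$bac_id <- sprintf("b%02d", i)
    g
  }))
  b <- uncaptured_burden(gaps, manifest, group_by = "species")
  expect_equal(b$frac_ge2_uncaptured, 0.30)
  expect_equal(b$n_gaps, sum(unc) + 10)
  expect_equal(b$frac_uncaptured, sum(unc) / (sum(unc) + 10))
  expect_equal(b$captured_per_mb + b$uncaptured_per_mb, b$n_gaps / b$total_mb)

  allcap <- gaps; allcap$status <- "captured"
  expect_equal(uncaptured_burden(allcap, manifest)$frac_uncaptured, 0)
  expect_error(uncaptured_burden(gaps, manifest[-1, ]), "missing")
  unc_gaps <- gaps; unc_gaps$status <- "unset"
  expect_error(uncaptured_burden(unc_gaps, manifest), "classified")
})

test_that("contig-coordinate placements lift through the map correctly", {
  sim <- simulate_bac(length = 50000, n_bias = 2, bias_length = c(600, 1200),
                      viability = 0, shuffle = TRUE, seed = 55)
  res <- assay_bac(sim$ref, sim$draft, pairs = sim$pairs)
  lifted <- lift_placements(sim$draft$placements, res$map)
  orig <- sim$pairs$pairs
  key <- function(d) paste(d$read_id, d$start, d$end, d$strand)
  # every lifted row must exist among the original reference placements
  # (reads clipped at contig ends shrink, so compare on containment)
  m <- match(lifted$read_id, orig$read_id)
  same_read <- !is.na(m)
  expect_true(all(same_read))
  expect_true(all(lifted$strand == orig$strand[m] |
                    lifted$start >= orig$start[m]))
  contained <- lifted$start >= orig$start[m] & lifted$end <= orig$end[m]
  # wrapped reads occupy two original rows; ignore those few
  dup_reads <- orig$read_id[duplicated(orig$read_id)]
  expect_true(all(contained[!lifted$read_id %in% dup_reads]))
  expect_true(all(lifted$strand[!lifted$read_id %in% dup_reads] ==
                    orig$strand[m][!lifted$read_id %in% dup_reads]))
})
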