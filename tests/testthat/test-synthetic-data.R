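test_that("generate_reference honors length, planted repeats, and GC targets", {
  g <- generate_reference(10000, gc_target = 0.5, seed = 7)
  expect_equal(nchar(g$reference$seq), 10000)
  expect_equal(g$reference$length, 10000L)
  expect_equal(nrow(g$annotation), 0)
  expect_true(all(strsplit(g$reference$seq, "")[[1]] %in% c("A", "C", "G", "T")))

  g2 <- generate_reference(10000, gc_target = 0.5, seed = 7,
                           repeats = data.frame(class = "Simple", length = 100,
                                                start = 2000, motif = "AC"))
  expect_equal(g2$annotation,
               data.frame(start = 2000L, end = 2100L, class = "Simple"))
  expect_equal(substr(g2$reference$seq, 2001, 2100),
               strrep("AC", 50))

  isl <- generate_reference(60000, gc_target = 0.4, seed = 11,
                            gc_islands = data.frame(length = 2100, gc = 0.83,
                                                    start = 30000))
  island_gc <- gc_content(isl$reference,
                          data.frame(start = 30000, end = 32100))
  expect_gte(island_gc, 0.78)
  expect_lte(island_gc, 0.88)
  bg_gc <- gc_content(isl$reference,
                      data.frame(start = c(0, 32100), end = c(30000, 60000)))
  expect_lt(abs(bg_gc - 0.4), 0.02)

  expect_error(
    generate_reference(2000, repeats = data.frame(class = "LINE", length = 2500,
                                                  start = NA, motif = NA)),
    "exceed")
})

test_that("read-pair count formula holds and placements are well-formed", {
  grid <- expand.grid(len = c(50000, 100000, 165000),
                      red = c(2, 6.5, 8), rl = c(500, 800))
  for (i in seq_len(nrow(grid))) {
    G <- grid$len[i]
    p <- simulate_shotgun(G, redundancy = grid$red[i], read_len = grid$rl[i],
                          seed = i)
    expect_identical(p$n_pairs, round(grid$red[i] * G / (2 * grid$rl[i])))
    expect_equal(length(unique(p$pairs$subclone_id)), p$n_pairs)
    # each read covers exactly read_len bases (possibly as two wrapped rows)
    per_read <- tapply(p$pairs$end - p$pairs$start, p$pairs$read_id, sum)
    expect_true(all(per_read == grid$rl[i]))
    expect_true(all(p$pairs$start >= 0 & p$pairs$end <= G &
                      p$pairs$start < p$pairs$end))
  }
  # fwd and rev reads of one subclone sit on opposite strands
  p <- simulate_shotgun(50000, redundancy = 4, seed = 3)
  both <- vapply(split(p$pairs$strand, p$pairs$subclone_id),
                 function(s) length(unique(s)) == 2, logical(1))
  expect_true(all(both))
  expect_error(simulate_shotgun(5000, redundancy = 0.01, read_len = 800,
                                insert_mean = 4000),
               "read pair")
})

test_that("zero-viability regions exclude every overlapping subclone", {
  G <- 100000L
  bias <- bias_model(data.frame(start = 40000, end = 42000, viability = 0),
                     host = "standard")
  p <- simulate_shotgun(G, redundancy = 8, bias = bias, seed = 21)
  # the region is a coverage gap...
  gaps <- coverage_gaps(p, G)
  expect_true(any(gaps$start <= 40000 & gaps$end >= 42000))
  # ... unspanned by any subclone ...
  cnt <- count_spanning_subclones(list(start = 40000, end = 42000), p)
  expect_identical(as.integer(cnt), 0L)
  # ... and no unwrapped subclone insert overlaps it
  geo <- finishassay:::.subclone_geometry(p$pairs)
  unwrapped <- geo[(geo$outer_end - geo$outer_start) < G / 2, ]
  expect_true(all(unwrapped$outer_end <= 40000 | unwrapped$outer_start >= 42000))
})

test_that("copy-control host restores viability arithmetic", {
  reg <- data.frame(start = 10, end = 20, viability = 0.25)
  full <- bias_model(reg, "copy_control", copy_control_rescue = 1)
  half <- bias_model(reg, "copy_control", copy_control_rescue = 0.5)
  none <- bias_model(reg, "standard")
  expect_equal(finishassay:::.effective_viability(full), 1)
  expect_equal(finishassay:::.effective_viability(half), 0.625)
  expect_equal(finishassay:::.effective_viability(none), 0.25)
})

test_that("draft contigs and true gaps tile the assembled span", {
  for (s in 1:15) {
    sim <- simulate_bac(length = 60000, n_bias = 2, bias_length = c(500, 2000),
                        viability = 0, seed = s, id = sprintf("b%d", s))
    layout <- sim$draft$truth$layout
    iv <- rbind(data.frame(start = layout$ref_start, end = layout$ref_end),
                sim$draft$truth$true_gaps)
    iv <- iv[order(iv$start), ]
    span <- sim$draft$truth$span
    expect_equal(iv$start[1], span[1])
    expect_equal(iv$end[nrow(iv)], span[2])
    expect_true(all(iv$start[-1] == iv$end[-nrow(iv)])) # abutting, no overlap
  }
})

test_that("sub-threshold coverage islands are discarded and flanking gaps merge", {
  ref <- generate_reference(30000, gc_target = 0.5, seed = 5)$reference
  mk_reads <- function(iv) {
    do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
      s <- seq(iv$start[i], iv$end[i] - 500, by = 250)
      data.frame(read_id = sprintf("r%d_%d", i, seq_along(s)),
                 subclone_id = sprintf("s%d_%d", i, seq_along(s)),
                 seq_id = ref$id, start = s, end = pmin(s + 500, iv$end[i]),
                 strand = "+", mate_id = NA, library_id = "lib1", role = "fwd")
    }))
  }
  covered <- data.frame(start = c(0, 11000, 13500), end = c(10000, 12500, 25000))
  pairs <- structure(list(pairs = mk_reads(covered),
                          library = list(insert_mean = 4000, insert_sd = 400,
                                         read_len = 500),
                          n_pairs = 1L, host = "standard"),
                     class = "read_pairs")
  d <- build_draft(ref, pairs, min_contig = 2000)
  expect_equal(nrow(d$contigs), 2)
  expect_equal(d$truth$true_gaps, data.frame(start = 10000L, end = 13500L))
  # brute force from the per-base coverage vector agrees
  depth <- oracle_depth(pairs$pairs, 30000)
  cov <- oracle_complement(data.frame(start = which(depth == 0) - 1L,
                                      end = which(depth == 0)), 0, 30000)
  cov <- cov[cov$end - cov$start >= 2000, ]
  expect_equal(d$truth$true_gaps,
               oracle_complement(cov, min(cov$start), max(cov$end)),
               ignore_attr = TRUE)

  dense <- data.frame(start = 0, end = 30000)
  pairs2 <- pairs; pairs2$pairs <- mk_reads(dense)
  d2 <- build_draft(ref, pairs2, min_contig = 2000)
  expect_equal(nrow(d2$contigs), 1)
  expect_equal(nrow(d2$truth$true_gaps), 0)

  expect_error(build_draft(ref, pairs, min_contig = 20000), "min_contig")
})

test_that("mean gap count decreases with redundancy", {
  G <- 40000L
  mean_gaps <- function(red) {
    mean(vapply(1:100, function(s) {
      coverage_gap_count(simulate_shotgun(G, redundancy = red, seed = s), G)
    }, numeric(1)))
  }
  expect_lte(mean_gaps(10), mean_gaps(6))
})

test_that("identical inputs and seed give byte-identical simulations", {
  a <- simulate_bac(length = 30000, n_bias = 2, viability = 0.2, seed = 99)
  b <- simulate_bac(length = 30000, n_bias = 2, viability = 0.2, seed = 99)
  expect_identical(a$ref$seq, b$ref$seq)
  expect_identical(a$pairs$pairs, b$pairs$pairs)
  expect_identical(a$draft$contigs, b$draft$contigs)
})
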