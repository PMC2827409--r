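test_that("gc_content counts G+C bases over sequences and intervals", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("AAGGCCTT", data.frame(start = 2, end = 6)), 1.0)
  expect_true(is.na(gc_content("ACGT", data.frame(start = integer(0),
                                                  end = integer(0)))))
})

test_that("planted simple-repeat tracts are recovered", {
  set.seed(42)
  bg <- random_dna_str(300)
  seq1 <- paste0(substr(bg, 1, 100), strrep("A", 20), substr(bg, 121, 300))
  r1 <- find_simple_repeats(seq1)
  expect_true(any(r1$start <= 100 & r1$end >= 120))

  seq2 <- paste0(substr(bg, 1, 150), strrep("AC", 12), substr(bg, 175, 300))
  r2 <- find_simple_repeats(seq2)
  expect_true(any(r2$start <= 150 & r2$end >= 174))
})

test_that("the tandem scan equals the exhaustive all-offsets oracle", {
  set.seed(7)
  for (i in 1:10) {
    bg <- random_dna_str(350)
    seq <- if (i %% 2 == 0) {
      # plant an impure dinucleotide tract to exercise the purity bound
      tract <- strsplit(strrep("AG", 20), "")[[1]]
      tract[c(9, 23)] <- "T"
      paste0(substr(bg, 1, 120), paste(tract, collapse = ""),
             substr(bg, 161, 350))
    } else bg
    expect_equal(find_simple_repeats(seq), oracle_simple_repeats(seq),
                 info = sprintf("case %d", i), ignore_attr = TRUE)
  }
})

test_that("repeat fractions match per-base bitmap counting", {
  ann <- data.frame(start = c(0, 500), end = c(250, 750),
                    class = c("LINE", "LINE"))
  iv <- data.frame(start = 0, end = 500)
  rf <- repeat_fractions(ann, iv)
  expect_equal(rf$fraction[rf$class == "LINE"], 0.5)
  expect_equal(rf$fraction[rf$class == "All"], 0.5)
  expect_equal(rf$fraction[rf$class == "SINE"], 0)

  empty <- repeat_fractions(ann[0, ], iv)
  expect_true(all(empty$fraction == 0))

  for (s in 1:25) {
    set.seed(s)
    G <- 5000L
    n <- sample(3:12, 1)
    st <- sample.int(G - 300, n) - 1L
    ann <- data.frame(start = st, end = st + sample(20:300, n, replace = TRUE),
                      class = sample(REPEAT_CLASSES, n, replace = TRUE))
    ann$end <- pmin(ann$end, G)
    k <- sample(1:5, 1)
    ivs <- sample.int(G - 400, k) - 1L
    iv <- data.frame(start = ivs, end = ivs + sample(100:400, k, replace = TRUE))
    flat <- flatten_annotation(ann)
    rf <- repeat_fractions(ann, iv)
    for (cls in c(REPEAT_CLASSES, "All")) {
      expect_equal(rf$fraction[rf$class == cls],
                   oracle_class_fraction(flat, iv, cls, G),
                   info = sprintf("seed %d class %s", s, cls))
    }
  }
})

test_that("flattening resolves overlaps by class priority", {
  ann <- data.frame(start = c(0, 50, 120), end = c(100, 150, 160),
                    class = c("LINE", "Simple", "LINE"))
  flat <- flatten_annotation(ann)
  expect_true(all(flat$end[-nrow(flat)] <= flat$start[-1]))
  # Simple outranks LINE on the overlap [50, 100)
  expect_true(any(flat$class == "Simple" & flat$start == 50 & flat$end == 150))
  expect_true(any(flat$class == "LINE" & flat$start == 0 & flat$end == 50))
})

test_that("bootstrap CI behaves like a CI", {
  # degenerate: all units identical
  ci <- composition_ci(rep(0.4, 8), units = letters[1:8], seed = 1)
  expect_equal(unname(ci), c(0.4, 0.4, 0.4))
  # single unit: point only
  ci1 <- composition_ci(0.3, weights = 5)
  expect_equal(ci1[["point"]], 0.3)
  expect_true(is.na(ci1[["lo"]]))

  # order independence under a fixed seed
  set.seed(2)
  v <- runif(30); w <- runif(30, 1, 4); u <- sprintf("u%02d", 1:30)
  perm <- sample(30)
  expect_identical(composition_ci(v, w, u, seed = 9),
                   composition_ci(v[perm], w[perm], u[perm], seed = 9))

  # binomial toy: CI width shrinks ~ 1/sqrt(n) from 100 to 400 units
  set.seed(3)
  width <- function(n) {
    vals <- rbinom(n, 1000, 0.5) / 1000
    ci <- composition_ci(vals, weights = rep(1000, n),
                         units = sprintf("b%04d", seq_len(n)), seed = 4)
    ci[["hi"]] - ci[["lo"]]
  }
  ratio <- width(400) / width(100)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("all-gap fractions are the base-weighted mean over capture classes", {
  sim <- simulate_bac(length = 60000, n_bias = 3, bias_length = c(600, 1500),
                      viability = 0.15, simple_in_bias = 0.4,
                      repeat_densities = c(Simple = 0.016, LINE = 0.15),
                      seed = 77)
  res <- assay_bac(sim$ref, sim$draft, pairs = sim$pairs,
                   annotation = sim$annotation)
  rp <- res$composition$repeats
  for (cls in c("Simple", "LINE", "All")) {
    get <- function(scope, col) rp[rp$scope == scope & rp$class == cls, col]
    tot_b <- get("captured_gaps", "total_bases") + get("uncaptured_gaps", "total_bases")
    expect_equal(get("all_gaps", "total_bases"), tot_b)
    expect_equal(get("all_gaps", "bases"),
                 get("captured_gaps", "bases") + get("uncaptured_gaps", "bases"))
  }
  gc <- res$composition$gc
  expect_equal(gc$n_bases[gc$scope == "all_gaps"],
               sum(gc$n_bases[gc$scope %in% c("captured_gaps", "uncaptured_gaps")]))
})
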