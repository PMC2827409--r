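# Independent brute-force oracles used to check the package's fast paths.
# These deliberately use naive per-base / double-loop formulations.

# Complement of intervals within [lo, hi) via a per-base occupancy vector.
oracle_complement <- function(df, lo, hi) {
  if (hi <= lo) return(data.frame(start = integer(0), end = integer(0)))
  occ <- logical(hi - lo)
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      a <- max(df$start[i], lo); b <- min(df$end[i], hi)
      if (b > a) occ[(a - lo + 1):(b - lo)] <- TRUE
    }
  }
  free <- which(!occ)
  if (!length(free)) return(data.frame(start = integer(0), end = integer(0)))
  brk <- c(0, which(diff(free) > 1), length(free))
  data.frame(start = free[brk[-length(brk)] + 1] - 1L + lo,
             end = free[brk[-1]] + lo)
}

# Naive double loop over subclones: spanning and qualifying counts for a gap.
oracle_spanning <- function(gap, pairs_df, max_span = Inf) {
  n_span <- 0L; n_qual <- 0L
  for (sc in unique(pairs_df$subclone_id)) {
    rows <- pairs_df[pairs_df$subclone_id == sc, , drop = FALSE]
    reads <- split(rows, rows$read_id)
    if (length(reads) != 2) next
    r1 <- reads[[1]]; r2 <- reads[[2]]
    i1 <- c(min(r1$start), max(r1$end))
    i2 <- c(min(r2$start), max(r2$end))
    first_left <- i1[1] <= i2[1]
    left <- if (first_left) i1 else i2
    right <- if (first_left) i2 else i1
    left_strand <- if (first_left) r1$strand[1] else r2$strand[1]
    right_strand <- if (first_left) r2$strand[1] else r1$strand[1]
    innie <- left_strand == "+" && right_strand == "-"
    if (innie && left[2] <= gap$start && right[1] >= gap$end) {
      n_span <- n_span + 1L
      if (max(i1[2], i2[2]) - min(i1[1], i2[1]) <= max_span) n_qual <- n_qual + 1L
    }
  }
  c(spanning = n_span, qualifying = n_qual)
}

# Per-base bitmap repeat fractions for one class set.
oracle_class_fraction <- function(ann, intervals, cls, genome_len) {
  inrep <- logical(genome_len)
  rows <- if (identical(cls, "All")) ann else ann[ann$class == cls, , drop = FALSE]
  if (nrow(rows)) for (i in seq_len(nrow(rows))) {
    inrep[(rows$start[i] + 1):rows$end[i]] <- TRUE
  }
  insc <- logical(genome_len)
  if (nrow(intervals)) for (i in seq_len(nrow(intervals))) {
    insc[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  if (!any(insc)) return(NA_real_)
  sum(inrep & insc) / sum(insc)
}

# Naive per-base depth count for one strand.
oracle_depth <- function(df, len) {
  d <- integer(len)
  if (nrow(df)) for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i]) d[(df$start[i] + 1):df$end[i]] <- d[(df$start[i] + 1):df$end[i]] + 1L
  }
  d
}

# Exhaustive all-offsets tandem scan: union of every interval [a, b] whose
# length and purity meet the thresholds, for motif sizes 1-4.
oracle_simple_repeats <- function(seq, min_len = c(`1` = 12, `2` = 20, `3` = 21, `4` = 24),
                                  purity = 0.9) {
  n <- nchar(seq)
  x <- utf8ToInt(seq)
  hits <- logical(n)
  for (m in as.integer(names(min_len))) {
    Lmin <- min_len[[as.character(m)]]
    if (n < Lmin) next
    for (a in 1:(n - Lmin + 1)) {
      bs <- (a + Lmin - 1):n
      # matches at positions a+m .. b for every b, via cumulative sum
      cmp <- x[(a + m):n] == x[a:(n - m)]
      if (length(cmp) == 0) next
      cum <- cumsum(cmp)
      lens <- bs - a + 1
      idx <- bs - (a + m) + 1
      idx[idx > length(cum)] <- length(cum)
      matches <- cum[pmin(idx, length(cum))]
      good <- bs[matches >= purity * (lens - m) - 1e-9 & bs >= a + m]
      if (length(good)) {
        hits[a:max(good)] <- TRUE
      }
    }
  }
  if (!any(hits)) return(data.frame(start = integer(0), end = integer(0)))
  w <- which(hits)
  brk <- c(0, which(diff(w) > 1), length(w))
  data.frame(start = w[brk[-length(brk)] + 1] - 1L, end = w[brk[-1]])
}

# Random non-degenerate placement frame for mapping/gap tests.
random_placements <- function(ref_len, n, min_w = 50, max_w = 2000) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(ref_len - wi, 1) - 1L, integer(1))
  data.frame(contig_id = sprintf("c%02d", seq_len(n)), start = s, end = s + w,
             qstart = 0L, qend = w, strand = sample(c("+", "-"), n, TRUE),
             identity = round(stats::runif(n, 0.9, 1), 3),
             n_anchors = 1L, stringsAsFactors = FALSE)
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}
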