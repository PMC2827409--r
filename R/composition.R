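#' GC content of a sequence or of intervals within it
#'
#' @param seq Character scalar (or `finished_sequence`) over A/C/G/T.
#' @param intervals Optional `data.frame(start, end)` (0-based half-open);
#'   NULL means the whole sequence.
#' @return Fraction of G+C bases, or NA when the intervals cover zero bases.
#' @export
gc_content <- function(seq, intervals = NULL) {
  if (inherits(seq, "finished_sequence")) seq <- seq$seq
  s <- Biostrings::DNAString(seq)
  if (is.null(intervals)) {
    tot <- length(s)
    if (tot == 0) return(NA_real_)
    return(sum(Biostrings::letterFrequency(s, c("G", "C"))) / tot)
  }
  if (nrow(intervals) == 0 || sum(intervals$end - intervals$start) == 0) {
    return(NA_real_)
  }
  v <- Biostrings::Views(s, start = intervals$start + 1L, end = intervals$end)
  sum(Biostrings::letterFrequency(v, c("G", "C"))) / sum(IRanges::width(v))
}

#' Find simple-repeat tracts (homopolymer to tetranucleotide)
#'
#' Reports the union of all tandem tracts of motif size 1-4 that meet the
#' per-motif-size minimum length and a purity threshold, merged when
#' overlapping. Purity of a tract of length `l` and period `m` is the
#' fraction of the `l - m` positions matching the base `m` before them. The
#' scan is deterministic: for every start, the furthest qualifying end is
#' found, and qualifying intervals are unioned.
#'
#' @param seq Character scalar (or `finished_sequence`).
#' @param min_len Named integer vector of minimum tract lengths per motif
#'   size `"1"`..`"4"`.
#' @param purity Minimum tract purity in (0, 1\].
#' @return `data.frame(start, end)` (0-based half-open), sorted, disjoint.
#' @export
find_simple_repeats <- function(seq,
                                min_len = c(`1` = 12, `2` = 20, `3` = 21, `4` = 24),
                                purity = 0.9) {
  if (inherits(seq, "finished_sequence")) seq <- seq$seq
  n <- nchar(seq)
  if (n == 0) stopf("empty sequence")
  x <- utf8ToInt(seq)
  eps <- 1e-9
  found <- list()
  for (m in as.integer(names(min_len))) {
    Lmin <- min_len[[as.character(m)]]
    if (n < Lmin || n <= m) next
    M <- x[(m + 1):n] == x[1:(n - m)]
    C <- c(0, cumsum(M))                    # C[j+1] = matches at positions m+1..m+j
    # Interval [a, b] (1-based inclusive, length l = b-a+1) qualifies iff
    #   matches(a,b) = C[b-m+1] - C[a] >= purity * (l - m)
    # i.e.  H(b) >= T(a)  with  H(b) = C[b-m+1] - purity*b,
    #                            T(a) = C[a] - purity*(a + m - 1).
    bs <- (m + 1):n
    H <- C[bs - m + 1] - purity * bs
    K <- rev(cummax(rev(H)))                # K[j] = max_{b' >= bs[j]} H(b')
    amax <- n - Lmin + 1L
    if (amax < 1) next
    a <- 1:amax
    Tq <- C[a] - purity * (a + m - 1)
    # largest b with H(b) >= T(a): prefix property of non-increasing K
    revK <- rev(K)
    pos <- length(K) - findInterval(Tq - eps, revK)   # index into bs of last b with K >= T
    ok <- pos >= 1 & pos <= length(bs)
    bmax <- rep(NA_integer_, length(a))
    bmax[ok] <- bs[pos[ok]]
    qual <- ok & !is.na(bmax) & (bmax - a + 1) >= Lmin
    if (any(qual)) {
      found[[length(found) + 1L]] <- data.frame(start = a[qual] - 1L,
                                                end = bmax[qual])
    }
  }
  if (length(found) == 0) return(data.frame(start = integer(0), end = integer(0)))
  merge_intervals(do.call(rbind, found))
}

#' Flatten a repeat annotation to class-disjoint intervals
#'
#' Overlapping annotations are resolved by class priority (default
#' Simple > LINE > SINE > LTR > DNA): higher-priority classes keep their
#' bases, lower-priority intervals are cut around them.
#'
#' @param annotation `data.frame(start, end, class)`.
#' @param priority Character vector of classes from highest to lowest
#'   priority.
#' @return Sorted `data.frame(start, end, class)` with pairwise-disjoint
#'   intervals.
#' @export
flatten_annotation <- function(annotation,
                               priority = c("Simple", "LINE", "SINE", "LTR", "DNA")) {
  if (is.null(annotation) || nrow(annotation) == 0) {
    return(data.frame(start = integer(0), end = integer(0), class = character(0)))
  }
  taken <- IRanges::IRanges()
  out <- list()
  for (cls in priority) {
    rows <- annotation[annotation$class == cls, , drop = FALSE]
    if (nrow(rows) == 0) next
    ir <- IRanges::reduce(.ir(rows$start, rows$end))
    free <- IRanges::setdiff(ir, taken)
    if (length(free)) {
      df <- .from_ir(free)
      df$class <- cls
      out[[cls]] <- df
    }
    taken <- IRanges::union(taken, ir)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0), class = character(0)))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Repeat-class base fractions within a set of intervals
#'
#' For each repeat class, the fraction of interval bases overlapped by that
#' class in the flattened annotation; `All` is the union over classes.
#'
#' @param annotation `data.frame(start, end, class)` (flattened with
#'   [flatten_annotation()] if classes may overlap).
#' @param intervals `data.frame(start, end)` defining the scope (e.g., all
#'   gaps); zero rows give NA fractions.
#' @param scope Label recorded on the output rows.
#' @return `data.frame(scope, class, bases, total_bases, fraction)` with one
#'   row per class plus `All`.
#' @export
repeat_fractions <- function(annotation, intervals, scope = "total") {
  ann <- flatten_annotation(annotation)
  total <- if (nrow(intervals)) {
    sum(IRanges::width(IRanges::reduce(.ir(intervals$start, intervals$end))))
  } else 0L
  classes <- c(REPEAT_CLASSES, "All")
  bases <- vapply(classes, function(cls) {
    sub <- if (cls == "All") ann else ann[ann$class == cls, , drop = FALSE]
    interval_overlap_bases(sub, intervals)
  }, numeric(1))
  data.frame(scope = scope, class = classes, bases = as.integer(bases),
             total_bases = as.integer(total),
             fraction = if (total > 0) bases / total else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bootstrap confidence interval for a pooled per-unit fraction
#'
#' The point estimate is the weight-pooled mean (e.g., base-weighted GC or
#' repeat fraction across BACs); the confidence interval is a percentile
#' bootstrap resampling whole units with replacement. Units are sorted by
#' id before resampling, so the result does not depend on input order.
#'
#' @param values Per-unit fractions.
#' @param weights Per-unit weights (e.g., bases); default equal.
#' @param units Optional unit ids used for canonical ordering.
#' @param reps Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional integer seed (fixed seed gives deterministic CIs).
#' @return Named numeric vector `point`, `lo`, `hi` (`lo`/`hi` are NA with
#'   a single unit).
#' @export
composition_ci <- function(values, weights = NULL, units = NULL, reps = 1000,
                           conf = 0.95, seed = NULL) {
  stopifnot(length(values) >= 1)
  weights <- weights %||% rep(1, length(values))
  stopifnot(length(weights) == length(values))
  ord <- if (!is.null(units)) order(as.character(units)) else order(values, weights)
  values <- values[ord]; weights <- weights[ord]
  point <- sum(values * weights) / sum(weights)
  if (length(values) < 2) {
    return(c(point = point, lo = NA_real_, hi = NA_real_))
  }
  n <- length(values)
  stat <- with_seed_if(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      sum(values[idx] * weights[idx]) / sum(weights[idx])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(point = point, lo = qs[1], hi = qs[2])
}

#' Composition profile of gap versus total sequence
#'
#' Computes GC and repeat-class fractions for the canonical scopes of the
#' assay: the whole finished sequence, all internal gaps, captured gaps,
#' and uncaptured gaps.
#'
#' @param ref A `finished_sequence`.
#' @param annotation Repeat annotation for `ref`.
#' @param gaps Classified gap `data.frame` for `ref`.
#' @return List of `data.frame`s: `gc` (`scope, n_bases, gc`) and `repeats`
#'   (rows from [repeat_fractions()] per scope).
#' @export
composition_profile <- function(ref, annotation, gaps) {
  g <- gaps[gaps$kind == "internal", , drop = FALSE]
  scopes <- list(
    total = data.frame(start = 0L, end = ref$length),
    all_gaps = g[, c("start", "end"), drop = FALSE],
    captured_gaps = g[g$status == "captured", c("start", "end"), drop = FALSE],
    uncaptured_gaps = g[g$status == "uncaptured", c("start", "end"), drop = FALSE])
  gc <- do.call(rbind, lapply(names(scopes), function(sc) {
    iv <- scopes[[sc]]
    data.frame(scope = sc, n_bases = sum(iv$end - iv$start),
               gc = gc_content(ref, iv), stringsAsFactors = FALSE)
  }))
  reps <- do.call(rbind, lapply(names(scopes), function(sc) {
    repeat_fractions(annotation, scopes[[sc]], scope = sc)
  }))
  rownames(gc) <- rownames(reps) <- NULL
  list(gc = gc, repeats = reps)
}
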