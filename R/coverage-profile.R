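#' Per-strand read redundancy along a contig
#'
#' @param placements Placement `data.frame` (rows for one contig or
#'   reference; filtered to `contig_id` when given).
#' @param length Contig length in bp.
#' @param contig_id Optional id to select rows (`seq_id` column) and record
#'   on the profile.
#' @return A `redundancy_profile`: list with `contig_id`, `length`,
#'   `depth_fwd`, `depth_rev` (integer vectors, upper/lower strand), and
#'   `depth` (their sum).
#' @export
depth_profile <- function(placements, length, contig_id = NULL) {
  df <- if (inherits(placements, "read_pairs")) placements$pairs else placements
  if (!is.null(contig_id)) df <- df[df$seq_id == contig_id, , drop = FALSE]
  depth_for <- function(rows) {
    if (nrow(rows) == 0) return(integer(length))
    as.integer(IRanges::coverage(.ir(rows$start, rows$end), width = length))
  }
  up <- depth_for(df[df$strand == "+", , drop = FALSE])
  dn <- depth_for(df[df$strand == "-", , drop = FALSE])
  structure(list(contig_id = contig_id %||% "contig", length = as.integer(length),
                 depth_fwd = up, depth_rev = dn, depth = up + dn),
            class = "redundancy_profile")
}

#' Ordinal redundancy-variation score
#'
#' Splits the combined-strand depth into non-overlapping windows, computes
#' the coefficient of variation (population SD / mean) of depth within each
#' window, summarizes by the 90th percentile of window CVs (so one severe
#' trough dominates), and maps the summary onto the ordinal scale
#' `-`, `+`, `++`, `++++` at the supplied cutpoints. Contigs shorter than
#' one window are scored as a single window.
#'
#' @param profile A `redundancy_profile`, or a numeric depth vector.
#' @param window Window size in bp.
#' @param thresholds Increasing CV cutpoints separating the four levels.
#' @return List: `score` (ordinal label), `summary_cv`, `window_cv`
#'   (`data.frame(start, cv)`).
#' @export
variation_score <- function(profile, window = 2000,
                            thresholds = c(0.35, 0.55, 0.80)) {
  depth <- if (inherits(profile, "redundancy_profile")) profile$depth else as.numeric(profile)
  n <- length(depth)
  stopifnot(n >= 1, length(thresholds) == 3, !is.unsorted(thresholds))
  if (n < window) {
    starts <- 0L
    cvs <- .depth_cv(depth)
  } else {
    k <- n %/% window
    starts <- (seq_len(k) - 1L) * window
    cvs <- vapply(seq_len(k), function(i) {
      .depth_cv(depth[(starts[i] + 1L):(starts[i] + window)])
    }, numeric(1))
  }
  summary_cv <- stats::quantile(cvs, 0.9, names = FALSE, type = 7)
  lev <- c("-", "+", "++", "++++")
  score <- lev[1L + findInterval(summary_cv, thresholds, left.open = TRUE)]
  list(score = score, summary_cv = summary_cv,
       window_cv = data.frame(start = starts, cv = cvs))
}

# Population CV; an entirely uncovered window has no redundancy signal and
# scores 0 by convention.
.depth_cv <- function(d) {
  m <- mean(d)
  if (m == 0) return(0)
  sqrt(mean((d - m)^2)) / m
}

#' Numeric rank of an ordinal redundancy score
#'
#' Maps `-`, `+`, `++`, `++++` to 0-3 (used for averaging in reports).
#' @param score Character vector of ordinal labels.
#' @export
score_rank <- function(score) {
  match(score, c("-", "+", "++", "++++")) - 1L
}
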