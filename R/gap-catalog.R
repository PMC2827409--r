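#' Catalogue sequence gaps from a contig map
#'
#' A gap is a reference interval not covered by any placed contig. Internal
#' gaps lie between adjacent placements; uncovered reference ends are
#' emitted as `terminal` gaps (one flank only) and are excluded from the
#' headline statistics by default. Abutting placements yield no gap.
#'
#' @param map A `contig_map` from [resolve_map()].
#' @return `data.frame` with columns `sequence_id`, `start`, `end`, `size`,
#'   `left_contig`, `right_contig`, `kind` (`internal`/`terminal`),
#'   `spanning_subclones` (NA until classified), `status` (`unset`).
#' @export
call_gaps <- function(map) {
  stopifnot(inherits(map, "contig_map"))
  pl <- map$placements
  mk <- function(start, end, left, right, kind) {
    n <- length(start)
    data.frame(sequence_id = rep(map$sequence_id, n), start = as.integer(start),
               end = as.integer(end), size = as.integer(end - start),
               left_contig = rep_len(left, n), right_contig = rep_len(right, n),
               kind = rep_len(kind, n),
               spanning_subclones = rep(NA_integer_, n),
               status = rep("unset", n), stringsAsFactors = FALSE)
  }
  empty <- mk(integer(0), integer(0), character(0), character(0), character(0))
  if (nrow(pl) == 0) return(empty)
  out <- list()
  if (pl$start[1] > 0) {
    out[[length(out) + 1L]] <- mk(0L, pl$start[1], NA_character_,
                                  pl$contig_id[1], "terminal")
  }
  if (nrow(pl) >= 2) {
    i <- which(pl$end[-nrow(pl)] < pl$start[-1])
    if (length(i)) {
      out[[length(out) + 1L]] <- mk(pl$end[i], pl$start[i + 1L],
                                    pl$contig_id[i], pl$contig_id[i + 1L],
                                    "internal")
    }
  }
  n <- nrow(pl)
  if (pl$end[n] < map$reference_length) {
    out[[length(out) + 1L]] <- mk(pl$end[n], map$reference_length,
                                  pl$contig_id[n], NA_character_, "terminal")
  }
  if (length(out) == 0) return(empty)
  g <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  g <- g[order(g$start), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Summary statistics for a gap catalogue
#'
#' Computes the per-Mb gap frequency, per-Mb gap bases, and median gap size
#' for one analysis unit (a species, region, or single assembly). The
#' median is the lower median for even counts. Terminal gaps are excluded
#' unless `include_terminal = TRUE`.
#'
#' @param gaps Gap `data.frame` from [call_gaps()] (possibly concatenated
#'   across assemblies).
#' @param total_mb Finished sequence analysed, in Mb (> 0).
#' @param unit Label for the analysis unit.
#' @param include_terminal Include terminal gaps in the statistics.
#' @return One-row `data.frame`: `unit`, `n_gaps`, `total_mb`,
#'   `gaps_per_mb`, `gap_bases_per_mb`, `median_gap_size` (NA when there are
#'   no gaps).
#' @export
gap_stats <- function(gaps, total_mb, unit = "all", include_terminal = FALSE) {
  if (!is.numeric(total_mb) || total_mb <= 0) {
    stopf("total_mb must be positive (got %s)", format(total_mb))
  }
  g <- if (include_terminal) gaps else gaps[gaps$kind == "internal", , drop = FALSE]
  data.frame(unit = unit, n_gaps = nrow(g), total_mb = total_mb,
             gaps_per_mb = nrow(g) / total_mb,
             gap_bases_per_mb = sum(g$size) / total_mb,
             median_gap_size = lower_median(g$size),
             stringsAsFactors = FALSE)
}

#' Percent of finished sequence residing in gaps
#'
#' @param gap_mb Total gap span (Mb).
#' @param total_mb Total finished sequence (Mb, > 0).
#' @return Percentage, rounded to one decimal.
#' @export
gap_span_percent <- function(gap_mb, total_mb) {
  stopifnot(total_mb > 0, gap_mb >= 0)
  if (gap_mb > total_mb) {
    warning("gap span exceeds total sequence; reporting > 100%")
  }
  round(100 * gap_mb / total_mb, 1)
}
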