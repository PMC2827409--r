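#' Aggregate a BAC manifest into totals
#'
#' Rows may describe single BACs (one row per `bac_id`) or pre-aggregated
#' groups carrying an `n_bacs` count column. Totals are computed, never
#' copied from a printed source: `n_bacs` is the sum of per-row counts and
#' `total_mb` the sum of per-row sequence (from `total_mb` or
#' `finished_length` in bp).
#'
#' @param manifest Manifest `data.frame`.
#' @return List `n_bacs`, `total_mb` (unrounded), `total_mb_printed`
#'   (rounded to 2 decimals, the usual table precision).
#' @export
aggregate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
  if ("bac_id" %in% names(manifest) && anyDuplicated(manifest$bac_id)) {
    stopf("duplicate bac_id in manifest: %s",
          paste(unique(manifest$bac_id[duplicated(manifest$bac_id)]), collapse = ", "))
  }
  n <- if ("n_bacs" %in% names(manifest)) sum(manifest$n_bacs) else nrow(manifest)
  mb <- if ("total_mb" %in% names(manifest)) {
    sum(manifest$total_mb)
  } else if ("finished_length" %in% names(manifest)) {
    sum(manifest$finished_length) / 1e6
  } else NA_real_
  list(n_bacs = as.integer(n), total_mb = mb,
       total_mb_printed = round(mb, 2))
}

#' Per-group report of the finishing-effort assay
#'
#' One row per species (or region): gap frequency and size statistics,
#' captured/uncaptured gaps per Mb with bootstrap confidence intervals
#' (resampling BACs with replacement), the fraction of assemblies with two
#' or more uncaptured gaps, and the mean redundancy-variation rank.
#'
#' @param per_bac `data.frame` with one row per assembly: `bac_id`,
#'   `species`, `region`, `finished_length`, `n_uncaptured`, `score`.
#' @param gaps Classified gap `data.frame` with `bac_id`.
#' @param group_by `"species"` or `"region"`.
#' @param reps Bootstrap replicates for the CIs.
#' @param seed Optional integer seed for the bootstrap.
#' @return `data.frame`, one row per non-empty group.
#' @export
summarize_assay <- function(per_bac, gaps, group_by = c("species", "region"),
                            reps = 500, seed = NULL) {
  group_by <- match.arg(group_by)
  g <- gaps[gaps$kind == "internal", , drop = FALSE]
  groups <- split(per_bac, as.character(per_bac[[group_by]]))
  rows <- lapply(names(groups), function(nm) {
    mf <- groups[[nm]]
    if (nrow(mf) == 0) return(NULL)
    gg <- g[g$bac_id %in% mf$bac_id, , drop = FALSE]
    mb_bac <- stats::setNames(mf$finished_length / 1e6, mf$bac_id)
    mb <- sum(mb_bac)
    st <- gap_stats(gg, mb, unit = nm)
    rate_ci <- function(status) {
      cnt <- vapply(mf$bac_id, function(b) sum(gg$bac_id == b & gg$status == status), numeric(1))
      composition_ci(cnt / mb_bac, weights = mb_bac, units = mf$bac_id,
                     reps = reps, seed = seed)
    }
    cap <- rate_ci("captured"); unc <- rate_ci("uncaptured")
    data.frame(group = nm, n_bacs = nrow(mf), total_mb = mb,
               n_gaps = st$n_gaps, gaps_per_mb = st$gaps_per_mb,
               gap_bases_per_mb = st$gap_bases_per_mb,
               median_gap_size = st$median_gap_size,
               captured_per_mb = cap[["point"]],
               captured_lo = cap[["lo"]], captured_hi = cap[["hi"]],
               uncaptured_per_mb = unc[["point"]],
               uncaptured_lo = unc[["lo"]], uncaptured_hi = unc[["hi"]],
               frac_uncaptured = if (nrow(gg)) mean(gg$status == "uncaptured") else 0,
               frac_ge2_uncaptured = mean(mf$n_uncaptured >= 2),
               mean_score_rank = mean(score_rank(mf$score)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    warning("no non-empty groups to summarize")
    return(data.frame())
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res[order(res$group), , drop = FALSE]
}

#' Round a report for presentation
#'
#' Per-Mb rates and percents at one decimal, as in the assay's reports;
#' the full-precision table should be written alongside.
#' @param report `data.frame` from [summarize_assay()].
#' @export
round_report <- function(report) {
  num <- vapply(report, is.numeric, logical(1))
  report[num] <- lapply(report[num], function(x) round(x, 1))
  report
}
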