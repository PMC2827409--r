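#' Rule for deciding whether a gap is captured by spanning subclones
#'
#' A gap is captured when at least `min_spanning_pairs` subclones span it
#' with an implied span that does not greatly exceed the library insert
#' size. The spacing bound is `insert_mean + k_sd * insert_sd` by default,
#' or `multiplier * insert_mean` when `multiplier` is given.
#'
#' @param min_spanning_pairs Minimum qualifying spanning subclones (>= 1).
#' @param k_sd Number of insert-size standard deviations allowed above the
#'   mean.
#' @param multiplier Optional alternative bound as a multiple of the mean
#'   insert size.
#' @export
capture_rule <- function(min_spanning_pairs = 2, k_sd = 3, multiplier = NULL) {
  stopifnot(min_spanning_pairs >= 1, k_sd > 0 || !is.null(multiplier))
  structure(list(min_spanning_pairs = as.integer(min_spanning_pairs),
                 k_sd = k_sd, multiplier = multiplier),
            class = "capture_rule")
}

.max_span <- function(rule, insert_mean, insert_sd) {
  ms <- if (!is.null(rule$multiplier)) rule$multiplier * insert_mean
        else insert_mean + rule$k_sd * insert_sd
  if (ms <= insert_mean) stopf("capture rule max span (%.0f) must exceed the mean insert size (%.0f)", ms, insert_mean)
  ms
}

# Per-subclone geometry from placement rows in one coordinate system: the
# outer interval [outer_start, outer_end), and for subclones with two placed
# reads the inner flanks (left read end, right read start) and strands. A
# properly oriented ("innie") pair has the left read on "+" and the right
# read on "-"; pairs wrapping the circular origin surface as outies and are
# thereby excluded from spanning evidence.
.subclone_geometry <- function(df) {
  if (nrow(df) == 0) {
    return(data.frame(subclone_id = character(0), n_reads = integer(0),
                      outer_start = integer(0), outer_end = integer(0),
                      left_end = integer(0), right_start = integer(0),
                      innie = logical(0)))
  }
  rid <- paste(df$subclone_id, df$read_id, sep = "\r")
  rs <- tapply(df$start, rid, min)
  re <- tapply(df$end, rid, max)
  rstrand <- tapply(df$strand, rid, function(s) s[1])
  sub <- sub("\r.*$", "", names(rs))
  ord <- order(sub, rs)
  rs <- rs[ord]; re <- re[ord]; sub <- sub[ord]; rstrand <- rstrand[ord]
  first <- !duplicated(sub)
  idx1 <- which(first)
  counts <- as.integer(tabulate(factor(sub, levels = unique(sub))))
  two <- counts >= 2
  res <- data.frame(subclone_id = unique(sub), n_reads = counts,
                    outer_start = NA_integer_, outer_end = NA_integer_,
                    left_end = NA_integer_, right_start = NA_integer_,
                    innie = FALSE, stringsAsFactors = FALSE)
  res$outer_start <- as.integer(rs[idx1])
  ends <- tapply(re, sub, max)
  res$outer_end <- as.integer(ends[res$subclone_id])
  res$left_end[two] <- as.integer(re[idx1[two]])
  res$right_start[two] <- as.integer(rs[idx1[two] + res$n_reads[two] - 1L])
  res$innie[two] <- rstrand[idx1[two]] == "+" &
    rstrand[idx1[two] + res$n_reads[two] - 1L] == "-"
  res
}

#' Count subclones spanning a gap
#'
#' A subclone spans a gap when its two read placements lie on opposite
#' sides of the gap interval (one read ends at or before the gap start, the
#' other starts at or after the gap end) in proper relative orientation
#' (mates pointing toward each other across the gap). The implied span is
#' the outermost distance between the two reads.
#'
#' @param gap One-row gap `data.frame` (or list with `start`/`end`).
#' @param pairs `read_pairs` object or placement `data.frame` on the same
#'   reference as the gap.
#' @return Integer count, with the qualifying spans attached as attribute
#'   `"spans"`.
#' @export
count_spanning_subclones <- function(gap, pairs) {
  df <- if (inherits(pairs, "read_pairs")) pairs$pairs else pairs
  geo <- .subclone_geometry(df)
  hit <- !is.na(geo$left_end) & geo$innie & geo$left_end <= gap$start &
    geo$right_start >= gap$end
  spans <- (geo$outer_end - geo$outer_start)[hit]
  structure(sum(hit), spans = as.integer(spans))
}

#' Classify gaps as captured or uncaptured
#'
#' Applies the capture rule to every internal gap: a gap is `captured` when
#' at least `rule$min_spanning_pairs` subclones span it with implied span
#' at most the rule's bound, else `uncaptured`. Terminal gaps have a single
#' flank and are never classified. The `spanning_subclones` column records
#' the qualifying count.
#'
#' @param gaps Gap `data.frame` from [call_gaps()].
#' @param pairs `read_pairs` or placement `data.frame` in reference
#'   coordinates (see [lift_placements()] for contig-coordinate input).
#' @param rule A [capture_rule()].
#' @param insert_mean,insert_sd Library insert statistics; taken from
#'   `pairs$library` when `pairs` is a `read_pairs` object.
#' @return `gaps` with `status` and `spanning_subclones` filled for
#'   internal gaps.
#' @export
classify_gaps <- function(gaps, pairs, rule = capture_rule(),
                          insert_mean = NULL, insert_sd = NULL) {
  if (inherits(pairs, "read_pairs")) {
    insert_mean <- insert_mean %||% pairs$library$insert_mean
    insert_sd <- insert_sd %||% pairs$library$insert_sd
  }
  if (is.null(insert_mean) || is.null(insert_sd)) {
    stopf("library insert statistics are required to classify gaps")
  }
  max_span <- .max_span(rule, insert_mean, insert_sd)
  df <- if (inherits(pairs, "read_pairs")) pairs$pairs else pairs
  geo <- .subclone_geometry(df)
  geo <- geo[!is.na(geo$left_end) & geo$innie, , drop = FALSE]
  span <- geo$outer_end - geo$outer_start
  for (i in which(gaps$kind == "internal")) {
    qual <- geo$left_end <= gaps$start[i] & geo$right_start >= gaps$end[i] &
      span <= max_span
    n <- sum(qual)
    gaps$spanning_subclones[i] <- n
    gaps$status[i] <- if (n >= rule$min_spanning_pairs) "captured" else "uncaptured"
  }
  gaps
}

#' Lift contig-coordinate read placements to reference coordinates
#'
#' Uses the trimmed contig map to transform placements made on draft
#' contigs into the finished-reference coordinate system; reads on
#' unmapped contigs (or outside the aligned contig interval) are dropped.
#'
#' @param placements Placement `data.frame` with `seq_id` equal to contig
#'   ids.
#' @param map A `contig_map`.
#' @return Placement `data.frame` in reference coordinates.
#' @export
lift_placements <- function(placements, map) {
  pl <- map$placements
  m <- match(placements$seq_id, pl$contig_id)
  keep <- !is.na(m)
  r <- placements[keep, , drop = FALSE]
  m <- m[keep]
  a <- pmax(r$start, pl$qstart[m]); b <- pmin(r$end, pl$qend[m])
  ok <- b > a
  r <- r[ok, , drop = FALSE]; m <- m[ok]; a <- a[ok]; b <- b[ok]
  plus <- pl$strand[m] == "+"
  start2 <- ifelse(plus, pl$start[m] + (a - pl$qstart[m]),
                   pl$start[m] + (pl$qend[m] - b))
  end2 <- ifelse(plus, pl$start[m] + (b - pl$qstart[m]),
                 pl$start[m] + (pl$qend[m] - a))
  strand2 <- ifelse(plus, r$strand, ifelse(r$strand == "+", "-", "+"))
  out <- r
  out$seq_id <- map$sequence_id
  out$start <- as.integer(start2); out$end <- as.integer(end2)
  out$strand <- strand2
  rownames(out) <- NULL
  out
}

#' Per-group burden of uncaptured gaps
#'
#' Summarizes classified gap catalogues across assemblies: the fraction of
#' assemblies containing two or more uncaptured gaps (the practical
#' difficulty criterion), the fraction of internal gaps uncaptured, and
#' captured/uncaptured gaps per Mb.
#'
#' @param gaps Classified gap `data.frame` carrying a `bac_id` column.
#' @param manifest `data.frame(bac_id, species, region, finished_length)`;
#'   every `bac_id` in `gaps` must appear.
#' @param group_by `"species"` or `"region"` (or `"bac_id"`).
#' @return One row per group: `group`, `n_assemblies`, `total_mb`,
#'   `n_gaps`, `frac_uncaptured`, `captured_per_mb`, `uncaptured_per_mb`,
#'   `frac_ge2_uncaptured`.
#' @export
uncaptured_burden <- function(gaps, manifest, group_by = "species") {
  stopifnot("bac_id" %in% names(gaps), group_by %in% names(manifest))
  g <- gaps[gaps$kind == "internal", , drop = FALSE]
  if (any(g$status == "unset")) stopf("all internal gaps must be classified first")
  grp_of <- stats::setNames(as.character(manifest[[group_by]]), manifest$bac_id)
  bad <- setdiff(unique(g$bac_id), names(grp_of))
  if (length(bad)) stopf("gap table references assemblies missing from the manifest: %s", paste(bad, collapse = ", "))
  out <- lapply(split(manifest, as.character(manifest[[group_by]])), function(mf) {
    gg <- g[g$bac_id %in% mf$bac_id, , drop = FALSE]
    mb <- sum(mf$finished_length) / 1e6
    unc_by_bac <- vapply(mf$bac_id, function(b) sum(gg$bac_id == b & gg$status == "uncaptured"), integer(1))
    data.frame(group = as.character(mf[[group_by]][1]),
               n_assemblies = nrow(mf), total_mb = mb, n_gaps = nrow(gg),
               frac_uncaptured = if (nrow(gg)) mean(gg$status == "uncaptured") else 0,
               captured_per_mb = sum(gg$status == "captured") / mb,
               uncaptured_per_mb = sum(gg$status == "uncaptured") / mb,
               frac_ge2_uncaptured = mean(unc_by_bac >= 2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$group), , drop = FALSE]
}
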