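#' Resolve contig alignments into an ordered, oriented contig map
#'
#' Automates the curation step of the assay: for each contig the
#' highest-scoring set of alignment blocks is retained (score = aligned bp x
#' identity; blocks competing for the same stretch of contig are resolved by
#' score), then overlaps between adjacent placements on the reference are
#' trimmed deterministically from the lower-identity placement (tie: trim
#' the shorter; still tied: trim the lexicographically later `contig_id`).
#' The resulting placements are pairwise disjoint and sorted by reference
#' start.
#'
#' @param alignments `data.frame` as returned by [align_contigs()].
#' @param reference_length Length of the reference (bp).
#' @param contig_ids Optional full universe of contig ids, used to report
#'   contigs with no surviving placement.
#' @param sequence_id Reference sequence id recorded in the map.
#' @param band Diagonal tolerance used to judge colinearity of retained
#'   blocks when flagging split contigs.
#' @return A `contig_map`: list with `sequence_id`, `reference_length`,
#'   `placements` (disjoint, sorted `data.frame(contig_id, start, end,
#'   qstart, qend, strand, identity)`), `unmapped_contigs`, `split_contigs`.
#' @export
resolve_map <- function(alignments, reference_length, contig_ids = NULL,
                        sequence_id = "ref", band = 100) {
  empty <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), qstart = integer(0),
                      qend = integer(0), strand = character(0),
                      identity = numeric(0))
  if (is.null(alignments) || nrow(alignments) == 0) {
    return(structure(list(sequence_id = sequence_id,
                          reference_length = as.integer(reference_length),
                          placements = empty,
                          unmapped_contigs = as.character(contig_ids %||% character(0)),
                          split_contigs = character(0)),
                     class = "contig_map"))
  }

  # Per-contig block selection: greedy by score, discarding blocks whose
  # contig interval substantially overlaps an already-kept block.
  kept <- list()
  split_ids <- character(0)
  for (cid in unique(alignments$contig_id)) {
    b <- alignments[alignments$contig_id == cid, , drop = FALSE]
    b$score <- (b$end - b$start) * b$identity
    b <- b[order(-b$score), , drop = FALSE]
    sel <- integer(0)
    for (i in seq_len(nrow(b))) {
      ok <- TRUE
      for (j in sel) {
        ov <- min(b$qend[i], b$qend[j]) - max(b$qstart[i], b$qstart[j])
        if (ov > 0.5 * min(b$qend[i] - b$qstart[i], b$qend[j] - b$qstart[j])) {
          ok <- FALSE; break
        }
      }
      if (ok) sel <- c(sel, i)
    }
    bb <- b[sel, , drop = FALSE]
    if (nrow(bb) >= 2) split_ids <- c(split_ids, cid)
    kept[[cid]] <- bb
  }
  pl <- do.call(rbind, c(kept, list(make.row.names = FALSE)))
  pl <- pl[order(pl$start, pl$end, pl$contig_id), , drop = FALSE]

  # Overlap trimming, left to right; kept placements stay disjoint/sorted.
  res <- list()
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, , drop = FALSE]
    while (length(res) > 0 && nrow(p) > 0) {
      last <- res[[length(res)]]
      ov <- last$end - p$start
      if (ov <= 0) break
      loser_is_p <- .trim_loser_is_second(last, p)
      if (loser_is_p) {
        p <- .trim_ref_left(p, ov)
      } else {
        last <- .trim_ref_right(last, ov)
        if (last$end - last$start > 0) {
          res[[length(res)]] <- last
          break
        }
        res[[length(res)]] <- NULL
      }
    }
    if (nrow(p) > 0 && p$end - p$start > 0) res[[length(res) + 1L]] <- p
  }
  placements <- if (length(res)) {
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  } else empty
  placements$score <- NULL
  rownames(placements) <- NULL

  ids_seen <- if (is.null(contig_ids)) unique(alignments$contig_id) else as.character(contig_ids)
  unmapped <- setdiff(ids_seen, unique(placements$contig_id))
  structure(list(sequence_id = sequence_id,
                 reference_length = as.integer(reference_length),
                 placements = placements,
                 unmapped_contigs = unmapped,
                 split_contigs = sort(unique(split_ids))),
            class = "contig_map")
}

# TRUE when the second (right) placement loses the overlap: lower identity
# loses; tie -> shorter aligned span loses; tie -> later contig_id loses.
.trim_loser_is_second <- function(a, b) {
  if (b$identity != a$identity) return(b$identity < a$identity)
  wa <- a$end - a$start; wb <- b$end - b$start
  if (wa != wb) return(wb < wa)
  b$contig_id >= a$contig_id
}

.trim_ref_left <- function(p, t) {
  p$start <- p$start + t
  if (p$strand == "+") p$qstart <- p$qstart + t else p$qend <- p$qend - t
  p
}

.trim_ref_right <- function(p, t) {
  p$end <- p$end - t
  if (p$strand == "+") p$qend <- p$qend - t else p$qstart <- p$qstart + t
  p
}

#' @export
print.contig_map <- function(x, ...) {
  cat(sprintf("<contig_map> %s (%d bp): %d placements, %d unmapped, %d split\n",
              x$sequence_id, x$reference_length, nrow(x$placements),
              length(x$unmapped_contigs), length(x$split_contigs)))
  invisible(x)
}

#' Import externally produced contig alignments
#'
#' Reads a 9-column TSV (`contig_id, start, end, qstart, qend, strand,
#' identity, n_anchors, sequence_id`) so alignments from an external aligner
#' can be fed to [resolve_map()] in place of [align_contigs()].
#'
#' @param path TSV file path.
#' @export
read_alignments_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("contig_id", "start", "end", "qstart", "qend", "strand", "identity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("alignment TSV lacks columns: %s", paste(miss, collapse = ", "))
  df
}
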