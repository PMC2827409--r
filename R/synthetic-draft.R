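#' Build a draft assembly from simulated read placements
#'
#' Emulates the outcome of a shotgun assembly without running an assembler:
#' contigs are the maximal reference intervals with read depth >=
#' `min_depth`, emitted as the (error-free) reference substring, and the gap
#' truth is recorded exactly. Contigs shorter than `min_contig` are
#' discarded, matching the comparative-grade convention that only contigs
#' greater than 2 kb are ordered and oriented.
#'
#' @param ref A `finished_sequence`.
#' @param pairs A `read_pairs` object (placements on `ref`).
#' @param min_contig Minimum retained contig length (bp).
#' @param min_depth Minimum read depth defining covered sequence.
#' @param shuffle Randomly permute contig order and reverse-complement a
#'   random subset, to exercise order/orientation recovery.
#' @param chimera If TRUE, join two distinct covered segments into one
#'   chimeric contig (a planted misassembly for the split-contig detector).
#' @param annotation Optional repeat annotation recorded in the truth.
#' @param bias Optional [bias_model()] recorded in the truth.
#' @param seed Optional integer seed (used when `shuffle` or `chimera`).
#' @return A `draft_assembly` list: `contigs`
#'   (`data.frame(contig_id, length, seq)`), `placements` (read placements
#'   lifted to contig coordinates, clipped at contig ends), `library`, and
#'   `truth` (list with `true_gaps`, `layout`
#'   (`contig_id, ref_start, ref_end, orientation`), `chimera_contigs`,
#'   `bias_regions`, `planted_repeats`, `seed`).
#' @export
build_draft <- function(ref, pairs, min_contig = 2000, min_depth = 1,
                        shuffle = FALSE, chimera = FALSE, annotation = NULL,
                        bias = NULL, seed = NULL) {
  stopifnot(inherits(ref, "finished_sequence"), inherits(pairs, "read_pairs"))
  G <- ref$length
  cov <- IRanges::coverage(.ir(pairs$pairs$start, pairs$pairs$end), width = G)
  covered <- IRanges::slice(cov, lower = min_depth, rangesOnly = TRUE)
  covered <- .from_ir(covered)
  retained <- covered[covered$end - covered$start >= min_contig, , drop = FALSE]
  if (nrow(retained) == 0) {
    stopf("no covered interval reaches min_contig = %d bp; nothing to assemble", min_contig)
  }
  span_lo <- min(retained$start); span_hi <- max(retained$end)
  true_gaps <- interval_complement(retained, span_lo, span_hi)

  with_seed_if(seed, {
    n <- nrow(retained)
    layout <- data.frame(ref_start = retained$start, ref_end = retained$end,
                         orientation = rep("+", n), stringsAsFactors = FALSE)
    chimera_members <- NULL
    if (chimera && n >= 2) {
      pick <- sort(sample.int(n, 2))
      chimera_members <- pick
    }
    ord <- if (shuffle) sample.int(n) else seq_len(n)
    if (shuffle) {
      layout$orientation <- sample(c("+", "-"), n, replace = TRUE)
    }
    layout <- layout[ord, , drop = FALSE]
    rownames(layout) <- NULL

    seqs <- character(nrow(layout))
    for (i in seq_len(nrow(layout))) {
      s <- substr(ref$seq, layout$ref_start[i] + 1, layout$ref_end[i])
      if (layout$orientation[i] == "-") s <- revcomp(s)
      seqs[i] <- s
    }

    chimera_ids <- character(0)
    if (!is.null(chimera_members)) {
      # join the two picked segments (in their shuffled incarnation) into one
      # contig; the joint inherits the first member's layout row, and the
      # second member's row is removed from the emitted contig set but kept
      # in the truth for reference.
      ji <- match(chimera_members, ord)
      a <- min(ji); b <- max(ji)
      seqs[a] <- paste0(seqs[a], seqs[b])
      seqs <- seqs[-b]
      chim_row <- layout[b, , drop = FALSE]
      layout <- layout[-b, , drop = FALSE]
      rownames(layout) <- NULL
      chimera_ids <- sprintf("ctg%03d", min(a, nrow(layout)))
      attr(chimera_ids, "second_segment") <- chim_row
    }

    ids <- sprintf("ctg%03d", seq_len(nrow(layout)))
    layout <- cbind(contig_id = ids, layout, stringsAsFactors = FALSE)
    contigs <- data.frame(contig_id = ids, length = nchar(seqs), seq = seqs,
                          stringsAsFactors = FALSE)

    placements <- .lift_to_contigs(pairs$pairs, layout)

    structure(list(
      contigs = contigs,
      placements = placements,
      library = pairs$library,
      reference_id = ref$id,
      truth = list(true_gaps = true_gaps, layout = layout,
                   chimera_contigs = chimera_ids,
                   bias_regions = if (is.null(bias)) NULL else bias$regions,
                   planted_repeats = annotation,
                   span = c(span_lo, span_hi), seed = seed)),
      class = "draft_assembly")
  })
}

# Lift reference-coordinate read rows onto contigs described by `layout`
# (contig_id, ref_start, ref_end, orientation), clipping at contig ends.
.lift_to_contigs <- function(rows, layout) {
  if (nrow(rows) == 0 || nrow(layout) == 0) {
    return(rows[0, , drop = FALSE])
  }
  hits <- IRanges::findOverlaps(.ir(rows$start, rows$end),
                                .ir(layout$ref_start, layout$ref_end))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  r <- rows[qi, , drop = FALSE]
  cs <- layout$ref_start[si]; ce <- layout$ref_end[si]
  os <- pmax(r$start, cs); oe <- pmin(r$end, ce)
  flip <- layout$orientation[si] == "-"
  start2 <- ifelse(flip, ce - oe, os - cs)
  end2 <- ifelse(flip, ce - os, oe - cs)
  strand2 <- ifelse(flip, ifelse(r$strand == "+", "-", "+"), r$strand)
  out <- data.frame(read_id = r$read_id, subclone_id = r$subclone_id,
                    seq_id = layout$contig_id[si],
                    start = as.integer(start2), end = as.integer(end2),
                    strand = strand2, mate_id = r$mate_id,
                    library_id = r$library_id, role = r$role,
                    stringsAsFactors = FALSE)
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}
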