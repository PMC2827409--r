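#' Align draft contigs to a finished reference
#'
#' A seed-and-chain aligner tailored to the finishing assay, where draft and
#' finished sequence derive from the same clone and alignments are
#' near-exact: anchors are k-mers unique in both the reference and the
#' contig, chained by strand and diagonal into colinear blocks, then
#' extended outward base-by-base while the sequences match exactly. Blocks
#' narrower than `min_block` are dropped. A contig yielding two or more
#' mutually non-colinear blocks is a putative misassembly (split contig).
#'
#' @param contigs A `draft_assembly`, a `data.frame(contig_id, seq)`, or a
#'   named character vector of contig sequences.
#' @param reference A `finished_sequence` or a character scalar.
#' @param k Anchor k-mer size (odd, 11-63).
#' @param min_block Minimum emitted block width (bp).
#' @param band Anchors whose alignment diagonals differ by more than this
#'   are not chained into one block.
#' @return `data.frame` with one row per block: `contig_id`, `start`, `end`
#'   (reference, 0-based half-open), `qstart`, `qend` (contig), `strand`,
#'   `identity`, `n_anchors`. Attribute `"split"` lists contigs with >= 2
#'   blocks.
#' @export
align_contigs <- function(contigs, reference, k = 31, min_block = 200,
                          band = 100) {
  stopifnot(k %% 2 == 1, k >= 11, k <= 63)
  refseq <- if (inherits(reference, "finished_sequence")) reference$seq else reference
  if (nchar(refseq) < k) stopf("reference (%d bp) is shorter than k = %d", nchar(refseq), k)
  ctg <- .as_contig_set(contigs)
  if (length(ctg) == 0) stopf("no contigs supplied")

  ref_km <- .kmers(refseq, k)
  dup <- duplicated(ref_km) | duplicated(ref_km, fromLast = TRUE)
  ref_km[dup] <- NA_character_

  out <- list()
  for (nm in names(ctg)) {
    cseq <- ctg[[nm]]
    blocks <- rbind(
      .strand_blocks(cseq, refseq, ref_km, k, band, "+"),
      .strand_blocks(cseq, refseq, ref_km, k, band, "-"))
    if (!is.null(blocks) && nrow(blocks) > 0) {
      blocks <- blocks[blocks$end - blocks$start >= min_block, , drop = FALSE]
      if (nrow(blocks) > 0) {
        blocks$contig_id <- nm
        out[[nm]] <- blocks
      }
    }
  }
  if (length(out) == 0) {
    res <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), qstart = integer(0), qend = integer(0),
                      strand = character(0), identity = numeric(0),
                      n_anchors = integer(0))
  } else {
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    res <- res[, c("contig_id", "start", "end", "qstart", "qend", "strand",
                   "identity", "n_anchors")]
    res <- res[order(res$contig_id, res$start), , drop = FALSE]
    rownames(res) <- NULL
  }
  counts <- table(res$contig_id)
  attr(res, "split") <- names(counts)[counts >= 2]
  res
}

.as_contig_set <- function(contigs) {
  if (inherits(contigs, "draft_assembly")) contigs <- contigs$contigs
  if (is.data.frame(contigs)) {
    stats::setNames(as.list(contigs$seq), contigs$contig_id)
  } else if (is.character(contigs)) {
    if (is.null(names(contigs))) names(contigs) <- sprintf("ctg%03d", seq_along(contigs))
    as.list(contigs)
  } else {
    stopf("unsupported contig container: %s", class(contigs)[1])
  }
}

.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

# Anchor-and-chain one orientation of a contig. For strand "-" the contig is
# reverse-complemented, blocks are computed in that frame, and contig
# coordinates are flipped back on output.
.strand_blocks <- function(cseq, refseq, ref_km_masked, k, band, strand) {
  work <- if (strand == "-") revcomp(cseq) else cseq
  km <- .kmers(work, k)
  if (length(km) == 0) return(NULL)
  dupc <- duplicated(km) | duplicated(km, fromLast = TRUE)
  m <- match(km, ref_km_masked)
  sel <- which(!dupc & !is.na(m))
  if (length(sel) == 0) return(NULL)
  qpos <- sel            # 1-based on `work`
  rpos <- m[sel]         # 1-based on reference
  d <- rpos - qpos
  ord <- order(d, qpos)
  qpos <- qpos[ord]; rpos <- rpos[ord]; d <- d[ord]
  grp <- cumsum(c(TRUE, diff(d) > band))

  clen <- nchar(cseq)
  rows <- lapply(split(seq_along(grp), grp), function(ix) {
    q1 <- min(qpos[ix]); q2 <- max(qpos[ix]) + k - 1  # 1-based inclusive
    r1 <- min(rpos[ix]); r2 <- max(rpos[ix]) + k - 1
    ext <- .extend_exact(work, refseq, q1, q2, r1, r2)
    q1 <- ext[1]; q2 <- ext[2]; r1 <- ext[3]; r2 <- ext[4]
    ident <- .span_identity(work, refseq, q1, q2, r1, r2)
    if (strand == "+") {
      qs <- q1 - 1L; qe <- q2
    } else {
      qs <- clen - q2; qe <- clen - q1 + 1L
    }
    data.frame(start = r1 - 1L, end = r2, qstart = as.integer(qs),
               qend = as.integer(qe), strand = strand, identity = ident,
               n_anchors = length(ix), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.raw_eq <- function(a, b) charToRaw(a) == charToRaw(b)

# Extend an anchored block outward while query and reference match exactly
# (interior mismatches between anchors are tolerated and scored by identity).
.extend_exact <- function(qseq, rseq, q1, q2, r1, r2) {
  avail <- min(q1 - 1L, r1 - 1L)
  if (avail > 0) {
    eq <- .raw_eq(substr(qseq, q1 - avail, q1 - 1L),
                  substr(rseq, r1 - avail, r1 - 1L))
    ext <- match(FALSE, rev(eq), nomatch = avail + 1L) - 1L
    q1 <- q1 - ext; r1 <- r1 - ext
  }
  avail <- min(nchar(qseq) - q2, nchar(rseq) - r2)
  if (avail > 0) {
    eq <- .raw_eq(substr(qseq, q2 + 1L, q2 + avail),
                  substr(rseq, r2 + 1L, r2 + avail))
    ext <- match(FALSE, eq, nomatch = avail + 1L) - 1L
    q2 <- q2 + ext; r2 <- r2 + ext
  }
  c(q1, q2, r1, r2)
}

.span_identity <- function(qseq, rseq, q1, q2, r1, r2) {
  w <- min(q2 - q1, r2 - r1) + 1L
  mean(.raw_eq(substr(qseq, q1, q1 + w - 1L), substr(rseq, r1, r1 + w - 1L)))
}
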