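# Interchange formats. Coordinates in TSV/BED files are 0-based half-open.

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings. `write_fasta()` accepts a
#' `finished_sequence`, a `draft_assembly` (contigs), a named character
#' vector, or a `data.frame(contig_id|id, seq)`.
#'
#' @param x Sequences to write.
#' @param path File path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "finished_sequence")) {
    set <- Biostrings::DNAStringSet(stats::setNames(x$seq, x$id))
  } else if (inherits(x, "draft_assembly")) {
    set <- Biostrings::DNAStringSet(stats::setNames(x$contigs$seq, x$contigs$contig_id))
  } else if (is.data.frame(x)) {
    ids <- x[["contig_id"]] %||% x[["id"]]
    set <- Biostrings::DNAStringSet(stats::setNames(x$seq, ids))
  } else {
    set <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

.PLACEMENT_COLS <- c("read_id", "subclone_id", "seq_id", "start", "end",
                     "strand", "mate_id", "library_id")

#' Read-placement TSV (8 columns, 0-based half-open)
#'
#' Columns: `read_id, subclone_id, seq_id, start, end, strand, mate_id,
#' library_id`.
#' @param x A `read_pairs` object or placement `data.frame`.
#' @param path File path.
#' @export
write_placements <- function(x, path) {
  df <- if (inherits(x, "read_pairs")) x$pairs else x
  utils::write.table(df[, .PLACEMENT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(.PLACEMENT_COLS, names(df))
  if (length(miss)) stopf("placement TSV lacks columns: %s", paste(miss, collapse = ", "))
  df$role <- ifelse(grepl("\\.f$", df$read_id), "fwd",
                    ifelse(grepl("\\.r$", df$read_id), "rev", NA_character_))
  df
}

#' Write a gap catalogue as BED and TSV
#'
#' BED columns: sequence, start, end, name = capture status, score = number
#' of qualifying spanning subclones.
#' @param gaps Gap `data.frame`.
#' @param path File path.
#' @export
write_gaps_bed <- function(gaps, path) {
  bed <- data.frame(gaps$sequence_id, gaps$start, gaps$end, gaps$status,
                    ifelse(is.na(gaps$spanning_subclones), 0L, gaps$spanning_subclones))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gaps_bed
#' @export
write_gaps_tsv <- function(gaps, path) {
  utils::write.table(gaps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a contig map as TSV and BED
#'
#' @param map A `contig_map`.
#' @param path File path.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(map$placements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
write_map_bed <- function(map, path) {
  pl <- map$placements
  bed <- data.frame(map$sequence_id, pl$start, pl$end, pl$contig_id,
                    round(1000 * pl$identity), pl$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Repeat annotation IO
#'
#' `read_repeatmasker_out()` parses the whitespace-delimited RepeatMasker
#' `.out` dialect (two header lines plus an optional blank line), returning
#' 0-based half-open intervals with the class collapsed to the assay's
#' Simple/LTR/SINE/LINE/DNA set; other classes (Low_complexity, Satellite,
#' rRNA, Unknown, ...) are returned as `Other`.
#'
#' @param path File path.
#' @return `data.frame(start, end, class, name, sequence_id)`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0), name = character(0),
                      sequence_id = character(0)))
  }
  fields <- strsplit(lines, "\\s+")
  getf <- function(i) vapply(fields, `[`, character(1), i)
  cls_raw <- getf(11)
  cls_base <- sub("/.*$", "", cls_raw)
  cls <- ifelse(cls_base == "Simple_repeat", "Simple",
         ifelse(cls_base %in% c("LINE", "SINE", "LTR", "DNA"), cls_base, "Other"))
  data.frame(start = as.integer(getf(6)) - 1L,   # .out is 1-based inclusive
             end = as.integer(getf(7)),
             class = cls, name = getf(10), sequence_id = getf(5),
             stringsAsFactors = FALSE)
}

#' @rdname read_repeatmasker_out
#' @param annotation `data.frame(start, end, class)`.
#' @param sequence_id Sequence name written into the file.
#' @export
write_repeatmasker_out <- function(annotation, sequence_id, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  cls_out <- ifelse(annotation$class == "Simple", "Simple_repeat", annotation$class)
  body <- sprintf("%5d %5.1f %4.1f %4.1f  %s %8d %8d (%d) + %s %s %d %d (0) %d",
                  1000L, 0, 0, 0, sequence_id,
                  annotation$start + 1L, annotation$end, 0L,
                  paste0("synthetic_", annotation$class),
                  cls_out, 1L, annotation$end - annotation$start,
                  seq_len(nrow(annotation)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname read_repeatmasker_out
#' @export
write_annotation_bed <- function(annotation, sequence_id, path) {
  bed <- data.frame(sequence_id, annotation$start, annotation$end,
                    annotation$class)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BAC manifest TSV
#'
#' Expected columns: `bac_id, species, region, finished_length`, plus
#' optional `draft_path`, `placement_path`, or a pre-aggregated `n_bacs`
#' count column.
#' @param path File path.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!any(c("species", "region") %in% names(df))) {
    stopf("manifest needs a species or region column")
  }
  df
}
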