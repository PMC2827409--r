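#' Cloning-bias model for shotgun subclone viability
#'
#' Models regions of the template that are deleterious ("poisonous") to the
#' bacterial host: a subclone whose insert overlaps such a region is only
#' accepted into the library with probability equal to the region's
#' viability. Under a copy-control host, part of the viability depression is
#' removed: `v' = v + copy_control_rescue * (1 - v)`.
#'
#' @param regions `data.frame(start, end, viability)` (0-based half-open;
#'   viability in \[0, 1\]). NULL or zero rows means no bias.
#' @param host `"standard"` or `"copy_control"`.
#' @param copy_control_rescue Fraction of the viability depression removed
#'   under the copy-control host, in \[0, 1\].
#' @return A `bias_model` list.
#' @export
bias_model <- function(regions = NULL, host = c("standard", "copy_control"),
                       copy_control_rescue = 1) {
  host <- match.arg(host)
  if (is.null(regions)) {
    regions <- data.frame(start = integer(0), end = integer(0),
                          viability = numeric(0))
  }
  stopifnot(all(c("start", "end", "viability") %in% names(regions)),
            all(regions$viability >= 0 & regions$viability <= 1),
            all(regions$start < regions$end),
            copy_control_rescue >= 0, copy_control_rescue <= 1)
  structure(list(regions = regions, host = host,
                 copy_control_rescue = copy_control_rescue),
            class = "bias_model")
}

# Effective per-region viability under the model's host.
.effective_viability <- function(bias) {
  v <- bias$regions$viability
  if (bias$host == "copy_control") v <- v + bias$copy_control_rescue * (1 - v)
  v
}

# Viability of candidate subclone intervals [s, e) on a circular template of
# size G: the minimum effective viability over all bias regions overlapped
# (1 outside all regions).
.candidate_viability <- function(s, e, G, bias) {
  v <- rep(1, length(s))
  if (is.null(bias) || nrow(bias$regions) == 0) return(v)
  veff <- .effective_viability(bias)
  p1s <- pmax(s, 0); p1e <- pmin(e, G)
  p2s <- ifelse(s < 0, s + G, ifelse(e > G, 0, NA))
  p2e <- ifelse(s < 0, G, ifelse(e > G, e - G, NA))
  for (i in seq_len(nrow(bias$regions))) {
    rs <- bias$regions$start[i]; re <- bias$regions$end[i]
    hit <- (p1s < re & p1e > rs) |
      (!is.na(p2s) & p2s < re & p2e > rs)
    v[hit] <- pmin(v[hit], veff[i])
  }
  v
}

.trunc_norm <- function(n, mean, sd, lo) {
  if (sd == 0) return(rep(max(mean, lo), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), 1)
  pmax(lo, round(stats::qnorm(u, mean, sd)))
}

# Emit placement rows for reads on a circular template, splitting a read
# that crosses the linear origin into two clipped rows with the same read_id.
.read_rows <- function(read_id, subclone_id, mate_id, seq_id, a, L, strand,
                       library_id, role, G) {
  a <- a %% G
  b <- a + L
  wraps <- b > G
  rows <- data.frame(
    read_id = read_id, subclone_id = subclone_id, seq_id = seq_id,
    start = as.integer(a), end = as.integer(pmin(b, G)), strand = strand,
    mate_id = mate_id, library_id = library_id, role = role,
    stringsAsFactors = FALSE)
  if (any(wraps)) {
    extra <- rows[wraps, , drop = FALSE]
    extra$start <- 0L
    extra$end <- as.integer(b[wraps] - G)
    rows <- rbind(rows, extra)
  }
  rows
}

#' Simulate a paired-end shotgun library over a finished reference
#'
#' Draws plasmid subclones uniformly from the (circular) template, subject to
#' the cloning-bias model, and emits the true reference placements of the
#' paired forward- and reverse-primed reads from each insert end. The number
#' of read pairs is `round(redundancy * length / (2 * read_len))`; rejected
#' subclones (cloning bias) are resampled so this count is always reached,
#' mirroring a production pipeline that sequences a fixed number of grown
#' clones.
#'
#' @param ref A `finished_sequence`, or an integer template length.
#' @param redundancy Target fold sequence redundancy (> 0).
#' @param read_len Read length in bp (< insert_mean).
#' @param insert_mean,insert_sd Subclone insert-size distribution (normal,
#'   truncated at `read_len + 1`).
#' @param bias Optional [bias_model()].
#' @param seed Optional integer seed.
#' @return A `read_pairs` list: `pairs` (placement `data.frame` with columns
#'   `read_id, subclone_id, seq_id, start, end, strand, mate_id, library_id,
#'   role`; 0-based half-open; a read crossing the circular origin appears as
#'   two clipped rows), `library` (insert/read-length stats), `n_pairs`,
#'   `host`.
#' @export
simulate_shotgun <- function(ref, redundancy = 8, read_len = 800,
                             insert_mean = 4000, insert_sd = 400,
                             bias = NULL, seed = NULL) {
  G <- if (inherits(ref, "finished_sequence")) ref$length else as.integer(ref)
  seq_id <- if (inherits(ref, "finished_sequence")) ref$id else "ref"
  stopifnot(redundancy > 0, read_len < insert_mean, insert_sd >= 0,
            insert_mean < G)
  n_pairs <- round(redundancy * G / (2 * read_len))
  if (n_pairs < 1) {
    stopf("redundancy %.3g over %d bp at read length %d yields < 1 read pair",
          redundancy, G, read_len)
  }
  with_seed_if(seed, {
    sub_s <- integer(0); sub_e <- integer(0)
    rounds <- 0L
    while (length(sub_s) < n_pairs) {
      rounds <- rounds + 1L
      if (rounds > 10000L) {
        stopf("could not draw %d viable subclones: bias model leaves (almost) no viable template", n_pairs)
      }
      m <- n_pairs - length(sub_s)
      nb <- max(2L * m, 64L)
      ins <- .trunc_norm(nb, insert_mean, insert_sd, read_len + 1)
      mid <- sample.int(G, nb, replace = TRUE) - 1L
      s <- mid - ins %/% 2L
      e <- s + ins
      keep <- stats::runif(nb) < .candidate_viability(s, e, G, bias)
      sub_s <- c(sub_s, s[keep]); sub_e <- c(sub_e, e[keep])
    }
    sub_s <- sub_s[seq_len(n_pairs)]; sub_e <- sub_e[seq_len(n_pairs)]

    # Insert orientation is uniform: the forward-primed read sits on the
    # left end for half the subclones, the right end for the other half.
    flip <- stats::runif(n_pairs) < 0.5
    sc <- sprintf("sc%06d", seq_len(n_pairs))
    lib <- "lib1"
    left_role <- ifelse(flip, "rev", "fwd")
    right_role <- ifelse(flip, "fwd", "rev")
    left_id <- paste0(sc, ".", ifelse(flip, "r", "f"))
    right_id <- paste0(sc, ".", ifelse(flip, "f", "r"))
    rows <- rbind(
      .read_rows(left_id, sc, right_id, seq_id, sub_s, read_len, "+",
                 lib, left_role, G),
      .read_rows(right_id, sc, left_id, seq_id, sub_e - read_len,
                 read_len, "-", lib, right_role, G))
    rows <- rows[order(rows$start, rows$read_id), , drop = FALSE]
    rownames(rows) <- NULL
    structure(list(pairs = rows,
                   library = list(insert_mean = insert_mean,
                                  insert_sd = insert_sd, read_len = read_len),
                   n_pairs = n_pairs,
                   host = if (is.null(bias)) "standard" else bias$host),
              class = "read_pairs")
  })
}

#' Per-base depth and uncovered intervals from read placements
#'
#' @param pairs A `read_pairs` object or a placement `data.frame`.
#' @param length Template length in bp.
#' @param min_depth Bases with depth below this count as uncovered.
#' @return `coverage_gaps()`: `data.frame(start, end)` of maximal uncovered
#'   intervals in linear coordinates. `coverage_gap_count()`: the number of
#'   uncovered arcs, merging the two boundary-touching intervals when
#'   `circular = TRUE`.
#' @export
coverage_gaps <- function(pairs, length, min_depth = 1) {
  df <- if (inherits(pairs, "read_pairs")) pairs$pairs else pairs
  if (nrow(df) == 0) return(data.frame(start = 0L, end = as.integer(length)))
  cov <- IRanges::coverage(.ir(df$start, df$end), width = length)
  low <- IRanges::slice(cov, upper = min_depth - 1L, rangesOnly = TRUE)
  .from_ir(low)
}

#' @rdname coverage_gaps
#' @param circular Treat the template as circular when counting arcs.
#' @export
coverage_gap_count <- function(pairs, length, min_depth = 1, circular = TRUE) {
  g <- coverage_gaps(pairs, length, min_depth)
  n <- nrow(g)
  if (circular && n >= 2 && g$start[1] == 0 && g$end[n] == length) n <- n - 1L
  n
}

#' Lander-Waterman expected number of coverage gaps
#'
#' Classical random-coverage expectation: with `n_reads` reads of length
#' `read_len` on a template of `genome_length` bp (fold coverage
#' `c = n_reads * read_len / genome_length`), the expected number of
#' uncovered stretches is `n_reads * exp(-c)`.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length (bp).
#' @param genome_length Template length (bp).
#' @export
expected_lw_gaps <- function(n_reads, read_len, genome_length) {
  c0 <- n_reads * read_len / genome_length
  n_reads * exp(-c0)
}
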