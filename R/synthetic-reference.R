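#' Repeat classes recognized by the assay
#'
#' Interspersed classes follow the usual repeat-library nomenclature
#' (LINE/SINE/LTR/DNA); `Simple` covers homopolymer and di-/tri-/tetra-
#' nucleotide tandem repeats.
#' @export
REPEAT_CLASSES <- c("Simple", "LTR", "SINE", "LINE", "DNA")

.SIMPLE_MOTIFS <- list(
  `1` = c("A", "T", "C", "G"),
  `2` = c("AC", "AG", "AT", "CT"),
  `3` = c("AAT", "CAG", "AGG", "ACT"),
  `4` = c("AAAT", "AGAT", "ACAT", "AAAC")
)

#' Draw a random repeat layout for a synthetic reference
#'
#' Produces one row per repeat instance to plant, with per-class densities
#' expressed as the target fraction of reference bases. Defaults emulate the
#' aggregate repeat content of vertebrate BAC sequence (roughly 1.6% simple,
#' 4.7% LTR, 9.3% SINE, 18.6% LINE, 2.7% DNA-transposon bases).
#'
#' @param length Reference length in bp.
#' @param densities Named numeric vector of target base fractions per class.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `class`, `length`, `start` (NA for
#'   random placement), `motif` (simple repeats only).
#' @export
repeat_layout <- function(length,
                          densities = c(Simple = 0.016, LTR = 0.047,
                                        SINE = 0.093, LINE = 0.186,
                                        DNA = 0.027),
                          seed = NULL) {
  stopifnot(all(names(densities) %in% REPEAT_CLASSES), all(densities >= 0))
  with_seed_if(seed, {
    rows <- list()
    for (cls in names(densities)) {
      target <- densities[[cls]] * length
      if (target <= 0) next
      lens <- switch(cls,
        Simple = 12L + stats::rgeom(ceiling(target / 45), 1 / 33),
        SINE   = pmax(80L, round(stats::rnorm(ceiling(target / 300), 300, 60))),
        LINE   = pmin(2500L, pmax(200L, round(stats::rlnorm(ceiling(target / 1000), log(800), 0.7)))),
        LTR    = pmax(150L, round(stats::rnorm(ceiling(target / 500), 500, 150))),
        DNA    = pmax(150L, round(stats::rnorm(ceiling(target / 600), 600, 200)))
      )
      lens <- lens[cumsum(lens) <= target | seq_along(lens) == 1L]
      motifs <- if (cls == "Simple") {
        sizes <- sample(c(1, 2, 3, 4), length(lens), replace = TRUE,
                        prob = c(0.35, 0.4, 0.1, 0.15))
        vapply(sizes, function(m) sample(.SIMPLE_MOTIFS[[as.character(m)]], 1),
               character(1))
      } else NA_character_
      rows[[cls]] <- data.frame(class = cls, length = as.integer(lens),
                                start = NA_integer_, motif = motifs,
                                stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) {
      data.frame(class = character(0), length = integer(0),
                 start = integer(0), motif = character(0))
    } else {
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    }
  })
}

# Place intervals without overlap: explicit starts first (validated), then
# random starts by rejection sampling against an occupancy mask.
.place_intervals <- function(length, widths, starts, label = "interval",
                             max_tries = 500L) {
  occ <- logical(length)
  out <- integer(base::length(widths))
  ord <- order(!is.na(starts), widths, decreasing = TRUE)
  ord <- c(which(!is.na(starts)), setdiff(ord, which(!is.na(starts))))
  for (i in ord) {
    w <- widths[i]
    if (w > length) {
      stopf("configured %s of %d bp exceeds reference length %d", label, w, length)
    }
    if (!is.na(starts[i])) {
      s <- starts[i]
      if (s < 0 || s + w > length) {
        stopf("%s at %d (+%d bp) lies outside the reference [0, %d)", label, s, w, length)
      }
      if (any(occ[(s + 1):(s + w)])) {
        stopf("%s at %d (+%d bp) overlaps a previously placed interval", label, s, w)
      }
    } else {
      s <- NA_integer_
      for (try in seq_len(max_tries)) {
        cand <- sample.int(length - w + 1L, 1L) - 1L
        if (!any(occ[(cand + 1):(cand + w)])) { s <- cand; break }
      }
      if (is.na(s)) {
        stopf("could not place %s of %d bp: reference too crowded (total planted span exceeds capacity?)", label, w)
      }
    }
    occ[(s + 1):(s + w)] <- TRUE
    out[i] <- s
  }
  out
}

.simple_tract <- function(motif, len) {
  substr(strrep(motif, ceiling(len / nchar(motif))), 1, len)
}

# Mutate a fraction of positions to a different base (used to diverge
# interspersed repeat copies from their class consensus).
.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(.BASES, b), 1), character(1))
    seq <- paste(chars, collapse = "")
  }
  seq
}

#' Generate a synthetic finished reference sequence
#'
#' Builds a BAC-sized reference with planted simple and interspersed repeats
#' and optional GC-rich islands on an i.i.d. background, returning both the
#' sequence and the ground-truth repeat annotation. Interspersed repeat
#' instances are copies of a per-class consensus, each diverged by
#' `divergence` substitutions, so copies resemble a real repeat family rather
#' than exact duplicates.
#'
#' @param length Reference length in bp (>= 1000).
#' @param gc_target Background GC fraction in (0, 1).
#' @param repeats `data.frame(class, length, start, motif)` as produced by
#'   [repeat_layout()]; `start = NA` requests random non-overlapping
#'   placement. NULL plants nothing.
#' @param gc_islands `data.frame(length, gc, start)`; `start = NA` random.
#' @param divergence Per-base substitution rate applied to each interspersed
#'   repeat copy relative to its class consensus.
#' @param id,species,region Metadata recorded on the reference.
#' @param seed Optional integer seed; identical inputs and seed give
#'   byte-identical output.
#' @return List with elements `reference` (a `finished_sequence`: `id`,
#'   `species`, `region`, `seq`, `length`) and `annotation`
#'   (`data.frame(start, end, class)`, 0-based half-open, disjoint, sorted).
#' @export
generate_reference <- function(length, gc_target = 0.4, repeats = NULL,
                               gc_islands = NULL, divergence = 0.08,
                               id = "synthetic_ref", species = "synthetic",
                               region = "synthetic", seed = NULL) {
  stopifnot(length >= 1000, gc_target > 0, gc_target < 1)
  with_seed_if(seed, {
    chars <- sample(.BASES, length, replace = TRUE,
                    prob = c((1 - gc_target) / 2, gc_target / 2,
                             gc_target / 2, (1 - gc_target) / 2))

    n_rep <- if (is.null(repeats)) 0L else nrow(repeats)
    n_isl <- if (is.null(gc_islands)) 0L else nrow(gc_islands)
    widths <- c(if (n_rep) as.integer(repeats$length),
                if (n_isl) as.integer(gc_islands$length))
    starts <- c(if (n_rep) as.integer(repeats$start),
                if (n_isl) as.integer(gc_islands$start %||% rep(NA_integer_, n_isl)))
    if (n_rep + n_isl > 0) {
      if (sum(widths) >= length) {
        stopf("configured repeats/islands total %d bp, exceeding the %d bp reference",
              sum(widths), length)
      }
      pos <- .place_intervals(length, widths, starts)
    } else {
      pos <- integer(0)
    }

    ann <- data.frame(start = integer(0), end = integer(0), class = character(0))
    if (n_rep > 0) {
      consensus <- list()
      seqs <- character(n_rep)
      for (i in seq_len(n_rep)) {
        cls <- repeats$class[i]
        len <- as.integer(repeats$length[i])
        if (cls == "Simple") {
          motif <- repeats$motif[i]
          if (is.na(motif)) motif <- sample(.SIMPLE_MOTIFS[[sample(1:4, 1)]], 1)
          seqs[i] <- .simple_tract(motif, len)
        } else {
          if (is.null(consensus[[cls]]) || nchar(consensus[[cls]]) < len) {
            consensus[[cls]] <- random_dna(max(len, 2500L), gc_target)
          }
          seqs[i] <- .mutate_dna(substr(consensus[[cls]], 1, len), divergence)
        }
      }
      for (i in seq_len(n_rep)) {
        s <- pos[i]
        chars[(s + 1):(s + nchar(seqs[i]))] <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      }
      ann <- data.frame(start = pos[seq_len(n_rep)],
                        end = pos[seq_len(n_rep)] + as.integer(repeats$length),
                        class = repeats$class, stringsAsFactors = FALSE)
      ann <- ann[order(ann$start), , drop = FALSE]
      rownames(ann) <- NULL
    }
    if (n_isl > 0) {
      for (j in seq_len(n_isl)) {
        s <- pos[n_rep + j]
        w <- as.integer(gc_islands$length[j])
        isl <- random_dna(w, gc_islands$gc[j])
        chars[(s + 1):(s + w)] <- strsplit(isl, "", fixed = TRUE)[[1]]
      }
    }

    reference <- structure(
      list(id = id, species = species, region = region,
           seq = paste(chars, collapse = ""), length = as.integer(length)),
      class = "finished_sequence")
    list(reference = reference, annotation = ann)
  })
}

#' @export
print.finished_sequence <- function(x, ...) {
  cat(sprintf("<finished_sequence> %s (%s / %s), %d bp, GC %.3f\n",
              x$id, x$species, x$region, x$length, gc_content(x$seq)))
  invisible(x)
}
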