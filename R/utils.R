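# Internal helpers shared across modules.
#
# All genomic coordinates in this package are 0-based, half-open [start, end),
# matching BED. IRanges objects are 1-based closed; .ir()/.from_ir() convert.

.ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

.from_ir <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Run `expr` under `seed` without disturbing the caller's RNG stream; with
# seed = NULL the ambient stream is consumed (callers that loop over seeds
# pass explicit ones).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Draw a fresh sub-seed from the current stream (< 2^31).
next_seed <- function() sample.int(.Machine$integer.max, 1L)

.BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Merge possibly-overlapping 0-based half-open intervals into a sorted,
# disjoint set.
merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  .from_ir(IRanges::reduce(.ir(df$start, df$end)))
}

# Complement of `df` within [lo, hi); df need not be disjoint.
interval_complement <- function(df, lo, hi) {
  if (hi <= lo) return(data.frame(start = integer(0), end = integer(0)))
  if (is.null(df) || nrow(df) == 0) return(data.frame(start = lo, end = hi))
  gaps <- IRanges::setdiff(.ir(lo, hi), .ir(df$start, df$end))
  .from_ir(gaps)
}

# Total bases of `df` overlapping `win` (both 0-based half-open data frames).
interval_overlap_bases <- function(df, win) {
  if (nrow(df) == 0 || nrow(win) == 0) return(0L)
  sum(IRanges::width(IRanges::intersect(
    IRanges::reduce(.ir(df$start, df$end)),
    IRanges::reduce(.ir(win$start, win$end))
  )))
}

# Lower median: for even n the smaller of the two central order statistics.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
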