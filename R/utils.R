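# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats quantile rbinom runif sd setNames
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

utils::globalVariables(c("diag", "rpos", "qpos", "run", "chrom", "qstart",
                         "qend", "rstart", "rend", "len", "."))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sequences are handled as uppercase character scalars over {A,C,G,T,N};
# byte views (raw vectors) are used for random access and vectorised compares.
.seq_bytes <- function(s) charToRaw(s)

.bytes_seq <- function(b) rawToChar(b)

.BYTE_N <- charToRaw("N")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper; N maps to N.
#'
#' @param s character scalar over {A,C,G,T,N}
#' @return character scalar
#' @export
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  chartr("ACGTN", "TGCAN", .bytes_seq(rev(.seq_bytes(s))))
}

#' Random DNA sequence
#'
#' Uniform over A/C/G/T; used by the simulator (consumes the active RNG
#' stream, so callers control determinism through set.seed()).
#'
#' @param n length in nucleotides
#' @return character scalar of length n
#' @export
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate a DNA string at a fixed per-site rate (substitutions only).
.mutate_seq <- function(s, rate) {
  n <- nchar(s)
  if (n == 0L || rate <= 0) return(s)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(s)
  b <- .seq_bytes(s)
  bases <- charToRaw("ACGT")
  for (i in hit) {
    alt <- bases[bases != b[i]]
    b[i] <- alt[sample.int(3L, 1L)]
  }
  .bytes_seq(b)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# merge sorted-interval data.frame(start, end) into disjoint intervals
.merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

# total length of the union of [start, end] (closed) intervals
.interval_union_len <- function(start, end) {
  m <- .merge_intervals(start, end)
  sum(m$end - m$start + 1L)
}
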