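# Internal seed-and-extend alignment primitives.
#
# The aligner is anchor-based: exact k-mer seeds (default k = 15) are merged
# into maximal exact runs, colinear runs are chained by sparse dynamic
# programming, and the short regions between chained runs are resolved by
# affine-gap Needleman-Wunsch (Biostrings). Base-level correspondences are
# returned as integer maps (query position -> reference position, 0 where
# unaligned). This keeps the toolkit self-contained: no external alignment
# program is invoked.

# k-mers are handled as 2-bit integer codes (A=0, C=1, G=2, T=3, base-4
# Horner encoding), which keeps seeding free of string allocation; a window
# containing N encodes to NA and is dropped (N never counts as a match).
# Exact for k <= 15 (4^15 < 2^31 fits a double exactly).

.encode_bases <- function(s) {
  b <- .seq_bytes(s)
  code <- rep(NA_real_, length(b))
  code[b == charToRaw("A")] <- 0
  code[b == charToRaw("C")] <- 1
  code[b == charToRaw("G")] <- 2
  code[b == charToRaw("T")] <- 3
  code
}

# codes of all k-length windows starting at 1..(n-k+1); NA where the window
# contains a non-ACGT symbol
.kmer_codes <- function(s, k) {
  v <- .encode_bases(s)
  n <- length(v)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  out <- numeric(m)
  for (j in seq_len(k)) out <- out * 4 + v[j:(m + j - 1L)]
  out
}

# k-mer index of a set of reference chromosomes:
# data.table(kmer (code), chrom (int), pos), keyed by kmer
.kmer_index <- function(sequences, k) {
  tabs <- lapply(seq_along(sequences), function(ci) {
    km <- .kmer_codes(sequences[[ci]], k)
    keep <- !is.na(km)
    data.table::data.table(kmer = km[keep], chrom = ci,
                           pos = seq_along(km)[keep])
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  idx
}

# exact k-mer matches of a query sequence against an index:
# data.table(qpos, chrom, rpos); `qk` may be precomputed .kmer_codes(qseq, k)
.seed_hits <- function(qseq, index, k, qk = NULL) {
  if (is.null(qk)) qk <- .kmer_codes(qseq, k)
  keep <- !is.na(qk)
  if (!any(keep))
    return(data.table::data.table(qpos = integer(0), chrom = integer(0),
                                  rpos = integer(0)))
  qdt <- data.table::data.table(kmer = qk[keep], qpos = seq_along(qk)[keep])
  hits <- index[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  data.table::data.table(qpos = hits$qpos, chrom = hits$chrom, rpos = hits$pos)
}

# merge same-diagonal consecutive seeds into maximal exact runs
# returns data.table(chrom, qstart, qend, rstart, rend, len)
.exact_runs <- function(seeds, k) {
  if (nrow(seeds) == 0L)
    return(data.table::data.table(chrom = integer(0), qstart = integer(0),
                                  qend = integer(0), rstart = integer(0),
                                  rend = integer(0), len = integer(0)))
  s <- data.table::copy(seeds)
  s[, diag := rpos - qpos]
  data.table::setorder(s, chrom, diag, qpos)
  brk <- c(TRUE, diff(s$qpos) != 1L | diff(s$diag) != 0L | diff(s$chrom) != 0L)
  s[, run := cumsum(brk)]
  runs <- s[, .(chrom = chrom[1L], qstart = qpos[1L], qend = qpos[.N] + k - 1L,
                rstart = rpos[1L], rend = rpos[.N] + k - 1L), by = run]
  runs[, len := qend - qstart + 1L]
  runs[, run := NULL]
  runs[]
}

# Sparse-DP chaining of exact runs (single reference chromosome assumed).
# Runs must be colinear (increasing in both q and r); overlaps up to the run
# length are tolerated and their length is not double-counted. `w` supplies
# per-run weights (defaults to run length); callers can up-weight runs in
# well-supported regions so repeat-induced pairings lose to orthologous
# ones. Returns the row indices of the best chain in q order.
.chain_runs <- function(runs, max_gap = 6000L, w = NULL) {
  m <- nrow(runs)
  if (m == 0L) return(integer(0))
  if (m == 1L) return(1L)
  if (is.null(w)) w <- as.numeric(runs$len)
  if (m > 3000L) {   # degenerate repeat soup: keep the heaviest runs
    keep <- sort(order(-w)[seq_len(3000L)])
    sub <- .chain_runs(runs[keep], max_gap, w[keep])
    return(keep[sub])
  }
  o <- order(runs$qstart, runs$rstart)
  qs <- runs$qstart[o]; qe <- runs$qend[o]
  rs <- runs$rstart[o]; re <- runs$rend[o]
  len <- runs$len[o]
  wo <- w[o]
  score <- wo
  prev <- integer(m)
  for (i in seq_len(m)) {
    if (i == 1L) next
    lo <- max(1L, i - 80L)  # bounded lookback keeps chaining near-linear
    for (j in (i - 1L):lo) {
      if (qs[j] >= qs[i] || rs[j] >= rs[i] || qe[j] >= qe[i] || re[j] >= re[i]) next
      qgap <- qs[i] - qe[j] - 1L
      rgap <- rs[i] - re[j] - 1L
      if (qgap > max_gap || rgap > max_gap) next
      ov <- max(0L, -qgap, -rgap)
      cand <- score[j] + wo[i] - ov * wo[i] / len[i] - 0.01 * max(qgap, rgap, 0L)
      if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
    }
  }
  best <- which.max(score)
  chain <- integer(0)
  i <- best
  while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
  o[chain]
}

# Align the short region between two chained runs.
# Returns list(map = integer vector length nchar(q) (0 = unaligned,
# values = positions in r), matches, mismatches).
# depth guards the recursion when large gaps are re-seeded.
.fill_region <- function(q, r, min_identity = 0.85, depth = 0L) {
  nq <- nchar(q); nr <- nchar(r)
  none <- list(map = integer(nq), matches = 0L, mismatches = 0L)
  if (nq == 0L || nr == 0L) return(none)
  guard <- function(mm, span) mm <= (1 - min_identity) * (span + 30L)
  if (nq == nr && nq <= 64L) {
    qb <- .seq_bytes(q); rb <- .seq_bytes(r)
    isN <- qb == .BYTE_N | rb == .BYTE_N
    eq <- qb == rb & !isN
    mm <- sum(!eq)
    if (!guard(mm, nq)) return(none)
    return(list(map = seq_len(nq), matches = sum(eq), mismatches = mm))
  }
  if (as.double(nq) * nr <= 2.5e5) {
    pa <- Biostrings::pairwiseAlignment(
      q, r, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1.5, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 0.6)
    qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    qi <- cumsum(qa != "-"); ri <- cumsum(ra != "-")
    both <- qa != "-" & ra != "-"
    isN <- qa == "N" | ra == "N"
    match <- both & qa == ra & !isN
    mm <- sum(both) - sum(match)
    if (!guard(mm, max(nq, nr))) return(none)
    map <- integer(nq)
    map[qi[both]] <- ri[both]
    return(list(map = map, matches = sum(match), mismatches = mm))
  }
  # larger gaps are re-seeded rather than fed to dense DP, so divergent
  # blocks (e.g. satellite arrays) cost little and stay unaligned
  if (depth >= 3L) return(none)
  fa <- fine_align(q, r, k = 13L, max_gap = 20000L,
                   min_identity = min_identity, depth = depth + 1L)
  list(map = fa$map, matches = fa$matches, mismatches = fa$mismatches)
}

#' Base-level local alignment of two sequences by seed, chain and fill
#'
#' Finds the best colinear chain of exact k-mer runs between \code{q} and
#' \code{r} and resolves the gaps between chained runs with affine-gap
#' dynamic programming. Gap fills whose mismatch load exceeds
#' \code{1 - min_identity} of the gap span are rejected (their positions stay
#' unaligned), so divergent intervening sequence never enters the map.
#'
#' @param q,r query and reference sequence (character scalars)
#' @param k seed length
#' @param max_gap largest within-chain gap (nt) in either sequence
#' @param min_identity identity floor applied to gap fills
#' @param depth internal recursion depth
#' @param r_support optional logical vector over reference positions marking
#'   well-supported (e.g. consensus) regions; runs mostly inside supported
#'   regions are strongly preferred during chaining
#' @return list with \code{map} (integer vector over query positions; 0 =
#'   unaligned), \code{matches}, \code{mismatches}, \code{n_aligned},
#'   \code{identity}, \code{score}, and the chained span bounds
#'   \code{qstart}, \code{qend}, \code{rstart}, \code{rend}
#' @export
fine_align <- function(q, r, k = 15L, max_gap = 6000L, min_identity = 0.85,
                       depth = 0L, r_support = NULL) {
  nq <- nchar(q)
  empty <- list(map = integer(nq), matches = 0L, mismatches = 0L,
                n_aligned = 0L, identity = NA_real_, score = -Inf,
                qstart = NA_integer_, qend = NA_integer_,
                rstart = NA_integer_, rend = NA_integer_)
  if (nq < k || nchar(r) < k) return(empty)
  idx <- .kmer_index(list(r), k)
  seeds <- .seed_hits(q, idx, k)
  runs <- .exact_runs(seeds, k)
  if (nrow(runs) == 0L) return(empty)
  w <- NULL
  if (!is.null(r_support)) {
    cs <- cumsum(c(0L, r_support))
    frac <- (cs[pmin(runs$rend, length(r_support)) + 1L] - cs[runs$rstart]) /
      runs$len
    w <- as.numeric(runs$len) * ifelse(frac > 0.5, 10, 1)
  }
  chain <- .chain_runs(runs, max_gap, w = w)
  .map_from_chain(q, r, runs[chain], min_identity, depth)
}

# Build the base-level map from a chain of exact runs, filling inter-run gaps.
.map_from_chain <- function(q, r, cruns, min_identity, depth = 0L) {
  nq <- nchar(q)
  map <- integer(nq)
  matches <- 0L; mismatches <- 0L; gaps <- 0L; opens <- 0L
  m <- nrow(cruns)
  # trim overlaps between consecutive runs
  qs <- cruns$qstart; qe <- cruns$qend; rs <- cruns$rstart; re <- cruns$rend
  for (i in seq_len(m)) {
    if (i > 1L) {
      ov <- max(0L, qe[i - 1L] - qs[i] + 1L, re[i - 1L] - rs[i] + 1L)
      if (ov > 0L) { qs[i] <- qs[i] + ov; rs[i] <- rs[i] + ov }
      if (qs[i] > qe[i] || rs[i] > re[i]) next
    }
    map[qs[i]:qe[i]] <- rs[i]:re[i]
    matches <- matches + (qe[i] - qs[i] + 1L)
  }
  for (i in seq_len(m - 1L)) {
    qgs <- qe[i] + 1L; qge <- qs[i + 1L] - 1L
    rgs <- re[i] + 1L; rge <- rs[i + 1L] - 1L
    nqg <- qge - qgs + 1L; nrg <- rge - rgs + 1L
    if (nqg < 0L || nrg < 0L) next
    if (nqg != nrg) { opens <- opens + 1L; gaps <- gaps + abs(nqg - nrg) }
    if (nqg == 0L || nrg == 0L) next
    f <- .fill_region(substring(q, qgs, qge), substring(r, rgs, rge),
                      min_identity, depth)
    hit <- f$map > 0L
    map[qgs:qge][hit] <- f$map[hit] + rgs - 1L
    matches <- matches + f$matches
    mismatches <- mismatches + f$mismatches
  }
  n_aligned <- sum(map > 0L)
  ident <- if (matches + mismatches > 0L) matches / (matches + mismatches) else NA_real_
  list(map = map, matches = matches, mismatches = mismatches,
       n_aligned = n_aligned, identity = ident,
       score = matches - mismatches - 0.5 * gaps - 2 * opens,
       qstart = qs[1L], qend = qe[m], rstart = rs[1L], rend = re[m])
}
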