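# Pairwise genome correspondence: block anchoring, proximity chaining and
# gap filling. The query genome is divided into 5-kb blocks, each block gets
# at most one best local hit on the reference, hits that are not in close
# proximity to a colinear neighbour in both genomes are removed, and the
# sequence between consecutive kept hits is aligned by a second local-search
# pass.

#' Divide a genome into consecutive anchor blocks
#'
#' Blocks are consecutive and non-overlapping; a final partial block shorter
#' than 100 nt is merged into the previous block.
#'
#' @param genome a \code{genome_set}
#' @param block_size block length in nt (>= 100)
#' @return data.frame with columns chrom, block_id, start, end (1-based
#'   closed), seq
#' @export
chop_blocks <- function(genome, block_size = 5000L) {
  if (block_size < 100L) .stopf("block_size must be >= 100")
  out <- list()
  bid <- 0L
  for (chrom in names(genome$sequences)) {
    L <- nchar(genome$sequences[[chrom]])
    starts <- seq.int(1L, L, by = block_size)
    ends <- pmin(starts + block_size - 1L, L)
    nb <- length(starts)
    if (nb > 1L && (ends[nb] - starts[nb] + 1L) < 100L) {
      ends[nb - 1L] <- ends[nb]
      starts <- starts[-nb]; ends <- ends[-nb]
      nb <- nb - 1L
    }
    out[[chrom]] <- data.frame(
      chrom = chrom, block_id = bid + seq_len(nb), start = starts, end = ends,
      seq = substring(genome$sequences[[chrom]], starts, ends),
      stringsAsFactors = FALSE)
    bid <- bid + nb
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Anchor blocks on a reference genome
#'
#' Each block is aligned to the reference with the internal seed-and-extend
#' aligner and at most the single best-scoring local hit is retained. Ties
#' are broken towards the lower reference chromosome index, then the lower
#' reference start. Hits below \code{min_identity} or shorter than
#' \code{min_hit_len} aligned positions are discarded (those blocks simply
#' have no hit). Minus-strand hits are detected but carry no base-level map.
#'
#' @param blocks data.frame from \code{\link{chop_blocks}}
#' @param reference a \code{genome_set}
#' @param min_identity minimum hit identity (matches over aligned pairs)
#' @param min_hit_len minimum aligned length (nt)
#' @param k seed length
#' @return object of class \code{anchor_hits}: data.frame of hits with the
#'   per-hit base maps in attribute \code{maps} (plus ref chromosome names in
#'   \code{ref_chroms})
#' @export
anchor_blocks <- function(blocks, reference, min_identity = 0.85,
                          min_hit_len = 100L, k = 15L) {
  if (sum(nchar(reference$sequences)) == 0L) .stopf("reference is empty")
  ridx <- .kmer_index(reference$sequences, k)
  .anchor_blocks_idx(blocks, ridx, reference$sequences,
                     min_identity, min_hit_len, k)
}

# anchor_blocks against a prebuilt reference index (reused across queries);
# ref_seqs is the named list/vector of reference chromosome sequences in the
# order the index was built with
.anchor_blocks_idx <- function(blocks, ridx, ref_seqs, min_identity,
                               min_hit_len, k, qkmer_cache = NULL) {
  ref_chroms <- names(ref_seqs)
  hits <- list(); maps <- list()
  for (chrom in unique(blocks$chrom)) {
    bl <- blocks[blocks$chrom == chrom, , drop = FALSE]
    qseq <- paste(bl$seq, collapse = "")
    Lc <- nchar(qseq)
    qk_fwd <- if (!is.null(qkmer_cache)) qkmer_cache[[chrom]]$fwd else NULL
    qk_rev <- if (!is.null(qkmer_cache)) qkmer_cache[[chrom]]$rev else NULL
    seeds_f <- .seed_hits(qseq, ridx, k, qk = qk_fwd)
    runs_f <- .exact_runs(seeds_f, k)
    rcseq <- revcomp(qseq)
    seeds_r <- .seed_hits(rcseq, ridx, k, qk = qk_rev)
    runs_r <- .exact_runs(seeds_r, k)

    # clip a run table to a query window (runs may span block boundaries)
    clip_runs <- function(ru, lo, hi) {
      ru <- ru[ru$qend >= lo & ru$qstart <= hi, ]
      if (nrow(ru)) {
        dl <- pmax(0L, lo - ru$qstart)
        dr <- pmax(0L, ru$qend - hi)
        ru[, `:=`(qstart = qstart + dl, rstart = rstart + dl,
                  qend = qend - dr, rend = rend - dr)]
        ru[, len := qend - qstart + 1L]
        ru <- ru[ru$len > 0L, ]
      }
      ru
    }
    for (bi in seq_len(nrow(bl))) {
      bs <- bl$start[bi]; be <- bl$end[bi]
      rf <- clip_runs(data.table::copy(runs_f), bs, be)
      rs_lo <- Lc - be + 1L; rs_hi <- Lc - bs + 1L
      rr <- clip_runs(data.table::copy(runs_r), rs_lo, rs_hi)
      best <- NULL
      for (strand in c("+", "-")) {
        ru <- if (strand == "+") rf else rr
        if (nrow(ru) == 0L) next
        sseq <- if (strand == "+") qseq else rcseq
        soff <- if (strand == "+") c(bs, be) else c(rs_lo, rs_hi)
        qloc <- substring(sseq, soff[1L], soff[2L])
        cand <- .block_candidates(ru)
        for (ci in cand) {
          cr <- ru[ci, ]
          rchrom <- cr$chrom[1L]
          cr2 <- data.table::copy(cr)
          cr2[, `:=`(qstart = qstart - soff[1L] + 1L, qend = qend - soff[1L] + 1L)]
          chain <- .chain_runs(cr2)
          cr2 <- cr2[chain, ]
          res <- .map_from_chain(qloc, ref_seqs[[rchrom]], cr2, min_identity)
          if (is.null(res) || res$n_aligned == 0L) next
          hit <- list(strand = strand, rchrom = rchrom, res = res,
                      qoff = soff[1L])
          if (is.null(best) || res$score > best$res$score ||
              (res$score == best$res$score &&
                 (hit$rchrom < best$rchrom ||
                    (hit$rchrom == best$rchrom && res$rstart < best$res$rstart)))) {
            best <- hit
          }
        }
      }
      if (is.null(best)) next
      res <- best$res
      if (is.na(res$identity) || res$identity < min_identity) next
      if (res$n_aligned < min_hit_len) next
      # convert to absolute query coordinates (original strand)
      if (best$strand == "+") {
        hqs <- res$qstart + best$qoff - 1L
        hqe <- res$qend + best$qoff - 1L
        amap <- res$map[res$qstart:res$qend]  # absolute reference positions
      } else {
        # positions were in revcomp space; map back
        hqe <- Lc - (res$qstart + best$qoff - 1L) + 1L
        hqs <- Lc - (res$qend + best$qoff - 1L) + 1L
        amap <- NULL  # inverted hits carry no base-level correspondence
      }
      hits[[length(hits) + 1L]] <- data.frame(
        block_id = bl$block_id[bi], qchrom = chrom,
        block_start = bs, block_end = be,
        qstart = hqs, qend = hqe,
        rchrom_id = best$rchrom, rchrom = ref_chroms[best$rchrom],
        rstart = res$rstart, rend = res$rend, strand = best$strand,
        identity = res$identity, score = res$score,
        n_aligned = res$n_aligned, stringsAsFactors = FALSE)
      maps[[as.character(bl$block_id[bi])]] <- amap
    }
  }
  df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(block_id = integer(0), qchrom = character(0),
               block_start = integer(0), block_end = integer(0),
               qstart = integer(0), qend = integer(0), rchrom_id = integer(0),
               rchrom = character(0), rstart = integer(0), rend = integer(0),
               strand = character(0), identity = numeric(0), score = numeric(0),
               n_aligned = integer(0))
  rownames(df) <- NULL
  structure(df, maps = maps, ref_chroms = ref_chroms, class = c("anchor_hits", "data.frame"))
}

# candidate run clusters within a block: split on reference chromosome or a
# reference-coordinate jump; keep clusters whose total run length is at least
# half the best, capped at 8, ordered by (chrom, rstart) so ties resolve
# deterministically
.block_candidates <- function(runs, max_span_gap = 12000L, cap = 8L) {
  o <- order(runs$chrom, runs$rstart)
  ch <- runs$chrom[o]; rst <- runs$rstart[o]
  brk <- c(TRUE, diff(ch) != 0L | diff(rst) > max_span_gap)
  grp <- cumsum(brk)
  idx <- split(o, grp)
  tot <- vapply(idx, function(i) sum(runs$len[i]), numeric(1))
  keep <- which(tot >= 0.5 * max(tot))
  ord <- order(vapply(idx[keep], function(i) min(runs$chrom[i]) * 1e9 + min(runs$rstart[i]),
                      numeric(1)))
  keep <- keep[ord]
  if (length(keep) > cap) keep <- keep[seq_len(cap)]
  idx[keep]
}

#' Chain anchored hits and fill the gaps between them
#'
#' Keeps hits only when they are colinear with a neighbour on the same
#' reference chromosome and strand with gaps of at most \code{max_join_gap}
#' in both genomes; chains of a single hit are discarded (they are usually
#' repeat-induced off-diagonal anchors). The unaligned sequence between
#' consecutive kept hits is aligned by a second local-search pass and merged.
#' Minus-strand chains are reported in the \code{inversions} table and carry
#' no base-level correspondence.
#'
#' @param hits an \code{anchor_hits} object
#' @param query,reference the two \code{genome_set}s
#' @param max_join_gap proximity threshold (nt) in both genomes
#' @param min_identity identity floor for fill alignments
#' @return object of class \code{correspondence_map}: per query chromosome,
#'   integer vectors \code{ref_chrom_id} and \code{ref_pos} (0 = unmatched),
#'   plus \code{segments} and \code{inversions} tables
#' @export
chain_and_fill <- function(hits, query, reference, max_join_gap = 20000L,
                           min_identity = 0.85) {
  maps <- attr(hits, "maps")
  ref_chroms <- attr(hits, "ref_chroms") %||% names(reference$sequences)
  cm <- list()
  segments <- list(); inversions <- list()
  for (chrom in names(query$sequences)) {
    Lq <- nchar(query$sequences[[chrom]])
    ref_chrom_id <- integer(Lq); ref_pos <- integer(Lq)
    h <- hits[hits$qchrom == chrom, , drop = FALSE]
    if (nrow(h)) {
      h <- h[order(h$qstart), , drop = FALSE]
      colinear <- function(a, b) {
        if (a$rchrom_id != b$rchrom_id || a$strand != b$strand) return(FALSE)
        qgap <- b$qstart - a$qend - 1L
        if (qgap > max_join_gap) return(FALSE)
        if (a$strand == "+") {
          rgap <- b$rstart - a$rend - 1L
          rgap >= -200L && rgap <= max_join_gap && b$rstart > a$rstart
        } else {
          rgap <- a$rstart - b$rend - 1L
          rgap >= -200L && rgap <= max_join_gap && b$rend < a$rend
        }
      }
      # iteratively drop hits without a colinear neighbour, so an isolated
      # off-diagonal (repeat-induced) hit does not sever the chain through
      # its region
      repeat {
        n <- nrow(h)
        if (n == 0L) break
        link <- logical(max(n - 1L, 0L))
        for (i in seq_len(max(n - 1L, 0L)))
          link[i] <- colinear(h[i, ], h[i + 1L, ])
        has_nb <- c(link, FALSE) | c(FALSE, link)
        if (all(has_nb)) break
        h <- h[has_nb, , drop = FALSE]
      }
      n <- nrow(h)
      link <- logical(max(n - 1L, 0L))
      for (i in seq_len(max(n - 1L, 0L)))
        link[i] <- colinear(h[i, ], h[i + 1L, ])
      chain_id <- cumsum(c(TRUE, !link))
      keep_chains <- which(tabulate(chain_id) >= 2L)
      plus_rows <- integer(0)
      for (ci in keep_chains) {
        rows <- which(chain_id == ci)
        ch <- h[rows, , drop = FALSE]
        if (ch$strand[1L] == "-") {
          inversions[[length(inversions) + 1L]] <- data.frame(
            qchrom = chrom, qstart = min(ch$qstart), qend = max(ch$qend),
            rchrom = ch$rchrom[1L], rstart = min(ch$rstart), rend = max(ch$rend),
            n_blocks = nrow(ch), stringsAsFactors = FALSE)
          next
        }
        plus_rows <- c(plus_rows, rows)
        rci <- ch$rchrom_id[1L]
        for (j in seq_len(nrow(ch))) {
          amap <- maps[[as.character(ch$block_id[j])]]
          if (is.null(amap)) next
          qr <- ch$qstart[j]:ch$qend[j]
          sel <- amap > 0L
          ref_pos[qr[sel]] <- amap[sel]
          ref_chrom_id[qr[sel]] <- rci
        }
        segments[[length(segments) + 1L]] <- data.frame(
          qchrom = chrom, qstart = min(ch$qstart), qend = max(ch$qend),
          rchrom = ch$rchrom[1L], rstart = min(ch$rstart), rend = max(ch$rend),
          strand = "+", n_blocks = nrow(ch), stringsAsFactors = FALSE)
      }
      # second local-search pass between consecutive remaining hits: the
      # fill spans chain boundaries too (a repeat cluster longer than
      # max_join_gap splits the chain, but the sequence between the
      # flanking kept hits is still aligned, and the seeded aligner simply
      # finds nothing where the region is genuinely unalignable)
      if (length(plus_rows) > 1L) {
        hk <- h[sort(plus_rows), , drop = FALSE]
        fill_max <- 3L * max_join_gap
        for (j in seq_len(nrow(hk) - 1L)) {
          a <- hk[j, ]; b <- hk[j + 1L, ]
          if (a$rchrom_id != b$rchrom_id) next
          qgs <- a$qend + 1L; qge <- b$qstart - 1L
          rgs <- a$rend + 1L; rge <- b$rstart - 1L
          if (qge < qgs || rge < rgs) next
          if (qge - qgs > fill_max || rge - rgs > fill_max) next
          rseq <- reference$sequences[[ref_chroms[a$rchrom_id]]]
          f <- .fill_region(substring(query$sequences[[chrom]], qgs, qge),
                            substring(rseq, rgs, rge), min_identity)
          sel <- f$map > 0L
          if (any(sel)) {
            qr <- qgs:qge
            ref_pos[qr[sel]] <- f$map[sel] + rgs - 1L
            ref_chrom_id[qr[sel]] <- a$rchrom_id
          }
        }
      }
    }
    # enforce injectivity and monotonicity of the matched positions
    em <- .enforce_monotone(ref_chrom_id, ref_pos)
    cm[[chrom]] <- list(ref_chrom_id = em$ref_chrom_id, ref_pos = em$ref_pos)
  }
  structure(list(chrom = cm, ref_chroms = ref_chroms,
                 segments = if (length(segments)) do.call(rbind, segments) else
                   data.frame(),
                 inversions = if (length(inversions)) do.call(rbind, inversions) else
                   data.frame()),
            class = "correspondence_map")
}

# Keep the heaviest strictly increasing subsequence of v (weighted LIS over
# maximal consecutive runs), so a spurious far-mapping run is dropped rather
# than poisoning everything that follows it (a greedy running-maximum rule
# would do the latter). For very fragmented inputs the DP runs on the
# longest runs and the remaining short runs are slotted in greedily where
# they fit. Returns a logical keep mask.
.lis_filter <- function(v) {
  n <- length(v)
  if (n <= 1L) return(rep(TRUE, n))
  brk <- c(TRUE, diff(v) != 1L)
  starts <- which(brk)
  ends <- c(starts[-1L] - 1L, n)
  m <- length(starts)
  if (m == 1L) return(rep(TRUE, n))
  vs <- v[starts]; ve <- v[ends]
  len <- as.numeric(ends - starts + 1L)
  big <- seq_len(m)
  if (m > 600L) big <- sort(order(-len, seq_len(m))[seq_len(600L)])
  mb <- length(big)
  vsb <- vs[big]; veb <- ve[big]; lenb <- len[big]
  # small overlaps between runs (boundary double-claims from adjacent
  # fills) are tolerated in the DP and trimmed at reconstruction, so a
  # few-bp overlap never disqualifies a long downstream run
  max_ov <- 100
  score <- lenb
  prev <- integer(mb)
  for (i in seq_len(mb)) {
    if (i == 1L) next
    jj <- seq_len(i - 1L)
    ov <- pmax(0, veb[jj] - vsb[i] + 1)
    ok <- ov < pmin(max_ov, lenb[i]) & vsb[jj] < vsb[i] & veb[jj] < veb[i]
    if (any(ok)) {
      cand <- score[jj] - ov
      cand[!ok] <- -Inf
      j <- which.max(cand)
      if (cand[j] + lenb[i] > score[i]) {
        score[i] <- cand[j] + lenb[i]
        prev[i] <- j
      }
    }
  }
  keep_runs <- logical(m)
  i <- which.max(score)
  while (i != 0L) { keep_runs[big[i]] <- TRUE; i <- prev[i] }
  if (any(!keep_runs)) {
    # value of the next kept run to the right, per position
    nxt <- rep(Inf, m)
    cur <- Inf
    for (t in m:1L) { nxt[t] <- cur; if (keep_runs[t]) cur <- vs[t] }
    lower <- 0
    for (t in seq_len(m)) {
      if (keep_runs[t]) { lower <- ve[t]; next }
      if (vs[t] > lower && ve[t] < nxt[t]) { keep_runs[t] <- TRUE; lower <- ve[t] }
    }
  }
  keep <- logical(n)
  last_ve <- 0
  for (t in which(keep_runs)) {
    trim <- max(0, last_ve - vs[t] + 1)
    if (trim >= len[t]) next
    keep[(starts[t] + trim):ends[t]] <- TRUE
    last_ve <- ve[t]
  }
  keep
}

# drop matched positions that break strict monotonicity or injectivity
# within each reference chromosome (repeat-induced off-target pairings)
.enforce_monotone <- function(ref_chrom_id, ref_pos) {
  for (ci in unique(ref_chrom_id[ref_chrom_id > 0L])) {
    sel <- which(ref_chrom_id == ci & ref_pos > 0L)
    if (length(sel) < 2L) next
    keep <- .lis_filter(ref_pos[sel])
    drop <- sel[!keep]
    if (length(drop)) { ref_pos[drop] <- 0L; ref_chrom_id[drop] <- 0L }
  }
  list(ref_chrom_id = ref_chrom_id, ref_pos = ref_pos)
}

#' Pairwise correspondence between two genomes
#'
#' Convenience wrapper: \code{\link{chop_blocks}} then
#' \code{\link{anchor_blocks}} then \code{\link{chain_and_fill}}.
#'
#' @param query,reference \code{genome_set}s
#' @param block_size anchor block length (nt)
#' @param max_join_gap proximity threshold for chaining (nt)
#' @param min_identity minimum hit identity
#' @param min_hit_len minimum aligned hit length (nt)
#' @param k seed length
#' @return a \code{correspondence_map}
#' @export
pairwise_align <- function(query, reference, block_size = 5000L,
                           max_join_gap = 20000L, min_identity = 0.85,
                           min_hit_len = 100L, k = 15L) {
  blocks <- chop_blocks(query, block_size)
  hits <- anchor_blocks(blocks, reference, min_identity, min_hit_len, k)
  chain_and_fill(hits, query, reference, max_join_gap, min_identity)
}
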