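# SNP and structural-variant extraction from the matrix of corresponding
# positions, the simple/complex SV classification by the allele-length rule,
# and presence-frequency polarity inference.

# byte matrix of per-accession bases for a set of gap-free columns
.column_bases <- function(aln, g, cols) {
  mat <- aln$chroms[[g]]
  cmap <- attr(mat, "chrom_map")
  out <- matrix(as.raw(0L), nrow = length(aln$accessions), ncol = length(cols),
                dimnames = list(aln$accessions, NULL))
  for (a in aln$accessions) {
    if (is.na(cmap[a])) next
    b <- .seq_bytes(aln$genomes[[a]]$sequences[[cmap[a]]])
    out[a, ] <- b[mat[a, cols]]
  }
  out
}

#' Call SNPs from a pangenome alignment
#'
#' In mode "all", every gap-free column with at least two distinct bases is a
#' SNP. In mode "isolated", both immediate neighbour columns must in
#' addition be gap-free and monomorphic (sequence differences flanked by
#' agreement, which protects against local alignment ambiguity). Columns
#' containing N never qualify.
#'
#' @param aln an indexed \code{pangenome_alignment}
#' @param mode "all" or "isolated"
#' @return \code{snp_set}: data.frame with columns chrom (pangenome
#'   chromosome), col (pangenome column), anchor_chrom, anchor_pos (position
#'   in the first non-gap accession of the alignment's accession order),
#'   alleles (one base per accession, in accession order)
#' @export
call_snps <- function(aln, mode = c("all", "isolated")) {
  mode <- match.arg(mode)
  n <- length(aln$accessions)
  anchor <- aln$accessions[1L]
  rows <- list()
  for (g in names(aln$chroms)) {
    mat <- aln$chroms[[g]]
    if (ncol(mat) == 0L) next
    full <- colSums(mat > 0L) == n
    fcols <- which(full)
    if (!length(fcols)) next
    bm <- .column_bases(aln, g, fcols)
    anyN <- colSums(bm == .BYTE_N) > 0L
    mono <- colSums(bm != rep(bm[1L, ], each = n)) == 0L
    poly <- !mono & !anyN
    snp_cols <- fcols[poly]
    if (mode == "isolated" && length(snp_cols)) {
      # neighbours must be gap-free and monomorphic
      good <- logical(ncol(mat))
      good[fcols] <- mono & !anyN
      left <- snp_cols - 1L; right <- snp_cols + 1L
      okL <- left >= 1L & good[pmax(left, 1L)]
      okR <- right <= ncol(mat) & good[pmin(right, ncol(mat))]
      snp_cols <- snp_cols[okL & okR]
    }
    if (!length(snp_cols)) next
    sel <- match(snp_cols, fcols)
    alle <- apply(bm[, sel, drop = FALSE], 2L, function(b) .bytes_seq(b))
    rows[[g]] <- data.frame(
      chrom = g, col = snp_cols,
      anchor_chrom = unname(attr(mat, "chrom_map")[anchor]),
      anchor_pos = mat[anchor, snp_cols],
      alleles = alle, stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), col = integer(0),
               anchor_chrom = character(0), anchor_pos = integer(0),
               alleles = character(0))
  rownames(out) <- NULL
  structure(out, accessions = aln$accessions, mode = mode,
            class = c("snp_set", "data.frame"))
}

#' Extract presence/absence SV loci from a pangenome alignment
#'
#' A locus is a maximal run of consecutive columns each containing at least
#' one gap, flanked by gap-free columns or chromosome ends (the latter are
#' flagged \code{terminal}). Per accession, the allele is its sequence over
#' the run (possibly empty); the SV length L is the maximum allele length.
#'
#' @param aln an indexed \code{pangenome_alignment}
#' @return \code{sv_set}: data.frame (chrom, sv_id, col_start, col_end, L,
#'   terminal) with the per-accession allele-length matrix in attribute
#'   \code{allele_lengths} and allele sequences in attribute \code{alleles}
#'   (list of per-accession character vectors)
#' @export
extract_sv_loci <- function(aln) {
  n <- length(aln$accessions)
  rows <- list(); len_mats <- list(); seq_lists <- list()
  sv_i <- 0L
  for (g in names(aln$chroms)) {
    mat <- aln$chroms[[g]]
    if (ncol(mat) == 0L) next
    cmap <- attr(mat, "chrom_map")
    hasgap <- colSums(mat > 0L) < n
    if (!any(hasgap)) next
    r <- rle(hasgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    for (t in gi) {
      sv_i <- sv_i + 1L
      cs <- starts[t]; ce <- ends[t]
      lens <- integer(n); seqs <- character(n)
      for (ai in seq_len(n)) {
        a <- aln$accessions[ai]
        pos <- mat[a, cs:ce]
        pos <- pos[pos > 0L]
        lens[ai] <- length(pos)
        seqs[ai] <- if (length(pos))
          substring(aln$genomes[[a]]$sequences[[cmap[a]]], min(pos), max(pos))
        else ""
      }
      rows[[sv_i]] <- data.frame(
        chrom = g, sv_id = sprintf("sv%05d", sv_i), col_start = cs, col_end = ce,
        L = max(lens), terminal = (cs == 1L || ce == ncol(mat)),
        stringsAsFactors = FALSE)
      len_mats[[sv_i]] <- lens
      seq_lists[[sv_i]] <- seqs
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), sv_id = character(0), col_start = integer(0),
               col_end = integer(0), L = integer(0), terminal = logical(0))
  rownames(out) <- NULL
  lm <- if (length(len_mats)) do.call(rbind, len_mats) else
    matrix(0L, 0L, n)
  colnames(lm) <- aln$accessions
  structure(out, accessions = aln$accessions, allele_lengths = lm,
            alleles = seq_lists, class = c("sv_set", "data.frame"))
}

#' Classify SV loci as simple (sSV) or complex (cSV)
#'
#' A locus is a simple indel (sSV) iff every allele is either shorter than
#' (1 - s) of the SV length L (an absence allele) or longer than s of L (a
#' presence allele); any allele of intermediate length makes the locus
#' complex (cSV). Presence frequency is the fraction of accessions carrying
#' the presence allele.
#'
#' @param svs an \code{sv_set}
#' @param s similarity threshold in (0.5, 1]; below 0.5 the absence and
#'   presence length intervals overlap and the rule is ill-posed
#' @return the \code{sv_set} with columns class ("sSV"/"cSV"),
#'   n_presence, n_absence, presence_freq added, and logical presence /
#'   absence membership matrices in attributes \code{presence} and
#'   \code{absence}
#' @export
classify_sv <- function(svs, s = 0.9) {
  if (s <= 0.5 || s > 1) .stopf("s must be in (0.5, 1]")
  lm <- attr(svs, "allele_lengths")
  n <- ncol(lm)
  L <- svs$L
  pres <- lm > s * L
  abse <- lm < (1 - s) * L
  simple <- rowSums(pres | abse) == n
  svs$class <- ifelse(simple, "sSV", "cSV")
  svs$n_presence <- rowSums(pres)
  svs$n_absence <- rowSums(abse)
  svs$presence_freq <- ifelse(simple, svs$n_presence / n, NA_real_)
  attr(svs, "presence") <- pres
  attr(svs, "absence") <- abse
  attr(svs, "s") <- s
  svs
}

#' Infer indel polarity from presence-allele frequency
#'
#' A simple indel whose presence allele is carried by at most
#' \code{max_minor} accessions is a likely insertion; one whose absence
#' allele is carried by at most \code{max_minor} accessions is a likely
#' deletion; anything else is unpolarized. Terminal loci are always
#' unpolarized (their boundaries are not resolvable).
#'
#' @param svs a classified \code{sv_set}
#' @param max_minor largest minor-allele count that still polarises
#' @return the \code{sv_set} with a \code{polarity} column added
#' @export
infer_polarity <- function(svs, max_minor = 3L) {
  if (is.null(svs$class)) .stopf("run classify_sv() first")
  pol <- rep("unpolarized", nrow(svs))
  ssv <- svs$class == "sSV" & !svs$terminal
  pol[ssv & svs$n_presence <= max_minor] <- "likely_insertion"
  pol[ssv & svs$n_absence <= max_minor & svs$n_presence > max_minor] <-
    "likely_deletion"
  svs$polarity <- pol
  svs
}

#' Consensus (medoid) presence allele of an SV locus
#'
#' Returns the presence allele with maximal mean global-alignment identity
#' to the other presence alleles (the medoid); a lone presence allele is
#' returned as is.
#'
#' @param svs a classified \code{sv_set}
#' @param i locus row index
#' @return character scalar (empty when the locus has no presence allele)
#' @export
consensus_allele <- function(svs, i) {
  pres <- attr(svs, "presence")
  seqs <- attr(svs, "alleles")[[i]]
  if (is.null(pres)) .stopf("run classify_sv() first")
  cand <- seqs[pres[i, ]]
  cand <- cand[nchar(cand) > 0L]
  if (length(cand) == 0L) return("")
  if (length(cand) == 1L) return(cand)
  if (length(unique(cand)) == 1L) return(cand[1L])
  mean_id <- vapply(seq_along(cand), function(j) {
    mean(vapply(setdiff(seq_along(cand), j), function(t)
      .global_identity(cand[j], cand[t]), numeric(1)))
  }, numeric(1))
  cand[which.max(mean_id)]
}

#' Bin sSV lengths into fixed length classes
#'
#' The class edges 1, 15, 100, 500, 1000, 5000, 20000 partition the loci
#' exactly: classes are [1,15), [15,100), ..., [5000,20000), [20000, Inf).
#'
#' @param L integer vector of SV lengths
#' @param edges ascending class edges
#' @return factor of length classes
#' @export
sv_length_class <- function(L, edges = c(1, 15, 100, 500, 1000, 5000, 20000)) {
  labs <- c(paste0("[", edges[-length(edges)], ",", edges[-1L], ")"),
            paste0("[", edges[length(edges)], ",Inf)"))
  cut(L, breaks = c(edges, Inf), labels = labs, right = FALSE)
}
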