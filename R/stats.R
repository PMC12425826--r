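# Pangenome-scale summaries: pan/core saturation curves, coordinate
# dilation against a reference accession, and pairwise divergence.

# unique subsets of size k from n accessions, at most max_subsets of them
.unique_subsets <- function(n, k, max_subsets, max_tries = 10000L) {
  total <- choose(n, k)
  if (total <= max_subsets)
    return(utils::combn(n, k, simplify = FALSE))
  out <- list(); seen <- character(0)
  tries <- 0L
  while (length(out) < max_subsets && tries < max_tries) {
    tries <- tries + 1L
    s <- sort(sample.int(n, k))
    key <- paste(s, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- s
  }
  out
}

#' Pan/core saturation curve
#'
#' For each sample size k = 1..n, draws up to \code{max_subsets} unique
#' accession subsets and counts pan columns (>= 1 subset member non-gap) and
#' core columns (all subset members non-gap), reporting mean and sample
#' standard deviation over subsets (0 when a size has a single subset).
#'
#' @param aln a \code{pangenome_alignment}
#' @param max_subsets subsets per sample size
#' @param seed integer seed for subset sampling
#' @return \code{saturation_curve}: data.frame (k, pan_mean, pan_sd,
#'   core_mean, core_sd, n_subsets)
#' @export
pan_core_curve <- function(aln, max_subsets = 20L, seed = 1L) {
  n <- length(aln$accessions)
  if (n < 2L) .stopf("need at least 2 accessions")
  set.seed(seed)
  gapfree <- lapply(aln$chroms, function(m) m > 0L)
  rows <- lapply(seq_len(n), function(k) {
    subs <- .unique_subsets(n, k, max_subsets)
    pan <- numeric(length(subs)); core <- numeric(length(subs))
    for (si in seq_along(subs)) {
      s <- subs[[si]]
      for (G in gapfree) {
        nz <- colSums(G[s, , drop = FALSE])
        pan[si] <- pan[si] + sum(nz > 0L)
        core[si] <- core[si] + sum(nz == k)
      }
    }
    data.frame(k = k, pan_mean = mean(pan),
               pan_sd = if (length(pan) > 1L) stats::sd(pan) else 0,
               core_mean = mean(core),
               core_sd = if (length(core) > 1L) stats::sd(core) else 0,
               n_subsets = length(subs))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("saturation_curve", "data.frame"))
}

#' Pangenome-versus-reference coordinate dilation
#'
#' For every column where the reference accession is non-gap, emits the
#' (pangenome column, reference position) pair; the curve is non-decreasing
#' in both coordinates and its deviation from the diagonal measures how much
#' the pangenome coordinate system is dilated by sequence absent from the
#' reference.
#'
#' @param aln a \code{pangenome_alignment}
#' @param reference_accession accession whose coordinates form the x axis
#' @return data.frame (chrom, column, ref_pos)
#' @export
dilation_curve <- function(aln, reference_accession) {
  if (!reference_accession %in% aln$accessions)
    .stopf("unknown accession: %s", reference_accession)
  rows <- lapply(names(aln$chroms), function(g) {
    v <- aln$chroms[[g]][reference_accession, ]
    nz <- which(v > 0L)
    data.frame(chrom = g, column = nz, ref_pos = v[nz])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise divergence between two accessions
#'
#' SNP differences are counted over columns where both accessions are
#' non-gap with differing bases (N excluded); sSV differences are the
#' classified simple loci where exactly one of the pair carries the presence
#' allele, binned by SV length, with the total presence-allele length in nt.
#'
#' @param aln a \code{pangenome_alignment}
#' @param i,j accession labels (i != j)
#' @param svs optional pre-computed classified \code{sv_set} (computed from
#'   the alignment when NULL)
#' @param length_class_edges bin edges for \code{\link{sv_length_class}}
#' @param s sSV classification threshold when \code{svs} is NULL
#' @return \code{divergence_summary}: list with \code{snp_count},
#'   \code{sv_count}, \code{sv_bp}, and \code{by_class} (counts and bp per
#'   length class)
#' @export
pairwise_divergence <- function(aln, i, j, svs = NULL,
                                length_class_edges = c(1, 15, 100, 500, 1000,
                                                       5000, 20000),
                                s = 0.9) {
  if (identical(i, j)) .stopf("i and j must differ")
  if (!all(c(i, j) %in% aln$accessions)) .stopf("unknown accession")
  snp_count <- 0L
  for (g in names(aln$chroms)) {
    mat <- aln$chroms[[g]]
    cmap <- attr(mat, "chrom_map")
    both <- mat[i, ] > 0L & mat[j, ] > 0L
    if (!any(both)) next
    bi <- .seq_bytes(aln$genomes[[i]]$sequences[[cmap[i]]])[mat[i, both]]
    bj <- .seq_bytes(aln$genomes[[j]]$sequences[[cmap[j]]])[mat[j, both]]
    snp_count <- snp_count + sum(bi != bj & bi != .BYTE_N & bj != .BYTE_N)
  }
  if (is.null(svs)) svs <- classify_sv(extract_sv_loci(aln), s = s)
  pres <- attr(svs, "presence")
  ssv <- svs$class == "sSV" & !svs$terminal
  diffp <- xor(pres[, i], pres[, j]) & ssv
  lens <- attr(svs, "allele_lengths")
  plen <- ifelse(pres[, i], lens[, i], lens[, j])
  cl <- sv_length_class(svs$L, length_class_edges)
  by_class <- data.frame(
    class = levels(cl),
    count = as.integer(table(cl[diffp])),
    bp = as.numeric(tapply(plen[diffp], cl[diffp], sum, default = 0)))
  structure(list(i = i, j = j, snp_count = as.integer(snp_count),
                 sv_count = sum(diffp), sv_bp = sum(plen[diffp]),
                 by_class = by_class),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("divergence %s vs %s: %d SNPs, %d sSVs (%d bp)\n",
              x$i, x$j, x$snp_count, x$sv_count, x$sv_bp))
  invisible(x)
}
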