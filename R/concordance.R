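# Reference-bias auditing: the six-way SNP-call taxonomy with FDR/FNR, the
# expression/methylation concordance rules, and ChIP-style quantile
# normalization.

#' Classify SNP calls against whole-genome-alignment truth
#'
#' Truth SNPs (assumed correct) become TP when also called, "uncalled" when
#' their site lacks read coverage, and FN otherwise. Test calls become
#' FP_het when heterozygous (accessions are completely inbred, so
#' heterozygous calls are false by construction and take precedence even
#' when they match a truth site), TP when matching a truth SNP, FP_non_snp
#' when at an aligned non-SNP site, and FP_unaligned when their site is not
#' in the aligned mask.
#'
#' @param truth list with \code{snps} (integer positions) and \code{aligned}
#'   (logical vector over sites: aligned in the WGA or not)
#' @param test list with \code{calls} (data.frame pos, het) and
#'   \code{covered} (logical vector over sites)
#' @return object of class \code{call_taxonomy}: counts TP, FN, uncalled,
#'   FP_non_snp, FP_unaligned, FP_het, plus FDR and FNR (NA when the
#'   denominator is empty, never 0 by convention)
#' @export
classify_calls <- function(truth, test) {
  tp_set <- test$calls$pos[!test$calls$het]
  truth_pos <- truth$snps
  is_tp <- truth_pos %in% tp_set
  is_uncov <- !test$covered[truth_pos]
  TP <- sum(is_tp)
  uncalled <- sum(!is_tp & is_uncov)
  FN <- sum(!is_tp & !is_uncov)
  het <- test$calls$het
  call_pos <- test$calls$pos
  in_truth <- call_pos %in% truth_pos
  FP_het <- sum(het)
  call_tp <- !het & in_truth
  aligned <- truth$aligned[call_pos]
  FP_non_snp <- sum(!het & !in_truth & aligned)
  FP_unaligned <- sum(!het & !in_truth & !aligned)
  stopifnot(TP + FN + uncalled == length(truth_pos),
            sum(call_tp) + FP_non_snp + FP_unaligned + FP_het == nrow(test$calls))
  ncalls <- TP + FP_non_snp + FP_unaligned + FP_het
  fdr <- if (ncalls > 0L) (FP_non_snp + FP_unaligned + FP_het) / ncalls else NA_real_
  fnr <- if (TP + FN > 0L) FN / (TP + FN) else NA_real_
  structure(list(TP = TP, FN = FN, uncalled = uncalled,
                 FP_non_snp = FP_non_snp, FP_unaligned = FP_unaligned,
                 FP_het = FP_het, FDR = fdr, FNR = fnr,
                 n_truth = length(truth_pos), n_calls = nrow(test$calls)),
            class = "call_taxonomy")
}

#' @export
print.call_taxonomy <- function(x, ...) {
  cat(sprintf(paste0("call_taxonomy: TP %d | FN %d | uncalled %d | ",
                     "FP_non_snp %d | FP_unaligned %d | FP_het %d\n"),
              x$TP, x$FN, x$uncalled, x$FP_non_snp, x$FP_unaligned, x$FP_het))
  cat(sprintf("  FDR = %s, FNR = %s\n",
              format(x$FDR, digits = 4), format(x$FNR, digits = 4)))
  invisible(x)
}

#' @method as.data.frame call_taxonomy
#' @export
as.data.frame.call_taxonomy <- function(x, ...) {
  data.frame(TP = x$TP, FN = x$FN, uncalled = x$uncalled,
             FP_non_snp = x$FP_non_snp, FP_unaligned = x$FP_unaligned,
             FP_het = x$FP_het, FDR = x$FDR, FNR = x$FNR)
}

#' Per-gene expression concordance between two mappings
#'
#' Compares read counts obtained by mapping to a common reference versus the
#' accession's own genome. A gene is excluded when the larger count is below
#' \code{min_count}, discordant when min/max <= \code{ratio_cut} (counts
#' differ by more than 30\% at the default), else concordant.
#'
#' @param counts_ref,counts_own non-negative per-gene counts over the same
#'   gene universe
#' @param min_count minimum of the larger count for a gene to be assessed
#' @param ratio_cut min/max ratio at or below which a gene is discordant
#' @return character vector ("concordant"/"discordant"/"excluded") per gene
#' @export
expression_concordance <- function(counts_ref, counts_own, min_count = 6,
                                   ratio_cut = 0.7) {
  if (length(counts_ref) != length(counts_own))
    .stopf("count vectors differ in length")
  if (any(counts_ref < 0) || any(counts_own < 0))
    .stopf("counts must be non-negative")
  mx <- pmax(counts_ref, counts_own)
  mn <- pmin(counts_ref, counts_own)
  out <- rep("concordant", length(mx))
  out[mn / mx <= ratio_cut] <- "discordant"
  out[mx < min_count] <- "excluded"
  out
}

#' Methylation level from methylated/unmethylated read counts
#'
#' level = methylated / (methylated + unmethylated), so levels lie in [0, 1]
#' and can feed the min/max concordance ratio; NA when there are no reads.
#'
#' @param meth_reads,unmeth_reads non-negative counts (vectorised)
#' @return numeric vector of levels in [0, 1], NA where both counts are 0
#' @export
methylation_level <- function(meth_reads, unmeth_reads) {
  if (any(meth_reads < 0) || any(unmeth_reads < 0))
    .stopf("read counts must be non-negative")
  tot <- meth_reads + unmeth_reads
  ifelse(tot == 0, NA_real_, meth_reads / tot)
}

#' Per-gene methylation concordance between two mappings
#'
#' Discordant when the smaller level is at most \code{ratio_cut} of the
#' larger (levels differ by more than 50\% at the default); excluded when
#' either level is missing; two zero levels are equal, hence concordant.
#'
#' @param level_ref,level_own methylation levels in [0, 1] (NA allowed)
#' @param ratio_cut min/max ratio at or below which a gene is discordant
#' @return character vector ("concordant"/"discordant"/"excluded") per gene
#' @export
methylation_concordance <- function(level_ref, level_own, ratio_cut = 0.5) {
  if (length(level_ref) != length(level_own)) .stopf("level vectors differ in length")
  out <- rep("concordant", length(level_ref))
  mx <- pmax(level_ref, level_own)
  mn <- pmin(level_ref, level_own)
  disc <- mx > 0 & (mn / mx) <= ratio_cut
  out[disc] <- "discordant"
  out[is.na(level_ref) | is.na(level_own)] <- "excluded"
  out
}

#' Quantile normalization of a coverage vector
#'
#' (x - q_low) / (q_high - q_low) with type-7 (linear interpolation)
#' quantiles, so that after normalization quantile(q_low) = 0 and
#' quantile(q_high) = 1; affine transforms of the input normalise
#' identically.
#'
#' @param values numeric vector with at least 2 distinct values
#' @param q_low,q_high the quantile probabilities to pin at 0 and 1
#' @param type quantile estimator type (see \code{\link[stats]{quantile}})
#' @return normalized numeric vector
#' @export
quantile_normalize <- function(values, q_low = 0.20, q_high = 0.80, type = 7L) {
  if (length(unique(values)) < 2L)
    .stopf("values must contain at least 2 distinct values")
  qs <- stats::quantile(values, c(q_low, q_high), names = FALSE, type = type)
  if (qs[2L] <= qs[1L])
    .stopf("quantile(%.2f) must exceed quantile(%.2f)", q_high, q_low)
  (values - qs[1L]) / (qs[2L] - qs[1L])
}
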