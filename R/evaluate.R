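# Scoring of pipeline output against a planted truth ledger: SNP
# sensitivity/precision, structural-variant recovery with breakpoint
# tolerance, and polarity accuracy.

# ancestor-coordinate interval membership
.in_intervals <- function(pos, start, end) {
  if (!length(start)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (t in seq_along(start)) out <- out | (pos >= start[t] & pos <= end[t])
  out
}

#' Score called SNPs against planted truth
#'
#' Sensitivity: fraction of planted SNPs whose pangenome column is called.
#' Precision: fraction of called columns that correspond to a planted SNP,
#' evaluated outside the planted satellite blocks (whose internal alignment
#' is not meaningful) and outside planted insertion content.
#'
#' @param snps \code{snp_set} from \code{\link{call_snps}}
#' @param aln the \code{pangenome_alignment} the SNPs came from
#' @param sim result of \code{\link{simulate_pangenome}} (genomes, truth,
#'   ancestor)
#' @param margin nt around satellite blocks also excluded from precision
#' @return list(sensitivity, precision, n_truth, n_called, n_true_calls)
#' @export
evaluate_snp_calls <- function(snps, aln, sim, margin = 10L) {
  truth <- sim$truth
  maps <- lapply(truth$accessions, function(a)
    truth_coord_maps(sim$ancestor, truth, a))
  names(maps) <- truth$accessions
  # which pangenome chromosome carries each genome chromosome, per accession
  found <- logical(nrow(truth$snps))
  called_key <- paste(snps$chrom, snps$col)
  for (t in seq_len(nrow(truth$snps))) {
    tr <- truth$snps[t, ]
    carrier <- .parse_carriers(tr$carriers)[1L]
    gpos <- maps[[carrier]][[tr$chrom]]$anc2acc[tr$anc_pos]
    if (is.na(gpos)) next
    colid <- aln$index[[carrier]][[tr$chrom]][gpos]
    if (colid == 0L) next
    g <- .pg_chrom_of(aln, carrier, tr$chrom)
    found[t] <- paste(g, colid) %in% called_key
  }
  # precision: map each called column back to an ancestor position via the
  # first accession present in the column
  anc_pos_of <- rep(NA_integer_, nrow(snps))
  anc_chrom_of <- rep(NA_character_, nrow(snps))
  for (t in seq_len(nrow(snps))) {
    g <- snps$chrom[t]
    mat <- aln$chroms[[g]]
    cmap <- attr(mat, "chrom_map")
    a <- aln$accessions[1L]
    p <- mat[a, snps$col[t]]
    if (p == 0L || is.na(cmap[a])) next
    anc_chrom_of[t] <- cmap[a]
    anc_pos_of[t] <- maps[[a]][[cmap[a]]]$acc2anc[p]
  }
  sat <- truth$satellites
  in_sat <- rep(FALSE, nrow(snps))
  for (ch in unique(sat$chrom)) {
    sel <- which(anc_chrom_of == ch & !is.na(anc_pos_of))
    ss <- sat[sat$chrom == ch, ]
    in_sat[sel] <- .in_intervals(anc_pos_of[sel], ss$anc_start - margin,
                                 ss$anc_end + margin)
  }
  assessable <- !is.na(anc_pos_of) & !in_sat
  truth_key <- paste(truth$snps$chrom, truth$snps$anc_pos)
  is_true <- paste(anc_chrom_of, anc_pos_of) %in% truth_key
  n_called <- sum(assessable)
  n_true <- sum(is_true & assessable)
  list(sensitivity = mean(found),
       precision = if (n_called) n_true / n_called else NA_real_,
       n_truth = nrow(truth$snps), n_called = n_called, n_true_calls = n_true)
}

# pangenome chromosome whose chrom_map assigns `chrom` to accession `acc`
.pg_chrom_of <- function(aln, acc, chrom) {
  for (g in names(aln$chroms)) {
    cmap <- attr(aln$chroms[[g]], "chrom_map")
    if (!is.na(cmap[acc]) && cmap[acc] == chrom) return(g)
  }
  NA_character_
}

#' Score recovered structural variants against planted truth
#'
#' A planted insertion is recovered when a simple (sSV) locus has both
#' breakpoint columns within \code{tol} columns of the columns flanking the
#' inserted sequence in a carrier genome; deletions are matched through a
#' non-carrier genome the same way. Polarity is scored on recovered events
#' whose minor-allele count is at most \code{max_minor}.
#'
#' @param svs classified and polarised \code{sv_set}
#' @param aln the \code{pangenome_alignment}
#' @param sim result of \code{\link{simulate_pangenome}}
#' @param tol breakpoint tolerance in pangenome columns
#' @param max_minor polarity minor-allele bound (as in
#'   \code{\link{infer_polarity}})
#' @return list with recovery fractions and per-event tables
#' @export
evaluate_sv_recovery <- function(svs, aln, sim, tol = 20L, max_minor = 3L) {
  truth <- sim$truth
  n <- length(truth$accessions)
  maps <- lapply(truth$accessions, function(a)
    truth_coord_maps(sim$ancestor, truth, a))
  names(maps) <- truth$accessions

  score_event <- function(chrom, left_anc, right_anc, via_acc, want_polarity,
                          carriers) {
    # columns flanking the event through the chosen genome
    gl <- maps[[via_acc]][[chrom]]$anc2acc[left_anc]
    gr <- maps[[via_acc]][[chrom]]$anc2acc[right_anc]
    if (is.na(gl) || is.na(gr)) return(list(recovered = FALSE))
    colL <- aln$index[[via_acc]][[chrom]][gl]
    colR <- aln$index[[via_acc]][[chrom]][gr]
    if (colL == 0L || colR == 0L) return(list(recovered = FALSE))
    g <- .pg_chrom_of(aln, via_acc, chrom)
    cand <- which(svs$chrom == g & svs$class == "sSV" &
                    abs(svs$col_start - (colL + 1L)) <= tol &
                    abs(svs$col_end - (colR - 1L)) <= tol)
    if (!length(cand)) return(list(recovered = FALSE))
    i <- cand[1L]
    pol_ok <- if (is.na(want_polarity)) NA else
      identical(svs$polarity[i], want_polarity)
    list(recovered = TRUE, locus = svs$sv_id[i], polarity_ok = pol_ok)
  }

  ins <- truth$insertions
  ins_rows <- lapply(seq_len(nrow(ins)), function(t) {
    carriers <- .parse_carriers(ins$carriers[t])
    r <- score_event(ins$chrom[t], ins$anc_pos[t], ins$anc_pos[t] + 1L,
                     carriers[1L],
                     if (length(carriers) <= max_minor) "likely_insertion" else NA_character_,
                     carriers)
    data.frame(event_id = ins$event_id[t], type = "insertion",
               n_carriers = length(carriers), recovered = r$recovered,
               locus = if (r$recovered) r$locus else NA_character_,
               polarity_ok = if (is.null(r$polarity_ok)) NA else r$polarity_ok,
               stringsAsFactors = FALSE)
  })
  del <- truth$deletions
  del_rows <- lapply(seq_len(nrow(del)), function(t) {
    carriers <- .parse_carriers(del$carriers[t])
    non_carrier <- setdiff(truth$accessions, carriers)[1L]
    r <- score_event(del$chrom[t], del$anc_start[t] - 1L, del$anc_end[t] + 1L,
                     non_carrier,
                     if (length(carriers) <= max_minor) "likely_deletion" else NA_character_,
                     carriers)
    data.frame(event_id = del$event_id[t], type = "deletion",
               n_carriers = length(carriers), recovered = r$recovered,
               locus = if (r$recovered) r$locus else NA_character_,
               polarity_ok = if (is.null(r$polarity_ok)) NA else r$polarity_ok,
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, c(ins_rows, del_rows))
  pol <- events$polarity_ok[events$recovered & !is.na(events$polarity_ok)]
  list(recovery = mean(events$recovered),
       insertion_recovery = mean(events$recovered[events$type == "insertion"]),
       deletion_recovery = mean(events$recovered[events$type == "deletion"]),
       polarity_accuracy = if (length(pol)) mean(pol) else NA_real_,
       events = events)
}

#' Component and planted-family labels for recovered insertions
#'
#' Joins the event-to-locus assignment of \code{\link{evaluate_sv_recovery}}
#' with the nestedness-graph components, giving for every recovered planted
#' insertion that is a graph member its component label next to its planted
#' family label, ready for an external clustering comparison (e.g. an
#' adjusted Rand index).
#'
#' @param graph a \code{nestedness_graph}
#' @param recovery result of \code{\link{evaluate_sv_recovery}}
#' @param sim result of \code{\link{simulate_pangenome}}
#' @return data.frame (event_id, sv_id, component, family_id)
#' @export
family_component_labels <- function(graph, recovery, sim) {
  ev <- recovery$events
  ev <- ev[ev$type == "insertion" & ev$recovered & !is.na(ev$locus), , drop = FALSE]
  mm <- graph$member_map
  rows <- list()
  for (t in seq_len(nrow(ev))) {
    id <- ev$locus[t]
    if (!id %in% names(mm)) next
    node <- mm[[id]]
    comp <- graph$nodes$component[match(node, graph$nodes$node_id)]
    fam <- sim$truth$insertions$family_id[match(ev$event_id[t],
                                                sim$truth$insertions$event_id)]
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = ev$event_id[t], sv_id = id, component = comp,
      family_id = fam, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), sv_id = character(0),
               component = integer(0), family_id = character(0))
}
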