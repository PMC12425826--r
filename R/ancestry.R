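# Gene-group ancestry classification: outgroup homolog assignment by the
# 50%-share / 80%-identity / 80%-coverage rule, colinear-segment
# construction with a bounded outgroup gap, and the three-state call.

#' Assign the outgroup homolog of a gene group
#'
#' The outgroup gene hit by at least \code{min_share} of the group's members
#' at identity >= \code{min_ident} over coverage >= \code{min_cov} of the
#' focal coding sequence; ties break towards higher member share, then
#' higher mean identity, then outgroup gene id.
#'
#' @param hits data.frame (member_id, outgroup_gene, identity, coverage) of
#'   this group's homology hits (may have zero rows)
#' @param n_members number of members in the group
#' @param min_share minimum fraction of members supporting the homolog
#' @param min_ident,min_cov per-hit thresholds
#' @return outgroup gene id, or NA when no gene qualifies
#' @export
assign_group_homolog <- function(hits, n_members, min_share = 0.5,
                                 min_ident = 0.8, min_cov = 0.8) {
  if (n_members < 1L) .stopf("group must be non-empty")
  if (nrow(hits) == 0L) return(NA_character_)
  ok <- hits$identity >= min_ident & hits$coverage >= min_cov
  h <- hits[ok, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_character_)
  share <- tapply(h$member_id, h$outgroup_gene, function(x) length(unique(x))) / n_members
  mid <- tapply(h$identity, h$outgroup_gene, mean)
  cand <- names(share)[share >= min_share]
  if (!length(cand)) return(NA_character_)
  o <- order(-share[cand], -mid[cand], cand)
  cand[o][1L]
}

#' Build colinear segments from homolog-assigned gene groups
#'
#' Groups are ordered by their pangenome rank. Two consecutive assigned
#' groups join the same segment iff their outgroup homologs are separated by
#' fewer than \code{max_outgroup_gap} genes in the outgroup gene order; an
#' unassigned group in between breaks the segment.
#'
#' @param groups data.frame with columns group_id and homolog (NA = no
#'   homolog), ordered by pangenome rank
#' @param outgroup_order character vector: outgroup gene ids in genomic
#'   order
#' @param max_outgroup_gap separation bound (strict; "fewer than")
#' @return the \code{groups} data.frame with an integer \code{segment}
#'   column (NA for unassigned groups) and a \code{segment_size} column
#' @export
build_colinear_segments <- function(groups, outgroup_order,
                                    max_outgroup_gap = 6L) {
  rank_out <- match(groups$homolog, outgroup_order)
  if (any(!is.na(groups$homolog) & is.na(rank_out)))
    .stopf("homolog missing from outgroup_order: %s",
           groups$homolog[!is.na(groups$homolog) & is.na(rank_out)][1L])
  n <- nrow(groups)
  seg <- rep(NA_integer_, n)
  cur <- 0L
  prev_rank <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(rank_out[i])) { prev_rank <- NA_integer_; next }
    if (is.na(prev_rank) || abs(rank_out[i] - prev_rank) >= max_outgroup_gap) {
      cur <- cur + 1L
    }
    seg[i] <- cur
    prev_rank <- rank_out[i]
  }
  groups$segment <- seg
  sizes <- table(seg)
  groups$segment_size <- ifelse(is.na(seg), 0L,
                                as.integer(sizes[as.character(seg)]))
  groups
}

#' Classify gene-group ancestry
#'
#' Three states: "ancestral_position_and_sequence" for groups in a colinear
#' segment of at least two groups (sequence and syntenic position both
#' conserved); "similar" for groups with an assigned homolog (the same
#' 80/80 identity/coverage evidence) but no qualifying segment; and
#' "non_ancestral" for groups without a homolog.
#'
#' @param groups data.frame from \code{\link{build_colinear_segments}}
#' @param min_segment minimum segment size for the ancestral call
#' @return the \code{groups} data.frame with an \code{ancestry} column
#' @export
classify_ancestry <- function(groups, min_segment = 2L) {
  if (is.null(groups$segment)) .stopf("run build_colinear_segments() first")
  out <- rep("non_ancestral", nrow(groups))
  has_hom <- !is.na(groups$homolog)
  out[has_hom] <- "similar"
  out[has_hom & groups$segment_size >= min_segment] <-
    "ancestral_position_and_sequence"
  groups$ancestry <- out
  groups
}

#' Simulate gene groups with controllable synteny decay
#'
#' Generates \code{n_groups} groups in perfect synteny with an outgroup
#' (outgroup order = focal order, all homolog hits passing the 80/80
#' thresholds), then disturbs the outgroup order by \code{n_swaps} random
#' transpositions of distant genes. Used to check that shuffling the
#' outgroup destroys colinear segments.
#'
#' @param n_groups number of gene groups
#' @param n_members members per group
#' @param n_swaps random long-range swaps applied to the outgroup order
#' @param seed integer seed
#' @return list with \code{groups} (group_id, homolog), \code{hits} (per
#'   group, a hits data.frame), and \code{outgroup_order}
#' @export
simulate_gene_groups <- function(n_groups = 200L, n_members = 8L,
                                 n_swaps = 0L, seed = 1L) {
  set.seed(seed)
  gid <- sprintf("grp%04d", seq_len(n_groups))
  out_gene <- sprintf("og%04d", seq_len(n_groups))
  hits <- lapply(seq_len(n_groups), function(i) {
    data.frame(member_id = sprintf("%s_m%d", gid[i], seq_len(n_members)),
               outgroup_gene = out_gene[i],
               identity = stats::runif(n_members, 0.85, 0.99),
               coverage = stats::runif(n_members, 0.85, 1.0),
               stringsAsFactors = FALSE)
  })
  names(hits) <- gid
  order_out <- out_gene
  if (n_swaps > 0L) for (t in seq_len(n_swaps)) {
    ij <- sample.int(n_groups, 2L)
    order_out[ij] <- order_out[rev(ij)]
  }
  list(groups = data.frame(group_id = gid, homolog = NA_character_,
                           stringsAsFactors = FALSE),
       hits = hits, outgroup_order = order_out)
}

#' Run the full ancestry classification over a set of groups
#'
#' @param groups data.frame (group_id) ordered by pangenome rank
#' @param hits named list of per-group hit data.frames
#' @param outgroup_order outgroup gene ids in genomic order
#' @param n_members members per group (scalar or per-group vector)
#' @param ... thresholds passed to the stage functions
#' @return groups data.frame with homolog, segment and ancestry columns
#' @export
run_ancestry <- function(groups, hits, outgroup_order, n_members, ...) {
  n_members <- rep_len(n_members, nrow(groups))
  groups$homolog <- vapply(seq_len(nrow(groups)), function(i)
    assign_group_homolog(hits[[groups$group_id[i]]], n_members[i], ...),
    character(1))
  groups <- build_colinear_segments(groups, outgroup_order)
  classify_ancestry(groups)
}
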