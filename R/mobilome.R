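# Mobile-ome discovery: a directed graph of sequence nestedness over sSV
# presence alleles, node merging, TE-content categorisation and ORF-based
# classification of unannotated elements.

#' Pairwise nestedness edges among sequences
#'
#' An edge A -> B (A nested in B) exists iff |A| <= |B| and local-alignment
#' hits of A against B, merged over overlaps, cover at least
#' \code{threshold} of A at identity >= \code{threshold}. Hits are maximal
#' exact matches of at least \code{min_run} nt, so hit identity is exact;
#' short polymorphic interruptions only reduce coverage. Sequences shorter
#' than \code{min_len} are excluded.
#'
#' @param sequences named character vector
#' @param threshold nestedness similarity threshold
#' @param min_len minimum sequence length for graph membership (nt)
#' @param k seed length
#' @param min_run minimal exact-hit length (nt)
#' @return data.frame (nested_id, container_id, coverage)
#' @export
pairwise_nestedness <- function(sequences, threshold = 0.85, min_len = 100L,
                                k = 13L, min_run = 16L) {
  sequences <- sequences[nchar(sequences) >= min_len]
  ids <- names(sequences)
  if (length(sequences) && is.null(ids)) .stopf("sequences must be named")
  n <- length(sequences)
  edges <- list()
  if (n >= 2L) {
    lens <- nchar(sequences)
    o <- order(lens, ids)      # process shorter (potential nested) first
    idxs <- lapply(sequences, function(s) .kmer_index(list(s), k))
    for (ii in seq_len(n)) {
      i <- o[ii]
      qk <- .kmer_codes(sequences[[i]], k)
      for (jj in seq_len(n)) {
        j <- o[jj]
        if (i == j || lens[i] > lens[j]) next
        seeds <- .seed_hits(sequences[[i]], idxs[[j]], k, qk = qk)
        runs <- .exact_runs(seeds, k)
        runs <- runs[runs$len >= min_run, ]
        if (nrow(runs) == 0L) next
        cov <- .interval_union_len(runs$qstart, runs$qend) / lens[i]
        if (cov >= threshold)
          edges[[length(edges) + 1L]] <- data.frame(
            nested_id = ids[i], container_id = ids[j], coverage = cov,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges)) do.call(rbind, edges) else
    data.frame(nested_id = character(0), container_id = character(0),
               coverage = numeric(0))
}

#' Build the graph of nestedness
#'
#' All input sequences become nodes (sequences without edges are isolated
#' nodes); weakly connected components are computed and are expected to
#' approximate mobile-element families.
#'
#' @param edges data.frame from \code{\link{pairwise_nestedness}}
#' @param sequences the named sequences the edges were computed over
#' @return object of class \code{nestedness_graph}: list with \code{nodes}
#'   (node_id, length, te_category, members, component), \code{edges}, and
#'   the underlying \code{igraph} object in \code{graph}
#' @export
build_graph <- function(edges, sequences) {
  ids <- names(sequences)
  g <- igraph::graph_from_data_frame(
    edges[, c("nested_id", "container_id"), drop = FALSE],
    directed = TRUE, vertices = data.frame(name = ids %||% character(0)))
  comp <- if (length(ids)) igraph::components(g, mode = "weak")$membership else
    integer(0)
  ids <- ids %||% character(0)
  nodes <- data.frame(node_id = ids,
                      length = if (length(ids)) unname(nchar(sequences)) else integer(0),
                      te_category = rep(NA_character_, length(ids)),
                      members = rep(1L, length(ids)),
                      component = as.integer(comp),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, graph = g,
                 member_map = stats::setNames(ids, ids)),
            class = "nestedness_graph")
}

#' @export
print.nestedness_graph <- function(x, ...) {
  cat("nestedness_graph:", nrow(x$nodes), "node(s),", nrow(x$edges),
      "edge(s),", length(unique(x$nodes$component)), "component(s)\n")
  invisible(x)
}

#' Merge mutually nested nodes
#'
#' Nodes connected by mutual edges whose coverages are both at least
#' \code{merge_threshold} collapse into a single node whose size is the
#' member count; edges are re-attached to the merged nodes and deduplicated
#' (self-edges dropped).
#'
#' @param graph a \code{nestedness_graph}
#' @param merge_threshold mutual-coverage threshold
#' @return the merged \code{nestedness_graph}; \code{member_map} maps every
#'   original sequence id to its merged node id
#' @export
merge_nodes <- function(graph, merge_threshold = 0.85) {
  e <- graph$edges
  if (nrow(e)) {
    key_f <- paste(e$nested_id, e$container_id, sep = "\r")
    key_r <- paste(e$container_id, e$nested_id, sep = "\r")
    mutual <- e$coverage >= merge_threshold & (key_r %in% key_f[e$coverage >= merge_threshold])
    me <- e[mutual, , drop = FALSE]
  } else me <- e
  ug <- igraph::graph_from_data_frame(
    me[, c("nested_id", "container_id"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = graph$nodes$node_id))
  grp <- igraph::components(ug)$membership
  # representative: first member in node-table order
  reps <- tapply(graph$nodes$node_id, grp, function(x) x[1L])
  member_map <- stats::setNames(unname(reps[as.character(grp)]), graph$nodes$node_id)
  sizes <- table(member_map)
  keep <- graph$nodes$node_id %in% unname(reps)
  nodes <- graph$nodes[keep, , drop = FALSE]
  nodes$members <- as.integer(sizes[nodes$node_id])
  e2 <- graph$edges
  if (nrow(e2)) {
    e2$nested_id <- unname(member_map[e2$nested_id])
    e2$container_id <- unname(member_map[e2$container_id])
    e2 <- e2[e2$nested_id != e2$container_id, , drop = FALSE]
    if (nrow(e2)) {
      key <- paste(e2$nested_id, e2$container_id, sep = "\r")
      agg <- tapply(e2$coverage, key, max)
      sp <- strsplit(names(agg), "\r", fixed = TRUE)
      e2 <- data.frame(nested_id = vapply(sp, `[`, "", 1L),
                       container_id = vapply(sp, `[`, "", 2L),
                       coverage = as.numeric(agg), stringsAsFactors = FALSE)
    }
  }
  g <- igraph::graph_from_data_frame(
    e2[, c("nested_id", "container_id"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = nodes$node_id))
  comp <- igraph::components(g, mode = "weak")$membership
  nodes$component <- as.integer(comp[nodes$node_id])
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = e2, graph = g,
                 member_map = member_map),
            class = "nestedness_graph")
}

#' Categorise the TE content of a sequence
#'
#' Computes (a) the fraction of the sequence covered by merged hits against
#' the TE library and (b) the maximum fraction of any single matched element
#' covered by its hits, then assigns: is_complete (a and b high), i.e. the
#' sequence essentially is a full element; contains_complete (full element
#' plus extra sequence); is_fragment (pure piece of an element);
#' contains_fragment (partial element plus extra sequence); none (no hits).
#'
#' @param sequence character scalar
#' @param te_annotations a \code{te_annotation_set} or \code{te_library}
#' @param cov_threshold coverage threshold for "complete"/"is" calls
#' @param k,min_run hit parameters (see \code{\link{pairwise_nestedness}})
#' @return list(category, seq_coverage = a, max_element_coverage = b,
#'   best_element)
#' @export
te_content_category <- function(sequence, te_annotations, cov_threshold = 0.85,
                                k = 13L, min_run = 16L) {
  elements <- if (inherits(te_annotations, "te_annotation_set"))
    te_annotations$elements else
      data.frame(element_id = te_annotations$family_id,
                 sequence = te_annotations$sequence, stringsAsFactors = FALSE)
  if (nrow(elements) == 0L) .stopf("TE annotation set is empty")
  seq_iv <- list(); b <- 0; best <- NA_character_
  for (i in seq_len(nrow(elements))) {
    el <- elements$sequence[i]
    if (nchar(sequence) < k || nchar(el) < k) next
    idx <- .kmer_index(list(el), k)
    seeds <- .seed_hits(sequence, idx, k)
    runs <- .exact_runs(seeds, k)
    runs <- runs[runs$len >= min_run, ]
    if (nrow(runs) == 0L) next
    seq_iv[[length(seq_iv) + 1L]] <- runs[, c("qstart", "qend")]
    el_cov <- .interval_union_len(runs$rstart, runs$rend) / nchar(el)
    if (el_cov > b) { b <- el_cov; best <- elements$element_id[i] }
  }
  if (!length(seq_iv))
    return(list(category = "none", seq_coverage = 0,
                max_element_coverage = 0, best_element = NA_character_))
  iv <- do.call(rbind, seq_iv)
  a <- .interval_union_len(iv$qstart, iv$qend) / nchar(sequence)
  category <- if (a >= cov_threshold && b >= cov_threshold) "is_complete"
  else if (a < cov_threshold && b >= cov_threshold) "contains_complete"
  else if (a >= cov_threshold && b < cov_threshold) "is_fragment"
  else "contains_fragment"
  list(category = category, seq_coverage = a, max_element_coverage = b,
       best_element = best)
}

#' Six-frame open reading frame scan
#'
#' Translates all six frames with the standard genetic code, splits each
#' frame on stop codons, and returns all stop-free stretches longer than 100
#' codons; if none exist, the single longest stretch is returned provided it
#' exceeds 30 codons, otherwise nothing.
#'
#' @param sequence character scalar (>= 93 nt)
#' @param long_codons "all stretches" length cutoff (codons, exclusive)
#' @param min_codons fallback single-stretch cutoff (codons, exclusive)
#' @return data.frame (frame, start_codon, n_codons, aa); zero rows when no
#'   stretch qualifies
#' @export
orf_scan <- function(sequence, long_codons = 100L, min_codons = 30L) {
  if (nchar(sequence) < 93L) .stopf("sequence must be at least 93 nt (31 codons)")
  frames <- .six_frame_stretches(sequence)
  long <- frames[frames$n_codons > long_codons, , drop = FALSE]
  if (nrow(long)) { rownames(long) <- NULL; return(long) }
  ok <- frames[frames$n_codons > min_codons, , drop = FALSE]
  if (!nrow(ok)) return(frames[0L, , drop = FALSE])
  best <- ok[order(-ok$n_codons, ok$frame, ok$start_codon)[1L], , drop = FALSE]
  rownames(best) <- NULL
  best
}

# all stop-free amino-acid stretches in the six frames; translation is a
# vectorised lookup into the standard genetic code (codons with N -> X)
.six_frame_stretches <- function(sequence) {
  gc_tab <- Biostrings::GENETIC_CODE
  rc <- revcomp(sequence)
  out <- list()
  for (f in 1:6) {
    s <- if (f <= 3L) sequence else rc
    off <- ((f - 1L) %% 3L)
    ncod <- (nchar(s) - off) %/% 3L
    if (ncod == 0L) next
    starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
    cods <- substring(s, starts, starts + 2L)
    aa_v <- unname(gc_tab[cods])
    aa_v[is.na(aa_v)] <- "X"
    aa <- paste(aa_v, collapse = "")
    parts <- strsplit(aa, "*", fixed = TRUE)[[1L]]
    if (!length(parts)) next
    starts <- cumsum(c(1L, nchar(parts[-length(parts)]) + 1L))
    keep <- nchar(parts) > 0L
    if (!any(keep)) next
    out[[f]] <- data.frame(frame = f, start_codon = starts[keep],
                           n_codons = nchar(parts[keep]), aa = parts[keep],
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(0), start_codon = integer(0),
               n_codons = integer(0), aa = character(0))
  rownames(res) <- NULL
  res
}

#' Classify protein BLAST hit descriptions
#'
#' Keyword classifier over free-text hit descriptions: "te_like" when any
#' description contains a transposition-related keyword; "undefined_protein"
#' when every description is an uninformative placeholder; "no_protein" for
#' an empty collection; "defined_protein" otherwise.
#'
#' @param hit_descriptions character vector of hit descriptions (may be
#'   empty)
#' @return one of "te_like", "undefined_protein", "defined_protein",
#'   "no_protein"
#' @export
classify_protein_hits <- function(hit_descriptions) {
  if (length(hit_descriptions) == 0L) return("no_protein")
  te_kw <- c("transcriptase", "reverse", "transpos", "gag-", "pol-",
             "integrase", "gag/pol", "gagpol", "retrovirus",
             "RNA-directed DNA polymerase", "RNA-dependent DNA polymerase")
  undef_kw <- c("hypothetical protein", "unnamed protein product",
                "uncharacterized protein", "predicted protein", "PREDICTED:",
                "putative protein", "unknown")
  d <- tolower(hit_descriptions)
  if (any(vapply(tolower(te_kw), function(k) any(grepl(k, d, fixed = TRUE)),
                 logical(1))))
    return("te_like")
  is_undef <- vapply(d, function(x)
    any(vapply(tolower(undef_kw), function(k) grepl(k, x, fixed = TRUE),
               logical(1))), logical(1))
  if (all(is_undef)) return("undefined_protein")
  "defined_protein"
}

#' Discover the mobile-ome from classified SVs
#'
#' Convenience wrapper: takes the sSV presence alleles (consensus per locus),
#' computes nestedness edges, builds the graph and merges mutually nested
#' nodes. When a TE annotation is supplied, nodes are TE-categorised before
#' merging.
#'
#' @param svs a classified \code{sv_set}
#' @param te_annotations optional \code{te_annotation_set}/\code{te_library}
#' @param threshold nestedness similarity threshold
#' @param min_len minimum presence-allele length (nt)
#' @param merge TRUE to merge mutually nested nodes
#' @return a \code{nestedness_graph}
#' @export
mobilome_graph <- function(svs, te_annotations = NULL, threshold = 0.85,
                           min_len = 100L, merge = TRUE) {
  ssv <- which(svs$class == "sSV")
  seqs <- vapply(ssv, function(i) consensus_allele(svs, i), character(1))
  names(seqs) <- svs$sv_id[ssv]
  seqs <- seqs[nchar(seqs) >= min_len]
  edges <- pairwise_nestedness(seqs, threshold = threshold, min_len = min_len)
  g <- build_graph(edges, seqs)
  if (!is.null(te_annotations)) {
    g$nodes$te_category <- vapply(g$nodes$node_id, function(id)
      te_content_category(seqs[[id]], te_annotations)$category, character(1))
  }
  if (merge) g <- merge_nodes(g, merge_threshold = threshold)
  g
}
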