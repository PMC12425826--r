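# Reference-free multiple alignment: reference rotation, matrix intersection
# and gap-block resolution produce the matrix of corresponding positions
# whose columns are the pangenome coordinate system.

#' Pick rotation references by k-mer distance
#'
#' Chooses the \code{n} most pairwise-distant accessions (Euclidean distance
#' on 6-mer frequency profiles, greedy max-min selection) so that reference
#' bias is probed from spread-out vantage points.
#'
#' @param genomes named list of \code{genome_set}s
#' @param n number of references
#' @return character vector of accession names
#' @export
select_references <- function(genomes, n = 4L) {
  n <- min(n, length(genomes))
  prof <- t(vapply(genomes, function(g) {
    s <- Biostrings::DNAStringSet(paste(g$sequences, collapse = ""))
    f <- Biostrings::oligonucleotideFrequency(s, width = 6L)[1L, ]
    f / sum(f)
  }, numeric(4096L)))
  d <- as.matrix(stats::dist(prof))
  accs <- names(genomes)
  if (n <= 1L) return(accs[1L])
  start <- which(d == max(d), arr.ind = TRUE)[1L, ]
  chosen <- sort(accs[start])
  while (length(chosen) < n) {
    rest <- setdiff(accs, chosen)
    mind <- vapply(rest, function(a) min(d[a, chosen]), numeric(1))
    chosen <- c(chosen, rest[which.max(mind)])
  }
  accs[accs %in% chosen]
}

#' Build reference-biased draft alignments
#'
#' For each chosen reference r, a draft whose columns are r's genome
#' positions, with every other accession's corresponding position filled in
#' from the pairwise correspondence of that accession against r.
#'
#' @param genomes named list of \code{genome_set}s (accession order is the
#'   row order of every matrix)
#' @param references accession subset to rotate as references (>= 2)
#' @param block_size,max_join_gap,min_identity,min_hit_len,k pairwise
#'   alignment parameters (see \code{\link{pairwise_align}})
#' @param verbose print progress
#' @return list of drafts; each draft has \code{reference}, and per reference
#'   chromosome a positions matrix (rows = accessions, 0 = gap) with a
#'   per-accession query-chromosome map in attribute \code{chrom_map}
#' @export
build_reference_matrices <- function(genomes, references,
                                     block_size = 5000L, max_join_gap = 20000L,
                                     min_identity = 0.85, min_hit_len = 100L,
                                     k = 15L, verbose = FALSE) {
  accs <- names(genomes)
  if (length(references) < 2L) .stopf("at least 2 rotation references are required")
  missing <- setdiff(references, accs)
  if (length(missing)) .stopf("reference not in genome set: %s", missing[1L])
  drafts <- vector("list", length(references))
  names(drafts) <- references
  # query k-mer codes and reference indexes are shared across the rotation
  qk_cache <- lapply(genomes, function(g)
    lapply(g$sequences, function(s)
      list(fwd = .kmer_codes(s, k), rev = .kmer_codes(revcomp(s), k))))
  for (r in references) {
    ref <- genomes[[r]]
    ridx <- .kmer_index(ref$sequences, k)
    ref_chroms <- names(ref$sequences)
    mats <- lapply(ref$sequences, function(s) {
      m <- matrix(0L, nrow = length(accs), ncol = nchar(s),
                  dimnames = list(accs, NULL))
      m[r, ] <- seq_len(nchar(s))
      m
    })
    chrom_maps <- lapply(ref_chroms, function(ch)
      stats::setNames(ifelse(accs == r, ch, NA_character_), accs))
    names(chrom_maps) <- ref_chroms
    for (q in setdiff(accs, r)) {
      if (verbose) message("  pairwise ", q, " vs ", r)
      blocks <- chop_blocks(genomes[[q]], block_size)
      hq <- .anchor_blocks_idx(blocks, ridx, ref$sequences, min_identity,
                               min_hit_len, k, qkmer_cache = qk_cache[[q]])
      cmq <- chain_and_fill(hq, genomes[[q]], ref, max_join_gap, min_identity)
      for (qchrom in names(cmq$chrom)) {
        ch <- cmq$chrom[[qchrom]]
        for (ci in unique(ch$ref_chrom_id[ch$ref_chrom_id > 0L])) {
          rchrom <- cmq$ref_chroms[ci]
          sel <- which(ch$ref_chrom_id == ci)
          # dominant query chromosome wins this reference chromosome
          cur <- chrom_maps[[rchrom]][q]
          if (is.na(cur)) {
            chrom_maps[[rchrom]][q] <- qchrom
          } else if (cur != qchrom) {
            prev_n <- sum(mats[[rchrom]][q, ] > 0L)
            if (length(sel) <= prev_n) next
            mats[[rchrom]][q, ] <- 0L
            chrom_maps[[rchrom]][q] <- qchrom
          }
          mats[[rchrom]][q, ch$ref_pos[sel]] <- sel
        }
      }
    }
    for (ch in ref_chroms) attr(mats[[ch]], "chrom_map") <- chrom_maps[[ch]]
    drafts[[r]] <- list(reference = r, matrices = mats)
  }
  drafts
}

# column keys: per accession "chromid:pos", "." for gap, joined with "|"
.draft_keys <- function(mat, chrom_map, all_chroms) {
  n <- nrow(mat)
  parts <- vector("list", n)
  for (a in seq_len(n)) {
    cid <- match(chrom_map[a], all_chroms)
    v <- mat[a, ]
    p <- ifelse(v > 0L, paste0(cid, ":", v), ".")
    parts[[a]] <- p
  }
  do.call(paste, c(parts, sep = "|"))
}

#' Intersect reference-biased drafts into a skeleton alignment
#'
#' A column (a tuple of per-accession positions) survives only if the
#' identical correspondence tuple appears in every draft. The result is
#' invariant to draft order; surviving columns keep the first draft's order.
#'
#' @param drafts list from \code{\link{build_reference_matrices}}
#' @return skeleton: per pangenome chromosome, a positions matrix with a
#'   \code{chrom_map} attribute
#' @export
intersect_matrices <- function(drafts) {
  if (length(drafts) < 2L) .stopf("need at least 2 drafts to intersect")
  accs_list <- lapply(drafts, function(d) rownames(d$matrices[[1L]]))
  if (!all(vapply(accs_list, identical, logical(1), accs_list[[1L]])))
    .stopf("drafts are over different accession sets")
  accs <- accs_list[[1L]]
  refs <- vapply(drafts, `[[`, "", "reference")
  anchor_ref <- refs[1L]
  # all chromosome labels seen anywhere, fixed order for key encoding
  all_chroms <- unique(unlist(lapply(drafts, function(d)
    unlist(lapply(d$matrices, function(m) attr(m, "chrom_map"))))))
  all_chroms <- all_chroms[!is.na(all_chroms)]

  # per draft: keep only columns where every rotation reference is matched,
  # then pool keys grouped by the first reference's chromosome
  pool <- lapply(drafts, function(d) {
    grp_keys <- list()
    for (rchrom in names(d$matrices)) {
      m <- d$matrices[[rchrom]]
      cmap <- attr(m, "chrom_map")
      ok <- colSums(m[refs, , drop = FALSE] > 0L) == length(refs)
      if (!any(ok)) next
      sub <- m[, ok, drop = FALSE]
      keys <- .draft_keys(sub, cmap, all_chroms)
      g <- cmap[anchor_ref]
      if (is.na(g)) next
      grp_keys[[g]] <- c(grp_keys[[g]], keys)
      attr(grp_keys[[g]], "cols") <- NULL
    }
    grp_keys
  })
  groups <- unique(unlist(lapply(pool, names)))
  skeleton <- list()
  d1 <- drafts[[1L]]
  for (g in groups) {
    keys1 <- pool[[1L]][[g]]
    if (is.null(keys1)) next
    keep <- rep(TRUE, length(keys1))
    for (j in 2L:length(drafts)) {
      kj <- pool[[j]][[g]]
      if (is.null(kj)) { keep[] <- FALSE; break }
      keep <- keep & (keys1 %in% kj)
    }
    if (!any(keep)) next
    # rebuild the surviving columns from the first draft (its order)
    surv <- keys1[keep]
    mat <- .keys_to_matrix(surv, accs)
    cmaps <- lapply(d1$matrices, function(m) attr(m, "chrom_map"))
    cmap <- .consensus_chrom_map(mat, drafts, g, accs, all_chroms)
    attr(mat, "chrom_map") <- cmap
    skeleton[[g]] <- mat
  }
  skeleton
}

# decode "cid:pos|..." keys back into a positions matrix
.keys_to_matrix <- function(keys, accs) {
  sp <- strsplit(keys, "|", fixed = TRUE)
  n <- length(accs)
  mat <- matrix(0L, nrow = n, ncol = length(keys), dimnames = list(accs, NULL))
  for (a in seq_len(n)) {
    v <- vapply(sp, `[`, "", a)
    pos <- rep(0L, length(v))
    nz <- v != "."
    pos[nz] <- as.integer(sub("^[0-9]+:", "", v[nz]))
    mat[a, ] <- pos
  }
  mat
}

# majority chromosome per accession across drafts for a pangenome chromosome
.consensus_chrom_map <- function(mat, drafts, g, accs, all_chroms) {
  votes <- matrix(0L, nrow = length(accs), ncol = length(all_chroms),
                  dimnames = list(accs, all_chroms))
  for (d in drafts) {
    for (rchrom in names(d$matrices)) {
      cmap <- attr(d$matrices[[rchrom]], "chrom_map")
      if (is.na(cmap[d$reference]) || !identical(unname(cmap[drafts[[1L]]$reference]), g)) next
      for (a in accs) if (!is.na(cmap[a]))
        votes[a, cmap[a]] <- votes[a, cmap[a]] + 1L
    }
  }
  out <- apply(votes, 1L, function(v)
    if (all(v == 0L)) NA_character_ else colnames(votes)[which.max(v)])
  stats::setNames(out, accs)
}

#' Resolve unaligned blocks between skeleton columns
#'
#' For every run of genome positions not captured by the skeleton, the
#' per-accession subsequences between the flanking skeleton columns
#' (chromosome ends count as flanks) are aligned with an internal progressive
#' (center-star) aligner and the resulting columns spliced in. Blocks where
#' any accession's subsequence exceeds \code{max_block} are considered highly
#' diverged and kept as accession-private columns instead.
#'
#' @param skeleton from \code{\link{intersect_matrices}}
#' @param genomes named list of \code{genome_set}s
#' @param max_block largest block length (nt) that is still aligned
#' @param min_identity identity floor for the star alignments
#' @return a \code{pangenome_alignment} (unsorted; see
#'   \code{\link{sort_and_index}})
#' @export
resolve_unaligned_blocks <- function(skeleton, genomes, max_block = 30000L,
                                     min_identity = 0.85) {
  accs <- rownames(skeleton[[1L]])
  chroms_out <- list()
  for (g in names(skeleton)) {
    mat <- skeleton[[g]]
    cmap <- attr(mat, "chrom_map")
    mat <- .drop_nonmonotone_columns(mat)
    m <- ncol(mat)
    # collect unplaced runs per accession with their flanking columns:
    # the run must fall strictly between skeleton columns (lcol, rcol)
    runs <- list()
    for (a in accs) {
      if (is.na(cmap[a])) next
      La <- nchar(genomes[[a]]$sequences[[cmap[a]]])
      cols <- which(mat[a, ] > 0L)
      p <- mat[a, cols]
      addrun <- function(lcol, rcol, s, e) {
        runs[[length(runs) + 1L]] <<- list(acc = a, start = s, end = e,
                                           lcol = lcol, rcol = rcol)
      }
      if (length(p) == 0L) {
        addrun(0L, m + 1L, 1L, La)
        next
      }
      if (p[1L] > 1L) addrun(0L, cols[1L], 1L, p[1L] - 1L)
      if (length(p) > 1L) {
        gi <- which(diff(p) > 1L)
        for (t in gi) addrun(cols[t], cols[t + 1L], p[t] + 1L, p[t + 1L] - 1L)
      }
      if (p[length(p)] < La)
        addrun(cols[length(cols)], m + 1L, p[length(p)] + 1L, La)
    }
    # cluster runs whose flanking-column intervals overlap: runs from
    # different accessions describing the same physical block may see
    # different flanks (an accession can be gapped at the shared flank), so
    # grouping is by interval intersection, and the cluster is spliced after
    # the innermost left flank
    chunks <- list()
    prev <- 0L
    if (length(runs)) {
      o <- order(vapply(runs, `[[`, 0L, "lcol"),
                 vapply(runs, `[[`, 0L, "rcol"))
      runs <- runs[o]
      clusters <- list()
      curL <- -1L; curR <- -1L; cur <- list()
      for (r in runs) {
        if (length(cur) && r$lcol < curR && r$rcol > curL &&
              max(curL, r$lcol) < min(curR, r$rcol)) {
          cur[[length(cur) + 1L]] <- r
          curL <- max(curL, r$lcol); curR <- min(curR, r$rcol)
        } else {
          if (length(cur)) clusters[[length(clusters) + 1L]] <-
              list(key = curL, runs = cur)
          cur <- list(r); curL <- r$lcol; curR <- r$rcol
        }
      }
      clusters[[length(clusters) + 1L]] <- list(key = curL, runs = cur)
      keys <- vapply(clusters, `[[`, 0L, "key")
      clusters <- clusters[order(keys)]
      for (cl in clusters) {
        if (cl$key > prev) {
          chunks[[length(chunks) + 1L]] <- mat[, (prev + 1L):cl$key, drop = FALSE]
          prev <- cl$key
        }
        chunks[[length(chunks) + 1L]] <-
          .resolve_block(cl$runs, genomes, cmap, accs, max_block, min_identity)
      }
    }
    if (prev < m)
      chunks[[length(chunks) + 1L]] <- mat[, (prev + 1L):m, drop = FALSE]
    full <- do.call(cbind, chunks)
    attr(full, "chrom_map") <- cmap
    chroms_out[[g]] <- full
  }
  structure(list(accessions = accs, chroms = chroms_out, genomes = genomes,
                 index = NULL),
            class = "pangenome_alignment")
}

# positional map of a short run onto the center's prefix or suffix,
# whichever matches better; empty map when neither is close
.prefix_suffix_map <- function(s, center, max_mm_frac = 0.34) {
  L <- nchar(s); Cc <- nchar(center)
  if (L == 0L || L > Cc) return(integer(L))
  sb <- .seq_bytes(s)
  pre <- .seq_bytes(substring(center, 1L, L))
  suf <- .seq_bytes(substring(center, Cc - L + 1L, Cc))
  mm_pre <- sum(sb != pre)
  mm_suf <- sum(sb != suf)
  lim <- ceiling(max_mm_frac * L)
  if (min(mm_pre, mm_suf) > lim) return(integer(L))
  if (mm_pre <= mm_suf) seq_len(L) else (Cc - L + 1L):Cc
}

# drop skeleton columns that break any accession's strict monotonicity,
# discarding the minority (weighted-LIS) side of any conflict
.drop_nonmonotone_columns <- function(mat) {
  bad <- integer(0)
  for (a in seq_len(nrow(mat))) {
    nz <- which(mat[a, ] > 0L)
    if (length(nz) < 2L) next
    keep <- .lis_filter(mat[a, nz])
    bad <- c(bad, nz[!keep])
  }
  if (length(bad)) mat <- mat[, -unique(bad), drop = FALSE]
  mat
}

# align one inter-skeleton block: center-star progressive alignment, private
# columns for oversized or unalignable runs; runs left unmatched by the
# center that share a splice point are co-aligned by one recursive pass
# (identical insertions carried by several accessions must merge even when
# the center is an unrelated longer run)
.resolve_block <- function(runs, genomes, cmap, accs, max_block, min_identity,
                           depth = 0L) {
  n <- length(accs)
  seqs <- lapply(runs, function(r)
    substring(genomes[[r$acc]]$sequences[[cmap[r$acc]]], r$start, r$end))
  lens <- vapply(seqs, nchar, integer(1))
  private_cols <- function(sel) {
    mats <- lapply(sel, function(i) {
      m <- matrix(0L, nrow = n, ncol = lens[i], dimnames = list(accs, NULL))
      m[runs[[i]]$acc, ] <- runs[[i]]$start:runs[[i]]$end
      m
    })
    do.call(cbind, mats)
  }
  if (length(runs) == 1L || any(lens > max_block))
    return(private_cols(seq_along(runs)))
  # center-star: longest run is the template
  ci <- which.max(lens)
  center <- seqs[[ci]]
  Cc <- lens[ci]
  others <- setdiff(seq_along(runs), ci)
  base <- matrix(0L, nrow = n, ncol = Cc, dimnames = list(accs, NULL))
  base[runs[[ci]]$acc, ] <- runs[[ci]]$start:runs[[ci]]$end
  # consensus support: center positions whose 13-mers recur in most of the
  # other runs mark the orthologous backbone of the block, so chains through
  # them win over equally long paralogous (e.g. repeat-copy) pairings
  r_support <- NULL
  kk <- 13L
  nonempty <- others[lens[others] >= kk]
  if (Cc >= kk && length(nonempty) >= 2L) {
    cc <- .kmer_codes(center, kk)
    supp <- integer(length(cc))
    for (i in nonempty) supp <- supp + (cc %in% .kmer_codes(seqs[[i]], kk))
    core <- supp >= 0.7 * length(nonempty)
    r_support <- logical(Cc)
    if (any(core)) for (off in 0:(kk - 1L)) r_support[which(core) + off] <- TRUE
  }
  ins <- list()  # list of (key = center offset 0..Cc, acc, positions)
  for (i in others) {
    if (lens[i] < 26L) {
      # sub-seed-length runs: positional match against the equal-length
      # center prefix or suffix (insertion-breakpoint wobble produces these)
      map <- .prefix_suffix_map(seqs[[i]], center)
    } else {
      fa <- fine_align(seqs[[i]], center, k = 13L, min_identity = min_identity,
                       r_support = r_support)
      map <- fa$map
    }
    # guard monotonicity
    nzm <- which(map > 0L)
    if (length(nzm) > 1L) {
      v <- map[nzm]
      cm <- cummax(c(0L, v[-length(v)]))
      map[nzm[v <= cm]] <- 0L
    }
    a <- runs[[i]]$acc
    abs_pos <- runs[[i]]$start:runs[[i]]$end
    sel <- map > 0L
    if (any(sel)) base[a, map[sel]] <- abs_pos[sel]
    # unmapped runs become insertions after their last mapped center position
    un <- which(!sel)
    if (length(un)) {
      brk <- c(TRUE, diff(un) != 1L)
      grp <- cumsum(brk)
      for (gp in split(un, grp)) {
        before <- gp[1L] - 1L
        key <- if (before >= 1L && map[before] > 0L) map[before] else {
          prevmapped <- which(sel[seq_len(max(before, 0L))])
          if (length(prevmapped)) map[max(prevmapped)] else 0L
        }
        ins[[length(ins) + 1L]] <- list(key = key, acc = a, pos = abs_pos[gp])
      }
    }
  }
  if (!length(ins)) return(base)
  # splice insertion columns after their key column; co-spliced runs from
  # different accessions are aligned among themselves first
  ins_key <- vapply(ins, `[[`, 0L, "key")
  chunks <- list()
  prev <- 0L
  for (key in sort(unique(ins_key))) {
    if (key > prev) {
      chunks[[length(chunks) + 1L]] <- base[, (prev + 1L):key, drop = FALSE]
      prev <- key
    }
    grp <- ins[ins_key == key]
    if (length(grp) >= 2L && depth == 0L) {
      sub <- lapply(grp, function(e)
        list(acc = e$acc, start = min(e$pos), end = max(e$pos)))
      chunks[[length(chunks) + 1L]] <-
        .resolve_block(sub, genomes, cmap, accs, max_block, min_identity,
                       depth = 1L)
    } else {
      grp <- grp[order(vapply(grp, function(x) match(x$acc, accs), 0L))]
      for (e in grp) {
        m <- matrix(0L, nrow = n, ncol = length(e$pos),
                    dimnames = list(accs, NULL))
        m[e$acc, ] <- e$pos
        chunks[[length(chunks) + 1L]] <- m
      }
    }
  }
  if (prev < Cc)
    chunks[[length(chunks) + 1L]] <- base[, (prev + 1L):Cc, drop = FALSE]
  do.call(cbind, chunks)
}

#' Sort alignment columns and build the coordinate index
#'
#' Columns are ordered to be increasing in the anchor accession's genome
#' positions (columns where the anchor is gapped keep their relative position
#' after the nearest preceding anchored column); a bidirectional index
#' between genome positions and pangenome columns is built and the alignment
#' invariants are checked.
#'
#' @param aln a \code{pangenome_alignment}
#' @param anchor_order accession preference order for sorting; defaults to
#'   the alignment's accession order
#' @return the sorted, indexed \code{pangenome_alignment}
#' @export
sort_and_index <- function(aln, anchor_order = NULL) {
  anchor_order <- anchor_order %||% aln$accessions
  if (!length(anchor_order)) .stopf("anchor_order must be non-empty")
  anchor <- anchor_order[1L]
  for (g in names(aln$chroms)) {
    mat <- aln$chroms[[g]]
    v <- mat[anchor, ]
    idx <- cumsum(v > 0L)
    nzv <- v[v > 0L]
    key <- ifelse(idx == 0L, 0L, nzv[pmax(idx, 1L)])
    o <- order(key)            # stable: preserves construction order at ties
    cmap <- attr(mat, "chrom_map")
    mat <- mat[, o, drop = FALSE]
    attr(mat, "chrom_map") <- cmap
    aln$chroms[[g]] <- mat
  }
  aln$index <- .build_index(aln)
  validate_alignment(aln)
  aln
}

# per accession, per genome chromosome: column index of every genome position
# (0 where the position is in no column)
.build_index <- function(aln) {
  index <- list()
  for (a in aln$accessions) {
    index[[a]] <- lapply(aln$genomes[[a]]$sequences, function(s) integer(nchar(s)))
  }
  for (g in names(aln$chroms)) {
    mat <- aln$chroms[[g]]
    cmap <- attr(mat, "chrom_map")
    for (a in aln$accessions) {
      ch <- cmap[a]
      if (is.na(ch)) next
      nz <- which(mat[a, ] > 0L)
      pos <- mat[a, nz]
      if (any(index[[a]][[ch]][pos] != 0L))
        .stopf("position of accession '%s' occurs in more than one column", a)
      index[[a]][[ch]][pos] <- nz
    }
  }
  index
}

#' Check the invariants of a pangenome alignment
#'
#' Verifies that every column has at least one non-gap entry, per-accession
#' positions are strictly increasing along columns, and no genome position
#' occurs in more than one column.
#'
#' @param aln a \code{pangenome_alignment}
#' @return invisibly TRUE (errors otherwise)
#' @export
validate_alignment <- function(aln) {
  for (g in names(aln$chroms)) {
    mat <- aln$chroms[[g]]
    if (ncol(mat) && any(colSums(mat > 0L) == 0L))
      .stopf("chromosome '%s' has a column with no non-gap entry", g)
    for (a in rownames(mat)) {
      v <- mat[a, mat[a, ] > 0L]
      if (length(v) > 1L && any(diff(v) <= 0L))
        .stopf("positions of accession '%s' are not strictly increasing on '%s'",
               a, g)
      if (anyDuplicated(v))
        .stopf("duplicated position for accession '%s' on '%s'", a, g)
    }
  }
  invisible(TRUE)
}

#' @export
print.pangenome_alignment <- function(x, ...) {
  nc <- vapply(x$chroms, ncol, integer(1))
  cat("pangenome_alignment:", length(x$accessions), "accessions,",
      length(x$chroms), "chromosome(s),", format(sum(nc), big.mark = ","),
      "columns\n")
  for (g in names(x$chroms))
    cat(sprintf("  %s: %s columns\n", g, format(ncol(x$chroms[[g]]), big.mark = ",")))
  invisible(x)
}

#' Build a reference-free pangenome alignment
#'
#' End-to-end construction: rotation references are chosen by k-mer distance
#' (unless given), reference-biased drafts are built and intersected, the
#' unaligned blocks are resolved, and the alignment is sorted and indexed on
#' the first accession.
#'
#' @param genomes named list of \code{genome_set}s
#' @param references rotation reference accessions; default: the
#'   \code{min(n_references, n)} most k-mer-distant accessions
#' @param n_references number of references when auto-selecting
#' @param max_block gap-block size limit (nt) beyond which blocks stay
#'   unaligned
#' @param verbose print progress
#' @param ... pairwise alignment parameters passed through
#' @return a sorted, indexed \code{pangenome_alignment}
#' @export
build_pangenome_alignment <- function(genomes, references = NULL,
                                      n_references = 4L, max_block = 30000L,
                                      verbose = FALSE, ...) {
  if (length(genomes) < 2L) .stopf("need at least 2 genomes")
  references <- references %||% select_references(genomes, n_references)
  if (verbose) message("references: ", paste(references, collapse = ", "))
  drafts <- build_reference_matrices(genomes, references, verbose = verbose, ...)
  skel <- intersect_matrices(drafts)
  aln <- resolve_unaligned_blocks(skel, genomes, max_block = max_block)
  sort_and_index(aln, anchor_order = names(genomes))
}

#' Construct a pangenome alignment from explicit position matrices
#'
#' Lets callers assemble small alignments directly (e.g. for saturation
#' analyses on constructed inputs). Matrices are rows = accessions, columns =
#' pangenome columns, entries = 1-based genome positions (0 = gap).
#'
#' @param matrices named list (per pangenome chromosome) of integer matrices
#' @param genomes named list of \code{genome_set}s; when NULL, placeholder
#'   genomes matching the positions are synthesised with 'A' bases
#' @param chrom_maps per pangenome chromosome, named character vector mapping
#'   accession to its genome chromosome; defaults to the pangenome
#'   chromosome's own name
#' @return an indexed \code{pangenome_alignment}
#' @export
pangenome_alignment <- function(matrices, genomes = NULL, chrom_maps = NULL) {
  accs <- rownames(matrices[[1L]])
  if (is.null(accs)) .stopf("matrices must have accession rownames")
  if (is.null(genomes)) {
    genomes <- lapply(accs, function(a) {
      seqs <- vapply(names(matrices), function(g) {
        mx <- max(matrices[[g]][a, ], 0L)
        if (mx == 0L) "A" else strrep("A", mx)
      }, character(1))
      genome_set(a, seqs)
    })
    names(genomes) <- accs
  }
  chroms <- list()
  for (g in names(matrices)) {
    m <- matrices[[g]]
    cmap <- if (!is.null(chrom_maps)) chrom_maps[[g]] else
      stats::setNames(rep(g, length(accs)), accs)
    attr(m, "chrom_map") <- cmap
    chroms[[g]] <- m
  }
  aln <- structure(list(accessions = accs, chroms = chroms, genomes = genomes,
                        index = NULL),
                   class = "pangenome_alignment")
  aln$index <- .build_index(aln)
  validate_alignment(aln)
  aln
}
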