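# Synthetic pangenome generator with a machine-readable truth ledger.
#
# The simulator plants SNPs, TE insertions (complete or truncated, shared by
# carrier subsets), deletions and unalignable satellite blocks on a random
# ancestor, then derives each accession's genome by replaying its events.
# Every event is recorded so downstream stages can be scored against ground
# truth.

#' Generate a synthetic TE family library
#'
#' Families are random sequences whose pairwise global-alignment identity is
#' verified to be below \code{max_identity} (rejection sampling), so planted
#' families are cleanly separable by sequence similarity.
#'
#' @param n_families number of families (>= 1)
#' @param length_range (min, max) consensus length in nt; min >= 300
#' @param seed integer seed; the library is deterministic for a fixed seed
#' @param max_identity pairwise identity ceiling (default 0.6)
#' @param max_tries rejection-sampling bound per family
#' @return object of class \code{te_library}: data.frame with columns
#'   family_id, superfamily, length, sequence
#' @export
make_te_library <- function(n_families, length_range = c(400, 6000), seed = 1L,
                            max_identity = 0.6, max_tries = 50L) {
  if (n_families < 1L) .stopf("n_families must be >= 1")
  if (length_range[1L] < 300L) .stopf("minimum family length is 300 nt")
  set.seed(seed)
  superfams <- c("LTR/Copia", "LTR/Gypsy", "DNA/MuDR", "LINE/L1",
                 "DNA/Harbinger", "RC/Helitron", "DNA/HAT", "SINE")
  seqs <- character(n_families)
  for (i in seq_len(n_families)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      cand <- random_dna(len)
      ok <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          if (.global_identity(cand, seqs[j]) >= max_identity) { ok <- FALSE; break }
        }
      }
      if (ok) { seqs[i] <- cand; break }
    }
    if (!ok) .stopf("could not satisfy the %.2f identity constraint after %d tries",
                    max_identity, max_tries)
  }
  lib <- data.frame(
    family_id = sprintf("fam%02d", seq_len(n_families)),
    superfamily = superfams[((seq_len(n_families) - 1L) %% length(superfams)) + 1L],
    length = nchar(seqs), sequence = seqs, stringsAsFactors = FALSE)
  structure(lib, class = c("te_library", "data.frame"))
}

# global-alignment identity (matches / alignment length), via Needleman-Wunsch
.global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1),
                                      gapOpening = 2, gapExtension = 0.5)
  aln_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / aln_len
}

#' Default simulation settings
#'
#' The defaults define the package's standard study conditions: 8 inbred
#' accessions derived from a 2 x 300-kb ancestor under a star genealogy, with
#' a per-lineage substitution rate of 5e-4 per site, 60 TE insertions from a
#' 6-family library (70\% complete, 30\% truncated to a uniform 0.2-0.8
#' fraction), 40 deletions of 15-2,000 nt and 4 unalignable satellite blocks.
#'
#' @param n_accessions number of accessions
#' @param chrom_lengths ancestor chromosome lengths (nt)
#' @param snp_rate per-site, per-lineage substitution probability
#' @param n_insertions total planted TE insertions
#' @param n_deletions total planted deletions
#' @param deletion_length_range (min, max) deletion length in nt
#' @param n_satellites number of unalignable satellite blocks
#' @param te_library a \code{te_library}, or NULL to generate a default
#'   6-family, 400-6,000 nt library from the run seed
#' @param insertion_complete_frac fraction of insertions that are complete
#'   family copies (the rest are truncated fragments)
#' @param truncation_range uniform range for the retained fraction of a
#'   truncated insertion
#' @param carrier_size_probs sampling weights for carrier-set sizes 1..n-1;
#'   default concentrates on 1-3 carriers so presence-frequency polarity is
#'   informative
#' @param satellite_unit_range tandem-repeat unit length range (nt, <= 180)
#' @param satellite_copy_range copies of the unit per array
#' @param satellite_divergence per-site divergence applied independently to
#'   each accession's satellite array (makes the blocks unalignable)
#' @param genealogy "star" (independent lineages) only, currently
#' @param min_event_spacing minimum nt between planted events on the ancestor
#' @param end_margin nt kept event-free at each chromosome end
#' @return a list of settings for \code{\link{simulate_pangenome}}
#' @export
sim_config <- function(n_accessions = 8L,
                       chrom_lengths = c(chr1 = 300000L, chr2 = 300000L),
                       snp_rate = 5e-4,
                       n_insertions = 60L,
                       n_deletions = 40L,
                       deletion_length_range = c(15L, 2000L),
                       n_satellites = 4L,
                       te_library = NULL,
                       insertion_complete_frac = 0.7,
                       truncation_range = c(0.2, 0.8),
                       carrier_size_probs = NULL,
                       satellite_unit_range = c(20L, 180L),
                       satellite_copy_range = c(15L, 40L),
                       satellite_divergence = 0.15,
                       genealogy = "star",
                       min_event_spacing = 300L,
                       end_margin = 2000L) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  if (is.null(carrier_size_probs)) {
    n <- n_accessions
    p <- numeric(max(n - 1L, 1L))
    small <- seq_len(min(3L, n - 1L))
    p[small] <- 0.85 / length(small)
    if (n - 1L > 3L) p[4:(n - 1L)] <- 0.15 / (n - 4L)
    carrier_size_probs <- p / sum(p)
  }
  as.list(environment())
}

#' Simulate a synthetic pangenome with planted ground truth
#'
#' Each accession genome equals the ancestor with its lineage's events
#' applied; the returned truth ledger records every event with enough detail
#' to reproduce the genomes exactly (see \code{\link{apply_truth}}).
#'
#' @param config settings from \code{\link{sim_config}}
#' @param seed integer seed; identical seeds give identical output
#' @return list with elements \code{genomes} (list of \code{genome_set}),
#'   \code{truth} (class \code{planted_truth}) and \code{ancestor}
#'   (\code{genome_set})
#' @export
simulate_pangenome <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  n <- cfg$n_accessions
  accs <- sprintf("acc%02d", seq_len(n))
  if (!identical(cfg$genealogy, "star"))
    .stopf("only the star genealogy is implemented")

  lib <- cfg$te_library %||%
    make_te_library(6L, c(400L, 6000L), seed = seed + 1000L)

  # ancestor
  anc <- lapply(cfg$chrom_lengths, random_dna)
  names(anc) <- names(cfg$chrom_lengths)

  # --- place non-overlapping event intervals on the ancestor -------------
  # Each event occupies [start, end] on the ancestor (insertions are points:
  # the new sequence goes between start and start+1, end == start).
  total_len <- sum(cfg$chrom_lengths)
  n_events <- cfg$n_insertions + cfg$n_deletions + cfg$n_satellites
  placed <- vector("list", length(cfg$chrom_lengths))
  names(placed) <- names(cfg$chrom_lengths)

  ev_chrom <- sample(names(cfg$chrom_lengths), n_events, replace = TRUE,
                     prob = cfg$chrom_lengths / total_len)
  # event spans on the ancestor
  kinds <- c(rep("insertion", cfg$n_insertions),
             rep("deletion", cfg$n_deletions),
             rep("satellite", cfg$n_satellites))
  del_len <- sample(cfg$deletion_length_range[1L]:cfg$deletion_length_range[2L],
                    cfg$n_deletions, replace = TRUE)
  sat_unit_len <- sample(cfg$satellite_unit_range[1L]:cfg$satellite_unit_range[2L],
                         cfg$n_satellites, replace = TRUE)
  sat_copies <- sample(cfg$satellite_copy_range[1L]:cfg$satellite_copy_range[2L],
                       cfg$n_satellites, replace = TRUE)
  span <- integer(n_events)
  span[kinds == "insertion"] <- 1L
  span[kinds == "deletion"] <- del_len
  span[kinds == "satellite"] <- sat_unit_len * sat_copies

  starts <- integer(n_events)
  occupied <- lapply(cfg$chrom_lengths, function(L)
    data.frame(start = integer(0), end = integer(0)))
  for (i in seq_len(n_events)) {
    chrom <- ev_chrom[i]
    L <- cfg$chrom_lengths[[chrom]]
    lo <- cfg$end_margin; hi <- L - cfg$end_margin - span[i]
    if (hi <= lo) .stopf("chromosome '%s' too short for planted events", chrom)
    ok <- FALSE
    for (try in seq_len(500L)) {
      s <- sample(lo:hi, 1L)
      e <- s + span[i] - 1L
      occ <- occupied[[chrom]]
      if (!any(s - cfg$min_event_spacing <= occ$end &
                 e + cfg$min_event_spacing >= occ$start)) {
        occupied[[chrom]] <- rbind(occ, data.frame(start = s, end = e))
        starts[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) .stopf("event density too high: could not place all events without overlap")
  }

  draw_carriers <- function() {
    k <- sample.int(length(cfg$carrier_size_probs), 1L, prob = cfg$carrier_size_probs)
    sort(sample.int(n, k))
  }
  carr_str <- function(ix) paste(accs[ix], collapse = ",")

  # --- insertions --------------------------------------------------------
  ins_idx <- which(kinds == "insertion")
  insertions <- NULL
  if (length(ins_idx)) {
    fam_pick <- sample.int(nrow(lib), length(ins_idx), replace = TRUE)
    complete <- stats::runif(length(ins_idx)) < cfg$insertion_complete_frac
    seqs <- character(length(ins_idx))
    for (j in seq_along(ins_idx)) {
      fs <- lib$sequence[fam_pick[j]]
      if (complete[j]) {
        seqs[j] <- fs
      } else {
        frac <- stats::runif(1L, cfg$truncation_range[1L], cfg$truncation_range[2L])
        keep <- max(50L, round(frac * nchar(fs)))
        off <- sample.int(nchar(fs) - keep + 1L, 1L)
        seqs[j] <- substring(fs, off, off + keep - 1L)
      }
    }
    insertions <- data.frame(
      event_id = sprintf("ins%03d", seq_along(ins_idx)),
      chrom = ev_chrom[ins_idx], anc_pos = starts[ins_idx],
      family_id = lib$family_id[fam_pick], complete = complete,
      length = nchar(seqs), sequence = seqs,
      carriers = vapply(seq_along(ins_idx), function(j) carr_str(draw_carriers()),
                        character(1)),
      stringsAsFactors = FALSE)
  } else {
    insertions <- data.frame(event_id = character(0), chrom = character(0),
                             anc_pos = integer(0), family_id = character(0),
                             complete = logical(0), length = integer(0),
                             sequence = character(0), carriers = character(0))
  }

  # --- deletions ---------------------------------------------------------
  del_idx <- which(kinds == "deletion")
  deletions <- data.frame(
    event_id = sprintf("del%03d", seq_along(del_idx)),
    chrom = ev_chrom[del_idx], anc_start = starts[del_idx],
    anc_end = starts[del_idx] + span[del_idx] - 1L,
    length = span[del_idx],
    carriers = vapply(seq_along(del_idx), function(j) carr_str(draw_carriers()),
                      character(1)),
    stringsAsFactors = FALSE)

  # --- satellites --------------------------------------------------------
  sat_idx <- which(kinds == "satellite")
  sat_units <- vapply(sat_unit_len, random_dna, character(1))
  satellites <- data.frame(
    block_id = sprintf("sat%02d", seq_along(sat_idx)),
    chrom = ev_chrom[sat_idx], anc_start = starts[sat_idx],
    anc_end = starts[sat_idx] + span[sat_idx] - 1L,
    unit = sat_units, copies = sat_copies, stringsAsFactors = FALSE)
  # plant the ancestral arrays
  for (j in seq_along(sat_idx)) {
    chrom <- satellites$chrom[j]
    arr <- strrep(satellites$unit[j], satellites$copies[j])
    substr(anc[[chrom]], satellites$anc_start[j], satellites$anc_end[j]) <- arr
  }
  # per-accession divergent arrays (independent unit mutation + copy jitter)
  sat_arrays <- NULL
  if (nrow(satellites)) {
    rows <- list()
    for (j in seq_len(nrow(satellites))) {
      for (a in seq_len(n)) {
        u <- .mutate_seq(satellites$unit[j], cfg$satellite_divergence)
        cp <- max(3L, round(satellites$copies[j] *
                              stats::runif(1L, 0.7, 1.3)))
        rows[[length(rows) + 1L]] <- data.frame(
          block_id = satellites$block_id[j], accession = accs[a],
          sequence = strrep(u, cp), stringsAsFactors = FALSE)
      }
    }
    sat_arrays <- do.call(rbind, rows)
  } else {
    sat_arrays <- data.frame(block_id = character(0), accession = character(0),
                             sequence = character(0))
  }

  # --- SNPs --------------------------------------------------------------
  # Sampled per lineage outside all event intervals; sites are de-duplicated
  # across lineages so each ancestor site carries one derived base.
  blocked <- lapply(names(cfg$chrom_lengths), function(chrom) {
    occ <- occupied[[chrom]]
    m <- .merge_intervals(occ$start, occ$end)
    m
  })
  names(blocked) <- names(cfg$chrom_lengths)
  snp_rows <- list()
  if (cfg$snp_rate > 0) {
    for (a in seq_len(n)) {
      for (chrom in names(cfg$chrom_lengths)) {
        L <- cfg$chrom_lengths[[chrom]]
        k <- stats::rbinom(1L, L, cfg$snp_rate)
        if (k == 0L) next
        pos <- sample.int(L, k)
        bl <- blocked[[chrom]]
        if (nrow(bl)) {
          inblk <- vapply(pos, function(p) any(p >= bl$start & p <= bl$end),
                          logical(1))
          pos <- pos[!inblk]
        }
        pos <- pos[pos > 10L & pos < L - 10L]
        if (length(pos) == 0L) next
        anc_b <- substring(anc[[chrom]], pos, pos)
        der <- vapply(anc_b, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                      character(1), USE.NAMES = FALSE)
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          chrom = chrom, anc_pos = pos, anc_base = anc_b, derived_base = der,
          carriers = accs[a], stringsAsFactors = FALSE)
      }
    }
  }
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(chrom = character(0), anc_pos = integer(0), anc_base = character(0),
               derived_base = character(0), carriers = character(0))
  if (nrow(snps)) {
    snps <- snps[!duplicated(snps[, c("chrom", "anc_pos")]), ]
    snps <- snps[order(snps$chrom, snps$anc_pos), ]
    rownames(snps) <- NULL
  }

  truth <- structure(list(
    accessions = accs,
    chrom_lengths = cfg$chrom_lengths,
    snps = snps, insertions = insertions, deletions = deletions,
    satellites = satellites, satellite_arrays = sat_arrays,
    te_library = lib), class = "planted_truth")

  ancestor <- genome_set("ancestor", unlist(anc))
  genomes <- lapply(accs, function(a) apply_truth(ancestor, truth, a))
  names(genomes) <- accs
  list(genomes = genomes, truth = truth, ancestor = ancestor)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", length(x$accessions), "accessions |",
      nrow(x$snps), "SNPs,", nrow(x$insertions), "insertions,",
      nrow(x$deletions), "deletions,", nrow(x$satellites), "satellite blocks\n")
  invisible(x)
}

.parse_carriers <- function(s) strsplit(s, ",", fixed = TRUE)[[1L]]

#' Replay a truth ledger for one accession
#'
#' Applies the recorded SNPs and events of \code{accession} to the ancestor,
#' reproducing that accession's genome exactly. This is the canonical event
#' semantics: insertions go after \code{anc_pos}, deletions remove
#' [anc_start, anc_end], satellite blocks are replaced by the accession's
#' recorded array.
#'
#' @param ancestor the ancestor \code{genome_set}
#' @param truth a \code{planted_truth}
#' @param accession accession label
#' @return that accession's \code{genome_set}
#' @export
apply_truth <- function(ancestor, truth, accession) {
  out <- lapply(names(ancestor$sequences), function(chrom)
    .apply_events_chrom(ancestor$sequences[[chrom]], truth, accession, chrom)$seq)
  names(out) <- names(ancestor$sequences)
  genome_set(accession, unlist(out))
}

# Replay events on one chromosome; returns the derived sequence plus both
# coordinate maps (ancestor -> accession and accession -> ancestor, NA where
# a position has no counterpart).
.apply_events_chrom <- function(anc_seq, truth, accession, chrom) {
  L <- nchar(anc_seq)
  b <- .seq_bytes(anc_seq)
  # SNPs carried by this accession
  sn <- truth$snps[truth$snps$chrom == chrom, , drop = FALSE]
  if (nrow(sn)) {
    mine <- vapply(sn$carriers, function(s) accession %in% .parse_carriers(s),
                   logical(1), USE.NAMES = FALSE)
    if (any(mine))
      b[sn$anc_pos[mine]] <- .seq_bytes(paste(sn$derived_base[mine], collapse = ""))
  }
  mut <- .bytes_seq(b)

  # structural events on this chromosome, in ancestor order
  evs <- list()
  ins <- truth$insertions[truth$insertions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    if (!(accession %in% .parse_carriers(ins$carriers[i]))) next
    evs[[length(evs) + 1L]] <- list(type = "ins", start = ins$anc_pos[i],
                                    end = ins$anc_pos[i], seq = ins$sequence[i])
  }
  del <- truth$deletions[truth$deletions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(del))) {
    if (!(accession %in% .parse_carriers(del$carriers[i]))) next
    evs[[length(evs) + 1L]] <- list(type = "del", start = del$anc_start[i],
                                    end = del$anc_end[i])
  }
  sat <- truth$satellites[truth$satellites$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sat))) {
    arr <- truth$satellite_arrays
    row <- arr[arr$block_id == sat$block_id[i] & arr$accession == accession, ]
    evs[[length(evs) + 1L]] <- list(type = "sat", start = sat$anc_start[i],
                                    end = sat$anc_end[i], seq = row$sequence[1L])
  }
  if (length(evs)) {
    o <- order(vapply(evs, `[[`, 0, "start"))
    evs <- evs[o]
  }

  chunks <- character(0)
  anc2acc <- rep(NA_integer_, L)
  out_len <- 0L
  cur <- 1L
  for (ev in evs) {
    if (ev$start >= cur) {
      seg_end <- if (ev$type == "ins") ev$start else ev$start - 1L
      if (seg_end >= cur) {
        seg <- substring(mut, cur, seg_end)
        chunks <- c(chunks, seg)
        anc2acc[cur:seg_end] <- out_len + seq_len(seg_end - cur + 1L)
        out_len <- out_len + (seg_end - cur + 1L)
      }
    }
    if (ev$type == "ins") {
      chunks <- c(chunks, ev$seq)
      out_len <- out_len + nchar(ev$seq)
      cur <- ev$start + 1L
    } else if (ev$type == "del") {
      cur <- ev$end + 1L
    } else { # satellite replacement
      chunks <- c(chunks, ev$seq)
      out_len <- out_len + nchar(ev$seq)
      cur <- ev$end + 1L
    }
  }
  if (cur <= L) {
    seg <- substring(mut, cur, L)
    chunks <- c(chunks, seg)
    anc2acc[cur:L] <- out_len + seq_len(L - cur + 1L)
    out_len <- out_len + (L - cur + 1L)
  }
  seq <- paste(chunks, collapse = "")
  acc2anc <- rep(NA_integer_, out_len)
  ok <- !is.na(anc2acc)
  acc2anc[anc2acc[ok]] <- which(ok)
  list(seq = seq, anc2acc = anc2acc, acc2anc = acc2anc)
}

#' Ancestor/accession coordinate maps implied by a truth ledger
#'
#' @param ancestor ancestor \code{genome_set}
#' @param truth a \code{planted_truth}
#' @param accession accession label
#' @return per chromosome, a list with integer vectors \code{anc2acc}
#'   (accession coordinate of each ancestor position, NA if deleted or
#'   replaced) and \code{acc2anc} (the inverse, NA inside insertions and
#'   satellite arrays)
#' @export
truth_coord_maps <- function(ancestor, truth, accession) {
  out <- lapply(names(ancestor$sequences), function(chrom) {
    r <- .apply_events_chrom(ancestor$sequences[[chrom]], truth, accession, chrom)
    list(anc2acc = r$anc2acc, acc2anc = r$acc2anc)
  })
  names(out) <- names(ancestor$sequences)
  out
}

#' Simulate an error-prone SNP call set against a truth set
#'
#' Emulates reference-based short-read calling: a fraction of sites is
#' uncovered, a fraction of covered truth SNPs is missed (false negatives),
#' false calls are added to reach a target false-discovery rate, and a number
#' of (always false) heterozygous calls is injected.
#'
#' @param truth_positions integer positions of true SNPs (single reference
#'   frame, 1-based)
#' @param n_sites number of sites in the reference frame
#' @param fdr_target target false-discovery rate in [0, 1)
#' @param fnr_target target false-negative rate in [0, 1]
#' @param uncovered_fraction fraction of sites without read coverage
#' @param het_count number of heterozygous calls to inject
#' @param seed integer seed
#' @return list with \code{calls} (data.frame pos, het) and \code{covered}
#'   (logical vector of length \code{n_sites})
#' @export
simulate_call_set <- function(truth_positions, n_sites,
                              fdr_target = 0, fnr_target = 0,
                              uncovered_fraction = 0, het_count = 0L,
                              seed = 1L) {
  if (fdr_target >= 1 || fdr_target < 0) .stopf("fdr_target must be in [0, 1)")
  if (fnr_target > 1 || fnr_target < 0) .stopf("fnr_target must be in [0, 1]")
  if (any(truth_positions < 1L) || any(truth_positions > n_sites))
    .stopf("truth positions outside 1..n_sites")
  set.seed(seed)
  covered <- rep(TRUE, n_sites)
  if (uncovered_fraction > 0)
    covered[sample.int(n_sites, round(uncovered_fraction * n_sites))] <- FALSE
  truth_cov <- truth_positions[covered[truth_positions]]
  drop <- stats::runif(length(truth_cov)) < fnr_target
  tp <- truth_cov[!drop]
  n_fp <- if (fdr_target > 0)
    max(0L, round(fdr_target / (1 - fdr_target) * length(tp))) else 0L
  het_count <- min(het_count, n_fp)
  free <- setdiff(which(covered), truth_positions)
  if (n_fp > length(free)) .stopf("not enough non-truth covered sites for false calls")
  fp <- if (n_fp > 0L) sample(free, n_fp) else integer(0)
  het <- rep(FALSE, length(tp) + length(fp))
  if (het_count > 0L && length(fp))
    het[length(tp) + seq_len(het_count)] <- TRUE
  calls <- data.frame(pos = c(tp, fp), het = het)
  calls <- calls[order(calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, covered = covered)
}

#' Write a truth ledger as TSV files
#'
#' @param truth a \code{planted_truth}
#' @param out_dir output directory
#' @return invisibly, the files written
#' @export
write_truth_tsv <- function(truth, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (nm in c("snps", "insertions", "deletions", "satellites", "satellite_arrays")) {
    f <- file.path(out_dir, paste0("truth_", nm, ".tsv"))
    write_table_tsv(truth[[nm]], f)
    files <- c(files, f)
  }
  invisible(files)
}
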