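# Shared fixtures: all inputs are generated in code.

# deterministic random genome pair differing by planted edits
tiny_sim <- function(seed = 4L, n = 3L, len = 30000L) {
  cfg <- sim_config(
    n_accessions = n, chrom_lengths = c(chr1 = len), snp_rate = 2e-4,
    n_insertions = 3L, n_deletions = 2L, n_satellites = 1L,
    te_library = make_te_library(2L, c(400L, 1000L), seed = 9L))
  simulate_pangenome(cfg, seed = seed)
}

# sv_set with one locus per row of an allele-length matrix (for classifier
# checks that need no sequences)
mk_sv_set <- function(lm) {
  if (is.null(colnames(lm))) colnames(lm) <- paste0("a", seq_len(ncol(lm)))
  L <- apply(lm, 1L, max)
  sv <- data.frame(chrom = "c", sv_id = sprintf("s%05d", seq_len(nrow(lm))),
                   col_start = 1L, col_end = 2L, L = L, terminal = FALSE,
                   stringsAsFactors = FALSE)
  structure(sv, accessions = colnames(lm), allele_lengths = lm,
            alleles = rep(list(character(ncol(lm))), nrow(lm)),
            class = c("sv_set", "data.frame"))
}

# independent brute-force global alignment identity (row-wise NW,
# match/mismatch/gap = 1/-1/-1 on alignment length); oracle for identity
# checks on short sequences
nw_identity_oracle <- function(a, b) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  # DP over (matches, alignment length) maximising matches, then min length
  sc <- matrix(0L, n + 1L, m + 1L)    # best match count
  ln <- matrix(0L, n + 1L, m + 1L)    # alignment length achieving it
  sc[1L, ] <- 0L; ln[1L, ] <- 0:m; ln[, 1L] <- 0:n
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- sc[i, j] + (av[i] == bv[j])
      cand <- c(d, sc[i, j + 1L], sc[i + 1L, j])
      lens <- c(ln[i, j] + 1L, ln[i, j + 1L] + 1L, ln[i + 1L, j] + 1L)
      best <- which.max(cand)
      sc[i + 1L, j + 1L] <- cand[best]
      ln[i + 1L, j + 1L] <- lens[best]
    }
  }
  sc[n + 1L, m + 1L] / ln[n + 1L, m + 1L]
}

# brute-force six-frame ORF scan used as an independent oracle
orf_scan_oracle <- function(sequence, long_codons = 100L, min_codons = 30L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
  codon_table <- {
    bases <- c("T", "C", "A", "G")
    aas <- strsplit(paste0(
      "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
      "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
    # codon order: first base slowest, third base fastest
    names(aas) <- paste0(rep(bases, each = 16L),
                         rep(bases, each = 4L, times = 4L),
                         rep(bases, times = 16L))
    aas
  }
  translate1 <- function(s) {
    ncod <- nchar(s) %/% 3L
    if (ncod == 0L) return("")
    cods <- substring(s, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod))
    aa <- unname(codon_table[cods])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  stretches <- list()
  for (f in 1:6) {
    s <- if (f <= 3) sequence else rc
    aa <- translate1(substring(s, 1L + (f - 1L) %% 3L, nchar(s)))
    parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
    parts <- parts[nchar(parts) > 0L]
    for (p in parts) stretches[[length(stretches) + 1L]] <- list(frame = f, aa = p)
  }
  lens <- vapply(stretches, function(x) nchar(x$aa), integer(1))
  long <- which(lens > long_codons)
  if (length(long)) return(sort(vapply(stretches[long], `[[`, "", "aa")))
  if (!length(lens) || max(lens) <= min_codons) return(character(0))
  sort(vapply(stretches[which.max(lens)], `[[`, "", "aa"))
}
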