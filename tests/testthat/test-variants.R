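# helper: alignment over explicit base strings; gaps written "-"
aln_from_strings <- function(rows) {
  accs <- names(rows)
  n <- length(accs)
  C <- nchar(rows[[1L]])
  mats <- matrix(0L, n, C, dimnames = list(accs, NULL))
  genomes <- list()
  for (a in accs) {
    ch <- strsplit(rows[[a]], "")[[1L]]
    pos <- cumsum(ch != "-")
    mats[a, ch != "-"] <- pos[ch != "-"]
    genomes[[a]] <- genome_set(a, c(chr = paste(ch[ch != "-"], collapse = "")))
  }
  pangenome_alignment(list(chr = mats), genomes = genomes)
}

test_that("SNP calling distinguishes all from isolated mode", {
  # identical genomes: no SNPs in either mode
  a0 <- aln_from_strings(list(x = "ACGTACGT", y = "ACGTACGT"))
  expect_equal(nrow(call_snps(a0, "all")), 0L)
  expect_equal(nrow(call_snps(a0, "isolated")), 0L)

  # one substitution with conserved flanks: found in both modes
  a1 <- aln_from_strings(list(x = "ACGTACGT", y = "ACCTACGT"))
  expect_equal(call_snps(a1, "all")$col, 3L)
  expect_equal(call_snps(a1, "isolated")$col, 3L)

  # two adjacent differing columns: 2 in mode all, 0 in isolated
  a2 <- aln_from_strings(list(x = "ACGTACGT", y = "ATCTACGT"))
  expect_equal(call_snps(a2, "all")$col, c(2L, 3L))
  expect_equal(nrow(call_snps(a2, "isolated")), 0L)

  # gap in a column disqualifies it in both modes
  a3 <- aln_from_strings(list(x = "ACGTACGT", y = "AC-TACGT"))
  expect_equal(nrow(call_snps(a3, "all")), 0L)

  # isolated count is never above all count on simulated alignments
  sim <- tiny_sim(seed = 31L)
  aln <- build_pangenome_alignment(sim$genomes, n_references = 3L)
  expect_lte(nrow(call_snps(aln, "isolated")), nrow(call_snps(aln, "all")))
})

test_that("SV loci are maximal gap runs with per-accession alleles", {
  a <- aln_from_strings(list(
    x = "ACGTACGTAAACCCGGGTTTACGT",
    y = paste0("ACGTACGT", strrep("-", 12), "ACGT"),
    z = "ACGTACGTAAACCCGGGTTTACGT"))
  svs <- extract_sv_loci(a)
  expect_equal(nrow(svs), 1L)
  expect_equal(svs$col_start, 9L)
  expect_equal(svs$col_end, 20L)
  expect_equal(unname(attr(svs, "allele_lengths")[1L, ]), c(12L, 0L, 12L))
  expect_equal(svs$L, 12L)
  expect_false(svs$terminal)
  expect_equal(attr(svs, "alleles")[[1L]][1L], "AAACCCGGGTTT")

  # two gap runs separated by one aligned column -> two loci
  b <- aln_from_strings(list(
    x = "ACGTAC--A--GTACGT",
    y = "ACGTACGTAGGGTACGT"))
  expect_equal(nrow(extract_sv_loci(b)), 2L)

  # a run abutting the chromosome end is flagged terminal
  d <- aln_from_strings(list(
    x = "ACGTACGTAAAA",
    y = "ACGTACGT----"))
  svs3 <- extract_sv_loci(d)
  expect_true(svs3$terminal)
})

test_that("sSV/cSV classification matches the allele-length rule exactly", {
  mk_sv <- function(lens, L = max(lens)) {
    sv <- data.frame(chrom = "chr", sv_id = "sv1", col_start = 10L,
                     col_end = 10L + L, L = L, terminal = FALSE)
    lm <- matrix(lens, nrow = 1L,
                 dimnames = list(NULL, paste0("a", seq_along(lens))))
    structure(sv, accessions = colnames(lm), allele_lengths = lm,
              alleles = list(rep("", length(lens))),
              class = c("sv_set", "data.frame"))
  }
  sv <- classify_sv(mk_sv(c(1000L, 998L, 0L, 50L)), s = 0.9)
  expect_equal(sv$class, "sSV")
  expect_equal(sv$presence_freq, 0.5)  # presence in 2 of 4

  expect_equal(classify_sv(mk_sv(c(1000L, 500L, 0L)), s = 0.9)$class, "cSV")
  expect_equal(classify_sv(mk_sv(c(1000L, 500L, 0L)), s = 0.8)$class, "cSV")
  expect_error(classify_sv(mk_sv(c(10L, 0L)), s = 0.5), "s must be")

  # exhaustive grid against a brute-force oracle (vectorised sv_set)
  for (L in c(10L, 100L, 1000L)) {
    fr <- c(0, 0.05, 0.5, 0.95, 1)
    for (n in c(2L, 4L, 8L)) {
      grid <- as.matrix(expand.grid(rep(list(as.integer(round(fr * L))), n)))
      grid <- grid[apply(grid, 1L, max) > 0L, , drop = FALSE]
      svs_grid <- mk_sv_set(grid)
      for (s in c(0.8, 0.9, 0.95)) {
        got <- classify_sv(svs_grid, s)$class
        Lmax <- apply(grid, 1L, max)
        want <- ifelse(rowSums(grid < (1 - s) * Lmax | grid > s * Lmax) == n,
                       "sSV", "cSV")
        expect_identical(got, unname(want))
      }
    }
  }

  # monotonicity in s: relaxing the threshold can only add sSVs
  set.seed(40)
  lens_list <- replicate(200, sample(0:1000, 4), simplify = FALSE)
  cls <- function(lens, s) classify_sv(mk_sv(as.integer(lens)), s)$class
  for (lens in lens_list) {
    if (max(lens) == 0) next
    c95 <- cls(lens, 0.95); c90 <- cls(lens, 0.9); c80 <- cls(lens, 0.8)
    if (c95 == "sSV") expect_equal(c90, "sSV")
    if (c90 == "sSV") expect_equal(c80, "sSV")
  }
})

test_that("polarity follows the minor-presence rule", {
  mk <- function(n_pres, n, L = 1000L) {
    lens <- c(rep(L, n_pres), rep(0L, n - n_pres))
    sv <- data.frame(chrom = "chr", sv_id = "sv1", col_start = 5L,
                     col_end = 6L, L = L, terminal = FALSE)
    lm <- matrix(lens, nrow = 1L, dimnames = list(NULL, paste0("a", 1:n)))
    structure(sv, accessions = colnames(lm), allele_lengths = lm,
              alleles = list(rep("", n)), class = c("sv_set", "data.frame"))
  }
  pol <- function(n_pres, n) infer_polarity(classify_sv(mk(n_pres, n)))$polarity
  expect_equal(pol(2L, 27L), "likely_insertion")
  expect_equal(pol(26L, 27L), "likely_deletion")
  expect_equal(pol(13L, 27L), "unpolarized")
})

test_that("consensus allele is the medoid of the presence alleles", {
  set.seed(41)
  base <- random_dna(300)
  variant <- base
  for (p in sample(300, 5)) {
    old <- substr(variant, p, p)
    substr(variant, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  }
  sv <- data.frame(chrom = "chr", sv_id = "sv1", col_start = 5L,
                   col_end = 304L, L = 300L, terminal = FALSE)
  lm <- matrix(c(300L, 300L, 300L, 0L), nrow = 1L,
               dimnames = list(NULL, paste0("a", 1:4)))
  svs <- structure(sv, accessions = colnames(lm), allele_lengths = lm,
                   alleles = list(c(base, base, variant, "")),
                   class = c("sv_set", "data.frame"))
  svs <- classify_sv(svs)
  expect_equal(consensus_allele(svs, 1L), base)
  # single presence allele returns itself
  lm2 <- matrix(c(300L, 0L), nrow = 1L, dimnames = list(NULL, c("a1", "a2")))
  svs2 <- structure(sv, accessions = colnames(lm2), allele_lengths = lm2,
                    alleles = list(c(variant, "")),
                    class = c("sv_set", "data.frame"))
  expect_equal(consensus_allele(classify_sv(svs2), 1L), variant)
})

test_that("length classes partition sSVs", {
  L <- c(1L, 14L, 15L, 99L, 100L, 4999L, 5000L, 19999L, 20000L, 50000L)
  cl <- sv_length_class(L)
  expect_false(anyNA(cl))
  expect_equal(as.character(cl[1:2]), rep("[1,15)", 2))
  expect_equal(as.character(cl[3]), "[15,100)")
  expect_equal(as.character(cl[9:10]), rep("[20000,Inf)", 2))
})
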