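test_that("TE library generation is deterministic and families are dissimilar", {
  lib1 <- make_te_library(3L, c(300L, 500L), seed = 1L)
  lib2 <- make_te_library(3L, c(300L, 500L), seed = 1L)
  expect_identical(lib1, lib2)
  expect_equal(nrow(make_te_library(1L, c(300L, 400L), seed = 2L)), 1L)
  # brute-force NW identity oracle confirms the < 0.6 invariant
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(nw_identity_oracle(lib1$sequence[i], lib1$sequence[j]), 0.6)
  }
})

test_that("simulation with zero rates returns clones of the ancestor", {
  cfg <- sim_config(n_accessions = 5L, chrom_lengths = c(chr1 = 5000L),
                    snp_rate = 0, n_insertions = 0L, n_deletions = 0L,
                    n_satellites = 0L,
                    te_library = make_te_library(1L, c(300L, 400L), seed = 3L))
  sim <- simulate_pangenome(cfg, seed = 7L)
  expect_equal(nrow(sim$truth$snps), 0L)
  for (g in sim$genomes)
    expect_identical(unname(g$sequences), unname(sim$ancestor$sequences))
})

test_that("planted events are reproduced verbatim and ledger is self-consistent", {
  sim <- tiny_sim(seed = 11L)
  # identical seed => byte-identical outputs
  sim2 <- tiny_sim(seed = 11L)
  expect_identical(lapply(sim$genomes, `[[`, "sequences"),
                   lapply(sim2$genomes, `[[`, "sequences"))
  expect_identical(sim$truth$snps, sim2$truth$snps)
  # replaying the ledger reproduces each genome exactly
  for (a in sim$truth$accessions) {
    re <- apply_truth(sim$ancestor, sim$truth, a)
    expect_identical(re$sequences, sim$genomes[[a]]$sequences)
  }
  # inserted sequences occur verbatim in carriers; for families with a
  # single planted event they are also absent from non-carriers (fragments
  # of multi-event families can recur inside another event's copy)
  fam_events <- table(sim$truth$insertions$family_id)
  for (t in seq_len(nrow(sim$truth$insertions))) {
    ins <- sim$truth$insertions[t, ]
    carriers <- strsplit(ins$carriers, ",")[[1]]
    for (a in sim$truth$accessions) {
      hit <- grepl(ins$sequence, sim$genomes[[a]]$sequences[[ins$chrom]],
                   fixed = TRUE)
      if (a %in% carriers) expect_true(hit)
      else if (fam_events[ins$family_id] == 1L) expect_false(hit)
    }
  }
  # satellite blocks are tandem arrays with unit period <= 180 nt
  expect_true(all(nchar(sim$truth$satellites$unit) <= 180L))
})

test_that("total planted SNP count matches the binomial expectation", {
  cfg <- sim_config(n_accessions = 4L, chrom_lengths = c(chr1 = 100000L),
                    snp_rate = 0.002, n_insertions = 0L, n_deletions = 0L,
                    n_satellites = 0L,
                    te_library = make_te_library(1L, c(300L, 400L), seed = 3L))
  sim <- simulate_pangenome(cfg, seed = 5L)
  expected <- 4 * 100000 * 0.002
  sdv <- sqrt(expected * (1 - 0.002))
  expect_lt(abs(nrow(sim$truth$snps) - expected), 3 * sdv)
})

test_that("coordinate maps are mutually inverse and respect events", {
  sim <- tiny_sim(seed = 12L)
  for (a in c("acc01", "acc03")) {
    mp <- truth_coord_maps(sim$ancestor, sim$truth, a)$chr1
    ok <- !is.na(mp$anc2acc)
    expect_true(all(mp$acc2anc[mp$anc2acc[ok]] == which(ok)))
    # bases agree wherever positions correspond (excluding the carrier SNPs)
    anc <- sim$ancestor$sequences[["chr1"]]
    acc <- sim$genomes[[a]]$sequences[["chr1"]]
    idx <- which(ok)[seq(1, sum(ok), by = 97)]
    snp_pos <- sim$truth$snps$anc_pos[
      vapply(sim$truth$snps$carriers, function(s)
        a %in% strsplit(s, ",")[[1]], logical(1))]
    idx <- setdiff(idx, snp_pos)
    expect_equal(substring(anc, idx, idx),
                 substring(acc, mp$anc2acc[idx], mp$anc2acc[idx]))
  }
})

test_that("simulated call sets hit their planted error rates", {
  truth_pos <- sort(sample.int(50000L, 1000L))
  cs0 <- simulate_call_set(truth_pos, 50000L, seed = 3L)
  expect_equal(cs0$calls$pos, truth_pos)
  expect_true(all(cs0$covered))

  cs_empty <- simulate_call_set(truth_pos, 50000L, fnr_target = 1,
                                fdr_target = 0, seed = 3L)
  expect_equal(nrow(cs_empty$calls), 0L)

  cs <- simulate_call_set(truth_pos, 50000L, fnr_target = 0.1, seed = 8L)
  dropped <- length(truth_pos) - nrow(cs$calls)
  expect_true(dropped >= qbinom(0.0005, 1000, 0.1) &&
                dropped <= qbinom(0.9995, 1000, 0.1))
  cs_rep <- simulate_call_set(truth_pos, 50000L, fnr_target = 0.1, seed = 8L)
  expect_identical(cs$calls, cs_rep$calls)

  expect_error(simulate_call_set(truth_pos, 50000L, fdr_target = 1), "fdr")
})
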