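test_that("chop_blocks partitions chromosomes with the short-tail merge rule", {
  set.seed(2)
  g <- genome_set("a", c(c1 = random_dna(12000)))
  b <- chop_blocks(g, 5000L)
  expect_equal(b$start, c(1L, 5001L, 10001L))
  expect_equal(b$end, c(5000L, 10000L, 12000L))

  g2 <- genome_set("a", c(c1 = random_dna(5050)))
  b2 <- chop_blocks(g2, 5000L)
  expect_equal(nrow(b2), 1L)   # 50 nt tail < 100 merges into the block
  expect_equal(b2$end, 5050L)

  g3 <- genome_set("a", c(c1 = random_dna(4000)))
  expect_equal(nrow(chop_blocks(g3, 5000L)), 1L)
  expect_error(chop_blocks(g3, 50L), "block_size")
})

test_that("anchoring a genome on itself gives identity hits on the + strand", {
  set.seed(3)
  g <- genome_set("a", c(c1 = random_dna(15000)))
  hits <- anchor_blocks(chop_blocks(g), g)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$identity, rep(1, 3))
  expect_equal(hits$strand, rep("+", 3))
  expect_equal(hits$qstart, hits$rstart)
  expect_equal(hits$qend, hits$rend)
})

test_that("a block present twice in the reference anchors at the first copy", {
  set.seed(4)
  copy <- random_dna(5000)
  filler1 <- random_dna(5000); filler2 <- random_dna(40000); filler3 <- random_dna(5000)
  ref <- genome_set("r", c(c1 = paste0(filler1, copy, filler2, copy, filler3)))
  q <- genome_set("q", c(c1 = copy))
  hits <- anchor_blocks(chop_blocks(q), ref)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$rstart, 5001L)  # deterministic tie-break: lower start
})

test_that("random sequence absent from the reference gets no hit", {
  set.seed(5)
  ref <- genome_set("r", c(c1 = random_dna(20000)))
  q <- genome_set("q", c(c1 = random_dna(6000)))
  hits <- anchor_blocks(chop_blocks(q), ref)
  expect_equal(nrow(hits), 0L)
})

test_that("identical genomes produce an identity correspondence map", {
  set.seed(6)
  g <- genome_set("a", c(c1 = random_dna(20000)))
  cm <- pairwise_align(g, g)
  expect_equal(cm$chrom$c1$ref_pos, seq_len(20000L))
})

test_that("a planted SNP inside an inter-hit gap is matched with differing bases", {
  set.seed(7)
  s <- random_dna(15000)
  q <- s
  substr(q, 7500, 7500) <- if (substr(s, 7500, 7500) == "A") "C" else "A"
  cm <- pairwise_align(genome_set("q", c(c1 = q)), genome_set("r", c(c1 = s)))
  expect_equal(cm$chrom$c1$ref_pos[7500], 7500L)
  expect_equal(sum(cm$chrom$c1$ref_pos == 0L), 0L)
})

test_that("an off-diagonal repeat anchor is removed and the map stays colinear", {
  set.seed(8)
  rep_unit <- random_dna(4800)
  # query: unique1 + repeat + unique2; reference has the repeat also at a
  # distant locus, which can pull the middle block off the diagonal
  u1 <- random_dna(5100); u2 <- random_dna(5100); far <- random_dna(20000)
  qseq <- paste0(u1, rep_unit, u2)
  rseq <- paste0(u1, rep_unit, u2, far, rep_unit)
  cm <- pairwise_align(genome_set("q", c(c1 = qseq)), genome_set("r", c(c1 = rseq)))
  rp <- cm$chrom$c1$ref_pos
  nz <- rp[rp > 0L]
  expect_true(all(diff(nz) > 0L))
  expect_true(all(nz <= nchar(qseq) + 100L))  # never maps into the far copy
  expect_gt(mean(rp[1:nchar(qseq)] > 0L), 0.95)
})

test_that("minus-strand chains are reported as inversions without a base map", {
  set.seed(9)
  a <- random_dna(12000); b <- random_dna(12000); c <- random_dna(12000)
  ref <- genome_set("r", c(c1 = paste0(a, b, c)))
  q <- genome_set("q", c(c1 = paste0(a, revcomp(b), c)))
  cm <- pairwise_align(q, ref)
  expect_gt(nrow(cm$inversions), 0L)
  inv <- cm$inversions[1L, ]
  expect_true(inv$qstart > 11000 && inv$qend < 25000)
  expect_true(all(cm$chrom$c1$ref_pos[13001:23000] == 0L))
})

test_that("planted satellite blocks stay unmatched while flanks align", {
  sim <- tiny_sim(seed = 21L)
  cm <- pairwise_align(sim$genomes$acc01, sim$genomes$acc02)
  sat <- sim$truth$satellites[1L, ]
  mp <- truth_coord_maps(sim$ancestor, sim$truth, "acc01")[[sat$chrom]]
  # accession positions inside the satellite replacement are those with no
  # ancestor counterpart between the block flanks
  gl <- mp$anc2acc[sat$anc_start - 1L]; gr <- mp$anc2acc[sat$anc_end + 1L]
  inside <- (gl + 1L):(gr - 1L)
  frac_matched <- mean(cm$chrom[[sat$chrom]]$ref_pos[inside] > 0L)
  expect_lt(frac_matched, 0.2)
  expect_gt(mean(cm$chrom[[sat$chrom]]$ref_pos > 0L), 0.85)
})

test_that("forward and reverse maps agree on matched positions", {
  sim <- tiny_sim(seed = 22L)
  cm12 <- pairwise_align(sim$genomes$acc01, sim$genomes$acc02)
  cm21 <- pairwise_align(sim$genomes$acc02, sim$genomes$acc01)
  f <- cm12$chrom$chr1$ref_pos
  r <- cm21$chrom$chr1$ref_pos
  both <- which(f > 0L)
  both <- both[r[f[both]] > 0L]
  agree <- mean(r[f[both]] == both)
  expect_gte(agree, 0.99)
})
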