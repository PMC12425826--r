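test_that("drafts of identical genomes are full identity matrices", {
  set.seed(90)
  s <- random_dna(20000)
  genomes <- list(a = genome_set("a", c(c1 = s)),
                  b = genome_set("b", c(c1 = s)),
                  c = genome_set("c", c(c1 = s)))
  drafts <- build_reference_matrices(genomes, references = c("a", "b"))
  for (d in drafts) {
    m <- d$matrices$c1
    for (acc in c("a", "b", "c")) expect_equal(unname(m[acc, ]), 1:20000)
  }
  expect_error(build_reference_matrices(genomes, references = "a"), "at least 2")
  expect_error(build_reference_matrices(genomes, references = c("a", "zz")), "zz")
})

test_that("a private insertion is absent from every reference draft", {
  set.seed(91)
  s <- random_dna(20000)
  ins <- random_dna(1000)
  withins <- paste0(substr(s, 1, 10000), ins, substr(s, 10001, 20000))
  genomes <- list(a = genome_set("a", c(c1 = s)),
                  b = genome_set("b", c(c1 = s)),
                  c = genome_set("c", c(c1 = withins)))
  drafts <- build_reference_matrices(genomes, references = c("a", "b"))
  for (d in drafts) {
    # columns are reference positions; positions 10001..11000 of c (the
    # insertion) correspond to no reference position
    expect_false(any(d$matrices$c1["c", ] %in% 10001:11000))
  }
})

test_that("intersection keeps agreeing tuples and is order-invariant", {
  set.seed(92)
  s <- random_dna(20000)
  genomes <- list(a = genome_set("a", c(c1 = s)),
                  b = genome_set("b", c(c1 = s)),
                  c = genome_set("c", c(c1 = s)))
  drafts <- build_reference_matrices(genomes, references = c("a", "b"))
  skel <- intersect_matrices(drafts)
  expect_equal(ncol(skel$c1), 20000L)
  skel_rev <- intersect_matrices(rev(drafts))
  expect_equal(unname(skel$c1), unname(skel_rev$c1))
  expect_error(intersect_matrices(drafts[1L]), "at least 2")
})

test_that("a two-copy repeat that drafts place differently is dropped", {
  set.seed(93)
  u1 <- random_dna(8000); u2 <- random_dna(8000); u3 <- random_dna(8000)
  rep_unit <- random_dna(3000)
  # genome c carries the repeat at locus 1; references carry it at both
  # loci, so c's repeat can map either way depending on the reference
  sa <- paste0(u1, rep_unit, u2, rep_unit, u3)
  sc <- paste0(u1, rep_unit, u2, u3)
  genomes <- list(a = genome_set("a", c(c1 = sa)),
                  b = genome_set("b", c(c1 = sa)),
                  c = genome_set("c", c(c1 = sc)))
  drafts <- build_reference_matrices(genomes, references = c("a", "b"))
  skel <- intersect_matrices(drafts)
  aln <- sort_and_index(resolve_unaligned_blocks(skel, genomes),
                        anchor_order = names(genomes))
  validate_alignment(aln)
  # unique flanks must survive as fully aligned columns
  mat <- aln$chroms$c1
  full <- colSums(mat > 0L) == 3L
  expect_gt(sum(full), 25000L)
})

test_that("pangenome length accounts for private insertions exactly", {
  set.seed(94)
  s <- random_dna(30000)
  ins <- random_dna(1000)
  withins <- paste0(substr(s, 1, 15000), ins, substr(s, 15001, 30000))
  genomes <- list(a = genome_set("a", c(c1 = s)),
                  b = genome_set("b", c(c1 = s)),
                  c = genome_set("c", c(c1 = withins)))
  aln <- build_pangenome_alignment(genomes, references = c("a", "b"))
  expect_equal(ncol(aln$chroms$c1), 31000L)
  # identical genomes: pangenome length equals genome length
  genomes2 <- list(a = genome_set("a", c(c1 = s)), b = genome_set("b", c(c1 = s)))
  aln2 <- build_pangenome_alignment(genomes2, references = c("a", "b"))
  expect_equal(ncol(aln2$chroms$c1), 30000L)
})

test_that("the 30-kb rule leaves oversized divergent blocks unaligned", {
  skel <- list(chr = structure(
    rbind(x = c(1L, 2L), y = c(1L, 35002L)),
    dimnames = list(c("x", "y"), NULL),
    chrom_map = c(x = "chr", y = "chr")))
  set.seed(95)
  genomes <- list(x = genome_set("x", c(chr = random_dna(2))),
                  y = genome_set("y", c(chr = paste0(
                    substr(random_dna(2), 1, 1),
                    random_dna(35000),
                    "A"))))
  # y has 35,000 unplaced positions between its two skeleton columns
  aln <- resolve_unaligned_blocks(skel, genomes, max_block = 30000L)
  m <- aln$chroms$chr
  expect_equal(ncol(m), 2L + 35000L)
  inner <- m[, 2:35001]
  expect_true(all(inner["x", ] == 0L))   # private columns: x all gap
  expect_equal(sum(inner["y", ] > 0L), 35000L)

  # empty block between adjacent columns: no change
  skel2 <- list(chr = structure(rbind(x = 1:2, y = 1:2),
                                dimnames = list(c("x", "y"), NULL),
                                chrom_map = c(x = "chr", y = "chr")))
  genomes2 <- list(x = genome_set("x", c(chr = "AC")),
                   y = genome_set("y", c(chr = "AC")))
  aln2 <- resolve_unaligned_blocks(skel2, genomes2)
  expect_equal(ncol(aln2$chroms$chr), 2L)
})

test_that("a one-accession surplus block becomes spliced gap columns", {
  set.seed(96)
  core <- random_dna(15000)
  extra <- random_dna(10)
  y <- paste0(substr(core, 1, 7000), extra, substr(core, 7001, 15000))
  genomes <- list(a = genome_set("a", c(c1 = core)),
                  b = genome_set("b", c(c1 = core)),
                  y = genome_set("y", c(c1 = y)))
  aln <- build_pangenome_alignment(genomes, references = c("a", "b"))
  expect_equal(ncol(aln$chroms$c1), 15010L)
  m <- aln$chroms$c1
  gapcols <- which(colSums(m > 0L) < 3L)
  expect_equal(length(gapcols), 10L)
  expect_true(all(m["a", gapcols] == 0L))
  expect_true(all(m["y", gapcols] > 0L))
})

test_that("sorting and indexing give a consistent bidirectional lookup", {
  sim <- tiny_sim(seed = 97L)
  aln <- build_pangenome_alignment(sim$genomes, n_references = 3L)
  validate_alignment(aln)
  for (a in aln$accessions) {
    mat <- aln$chroms$chr1
    nz <- which(mat[a, ] > 0L)
    probe <- nz[seq(1L, length(nz), by = 499L)]
    pos <- mat[a, probe]
    expect_equal(aln$index[[a]]$chr1[pos], probe)   # round trip
  }
  # pangenome length >= max individual genome length
  expect_gte(ncol(aln$chroms$chr1),
             max(vapply(sim$genomes, function(g) nchar(g$sequences[["chr1"]]), 1L)))
})

test_that("constructed alignments validate their invariants", {
  m <- rbind(x = c(1L, 2L, 3L), y = c(3L, 2L, 1L))
  expect_error(pangenome_alignment(list(c = m)), "strictly increasing")
  m2 <- rbind(x = c(1L, 2L, 0L), y = c(0L, 0L, 0L))
  expect_error(pangenome_alignment(list(c = m2)), "non-gap")
  m3 <- rbind(x = c(1L, 1L), y = c(1L, 2L))
  expect_error(pangenome_alignment(list(c = m3)), "")
})
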