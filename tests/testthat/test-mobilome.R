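test_that("nestedness edges follow the coverage threshold", {
  set.seed(50)
  B <- random_dna(600)
  A <- substr(B, 101, 250)                       # verbatim 150-nt substring
  seqs <- c(A = A, B = B)
  e <- pairwise_nestedness(seqs)
  expect_equal(nrow(e), 1L)
  expect_equal(e$nested_id, "A")
  expect_equal(e$container_id, "B")
  expect_equal(e$coverage, 1)

  # hits covering only ~0.8 of A: no edge at threshold 0.85
  A2 <- paste0(substr(B, 101, 260), random_dna(40))
  e2 <- pairwise_nestedness(c(A = A2, B = B))
  expect_equal(nrow(e2), 0L)

  # identical sequences: mutual edges
  e3 <- pairwise_nestedness(c(X = B, Y = B))
  expect_equal(nrow(e3), 2L)

  # sequences below min_len are excluded
  e4 <- pairwise_nestedness(c(short = substr(B, 1, 80), B = B))
  expect_equal(nrow(e4), 0L)
})

test_that("exact containment is transitive in the graph", {
  set.seed(51)
  C <- random_dna(900)
  B <- substr(C, 151, 750)
  A <- substr(C, 301, 500)
  e <- pairwise_nestedness(c(A = A, B = B, C = C))
  key <- paste(e$nested_id, e$container_id)
  expect_true(all(c("A B", "B C", "A C") %in% key))
})

test_that("graph components recover planted families and merge collapses clones", {
  set.seed(52)
  fams <- list(f1 = random_dna(2000), f2 = random_dna(1500), f3 = random_dna(2500))
  seqs <- character(0)
  labels <- character(0)
  for (f in names(fams)) {
    for (i in 1:10) {
      if (i <= 6) s <- fams[[f]]                       # complete copies
      else {
        keep <- round(stats::runif(1, 0.3, 0.8) * nchar(fams[[f]]))
        off <- sample(nchar(fams[[f]]) - keep + 1L, 1L)
        s <- substr(fams[[f]], off, off + keep - 1L)   # truncated fragments
      }
      id <- sprintf("%s_%02d", f, i)
      seqs[id] <- s
      labels[id] <- f
    }
  }
  e <- pairwise_nestedness(seqs)
  g <- build_graph(e, seqs)
  comp <- g$nodes$component[match(names(seqs), g$nodes$node_id)]
  ari <- mclust::adjustedRandIndex(comp, labels)
  expect_gte(ari, 0.9)

  gm <- merge_nodes(g)
  # the 6 identical complete copies per family collapse into one node
  big <- gm$nodes[gm$nodes$members >= 6L, ]
  expect_equal(nrow(big), 3L)
  expect_true(all(sort(big$length) == sort(vapply(fams, nchar, 1L))))
  # empty input stays empty; no-edge input keeps all nodes isolated
  g0 <- build_graph(pairwise_nestedness(character(0)), character(0))
  expect_equal(nrow(g0$nodes), 0L)
  iso <- build_graph(data.frame(nested_id = character(0),
                                container_id = character(0),
                                coverage = numeric(0)),
                     c(a = random_dna(200), b = random_dna(200)))
  expect_equal(length(unique(iso$nodes$component)), 2L)
})

test_that("one-directional containment does not merge nodes", {
  set.seed(53)
  B <- random_dna(1000)
  A <- substr(B, 201, 800)
  g <- merge_nodes(build_graph(pairwise_nestedness(c(A = A, B = B)),
                               c(A = A, B = B)))
  expect_equal(nrow(g$nodes), 2L)
  # but a clique of 5 near-identical sequences collapses to one node
  clones <- setNames(rep(B, 5), paste0("c", 1:5))
  g2 <- merge_nodes(build_graph(pairwise_nestedness(clones), clones))
  expect_equal(nrow(g2$nodes), 1L)
  expect_equal(g2$nodes$members, 5L)
})

test_that("TE content categories follow the dual-coverage rule", {
  set.seed(54)
  lib <- make_te_library(2L, c(4000L, 5000L), seed = 55L)
  el <- lib$sequence[1L]
  ann <- te_annotation_set(data.frame(element_id = lib$family_id,
                                      superfamily = lib$superfamily,
                                      sequence = lib$sequence))
  expect_equal(te_content_category(el, ann)$category, "is_complete")

  r <- te_content_category(paste0(el, random_dna(3000)), ann)
  expect_equal(r$category, "contains_complete")
  expect_lt(r$seq_coverage, 0.85)
  expect_gte(r$max_element_coverage, 0.85)

  frag <- substr(el, 1, round(nchar(el) * 0.2))
  r2 <- te_content_category(frag, ann)
  expect_equal(r2$category, "is_fragment")

  r3 <- te_content_category(paste0(frag, random_dna(3000)), ann)
  expect_equal(r3$category, "contains_fragment")

  expect_equal(te_content_category(random_dna(1000), ann)$category, "none")

  # brute-force oracle over a coverage grid: build sequences with known a/b
  el_len <- nchar(el)
  for (afrac in c(0.2, 0.5, 1.0)) {
    for (bfrac in c(0.2, 0.5, 1.0)) {
      piece <- substr(el, 1, round(bfrac * el_len))
      total <- round(nchar(piece) / afrac)
      seqx <- paste0(piece, random_dna(max(0, total - nchar(piece))))
      r <- te_content_category(seqx, ann)
      a_true <- nchar(piece) / nchar(seqx)
      b_true <- nchar(piece) / el_len
      expect_lt(abs(r$seq_coverage - a_true), 0.03)
      expect_lt(abs(r$max_element_coverage - b_true), 0.03)
      want <- if (a_true >= 0.85 && b_true >= 0.85) "is_complete"
      else if (b_true >= 0.85) "contains_complete"
      else if (a_true >= 0.85) "is_fragment"
      else "contains_fragment"
      expect_equal(r$category, want)
    }
  }
})

test_that("ORF scan matches an independent six-frame oracle", {
  # 101 leucine codons: stop-free in frame 1, while the reverse frames read
  # TAA stops -> exactly one ORF of 101 codons
  s <- strrep("TTA", 101)
  r <- orf_scan(s)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_codons, 101L)
  expect_equal(r$frame, 1L)
  expect_equal(r$aa, strrep("L", 101))

  expect_error(orf_scan("ACGT"), "93")

  # 100 random sequences against the brute-force oracle
  set.seed(2)
  for (i in 1:100) {
    x <- random_dna(sample(93:700, 1L))
    got <- sort(orf_scan(x)$aa)
    want <- orf_scan_oracle(x)
    expect_identical(got, want)
  }
})

test_that("protein-hit keyword classification follows the keyword lists", {
  expect_equal(classify_protein_hits(c("putative reverse transcriptase")), "te_like")
  expect_equal(classify_protein_hits(c("Gag-Pol polyprotein")), "te_like")
  expect_equal(classify_protein_hits(c("hypothetical protein", "unknown")),
               "undefined_protein")
  expect_equal(classify_protein_hits(c("PREDICTED: something")), "undefined_protein")
  expect_equal(classify_protein_hits(character(0)), "no_protein")
  expect_equal(classify_protein_hits(c("cytochrome P450")), "defined_protein")
  expect_equal(classify_protein_hits(c("hypothetical protein", "cytochrome P450")),
               "defined_protein")
  expect_equal(classify_protein_hits(c("RNA-directed DNA polymerase homolog")),
               "te_like")
})
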