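test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_from_distances(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["a"]], 0.5)
  expect_equal(bl[["b"]], 1.5)
  expect_equal(bl[["c"]], 2.5)
  expect_error(nj_from_distances(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive distance matrices exactly (topology and
           path lengths)", {
  skip_if_not_installed("phangorn")
  set.seed(16)
  for (ntax in c(5, 6)) {
    for (rep in 1:8) {
      tr0 <- ape::rtree(ntax, br = function(n) runif(n, 0.1, 1))
      tr0 <- ape::unroot(tr0)
      d <- stats::cophenetic(tr0)
      tr <- nj_from_distances(d)
      expect_equal(phangorn::RF.dist(tr, tr0), 0)
      expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
                   tolerance = 1e-8)
    }
  }
})

test_that("identical sequences give an all-zero-branch tree without error", {
  aln <- setNames(rep(strrep("ACGT", 50), 4), paste0("t", 1:4))
  tr <- build_nj_tree(aln)
  expect_equal(sum(tr$edge.length), 0)
  expect_equal(sort(tr$tip.label), paste0("t", 1:4))
})

test_that("negative NJ branches are clamped to zero", {
  ## a distance matrix known to produce a negative NJ branch
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_from_distances(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are percentages, {0,100} at one replicate,
           and collapse_below=0 keeps every edge", {
  fr <- read_aln_fixture(system.file("extdata", "fr_alignments_synthetic",
                                     "fr5_aln.fasta", package = "trflocus"))
  b1 <- bootstrap_support(fr, replicates = 1, collapse_below = 0, seed = 2)
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  b0 <- bootstrap_support(fr, replicates = 20, collapse_below = 0, seed = 2)
  expect_equal(b0$Nnode, build_nj_tree(fr)$Nnode)
  ## seeded: identical reruns
  b0b <- bootstrap_support(fr, replicates = 20, collapse_below = 0, seed = 2)
  expect_identical(ape::write.tree(b0), ape::write.tree(b0b))
})

test_that("edges below the support threshold are collapsed into polytomies", {
  fr <- read_aln_fixture(system.file("extdata", "fr_alignments_synthetic",
                                     "fr5_aln.fasta", package = "trflocus"))
  keep_all <- bootstrap_support(fr, replicates = 50, collapse_below = 0,
                                seed = 5)
  collapsed <- bootstrap_support(fr, replicates = 50, collapse_below = 101,
                                 seed = 5)
  ## collapsing at an impossible threshold removes every internal edge with
  ## numeric support below it
  expect_lt(collapsed$Nnode, keep_all$Nnode)
  sup <- suppressWarnings(as.numeric(keep_all$node.label))
  n_low <- sum(!is.na(sup) & sup < 101)
  expect_equal(keep_all$Nnode - collapsed$Nnode, n_low)
})

test_that("clearly separated clades reach high bootstrap support", {
  fr <- read_aln_fixture(system.file("extdata", "fr_alignments_synthetic",
                                     "fr5_aln.fasta", package = "trflocus"))
  bt <- bootstrap_support(fr, replicates = 200, collapse_below = 50, seed = 7)
  clade1 <- c("D1y", "D1g", "D1b", "D1e", "D1d", "D1f", "D1h",
              "B8", "B8a", "C4", "C4a")
  expect_true(has_bipartition(bt, clade1))
})

test_that("bootstrap supports are invariant to taxon input order", {
  fr <- read_aln_fixture(system.file("extdata", "fr_alignments_synthetic",
                                     "fr3_aln.fasta", package = "trflocus"))
  set.seed(30)
  perm <- sample(length(fr))
  b1 <- bootstrap_support(fr, replicates = 50, collapse_below = 50, seed = 9)
  b2 <- bootstrap_support(fr[perm], replicates = 50, collapse_below = 50,
                          seed = 9)
  clade1 <- c("D1y", "D1g", "D1b", "D1e", "D1d", "D1f", "D1h",
              "B8", "B8a", "C4", "C4a")
  expect_equal(has_bipartition(b1, clade1), has_bipartition(b2, clade1))
})

test_that("trees serialize to Newick and round-trip losslessly", {
  fr <- read_aln_fixture(system.file("extdata", "fr_alignments_synthetic",
                                     "fr5_aln.fasta", package = "trflocus"))
  tr <- build_nj_tree(fr, distance = "JC")
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(back, tr), 0)
  expect_equal(sum(back$edge.length), sum(tr$edge.length), tolerance = 1e-6)
})
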