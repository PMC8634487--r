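test_that("generation is byte-deterministic for a fixed spec and seed", {
  sp <- locus_spec(seed = 12, n_clusters = 2, genes_per_cluster = c(3, 2))
  l1 <- generate_locus(sp)
  l2 <- generate_locus(sp)
  expect_identical(as.character(l1$sequences), as.character(l2$sequences))
  expect_identical(l1$truth$genes, l2$truth$genes)
  d1 <- tempfile(); d2 <- tempfile()
  write_locus(l1, d1); write_locus(l2, d2)
  expect_identical(readLines(file.path(d1, "locus.fasta")),
                   readLines(file.path(d2, "locus.fasta")))
  expect_identical(readLines(file.path(d1, "truth.gff3")),
                   readLines(file.path(d2, "truth.gff3")))
})

test_that("gene counts in truth follow the cluster specification", {
  loc <- generate_locus(locus_spec(seed = 2, n_clusters = 2,
                                   genes_per_cluster = c(7, 6),
                                   duplications = 0))
  expect_equal(nrow(loc$truth$genes), 13L)
  expect_equal(sum(loc$truth$genes$contig == "cluster1"), 7L)
  expect_equal(length(loc$sequences), 2L)
  ## both strands occur over a few seeds
  strands <- unlist(lapply(1:4, function(s) {
    generate_locus(locus_spec(seed = s, n_clusters = 1,
                              genes_per_cluster = 3,
                              duplications = 0))$truth$genes$strand
  }))
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("mutation-free duplication produces byte-identical gene copies", {
  loc <- generate_locus(locus_spec(seed = 9, n_clusters = 1,
                                   genes_per_cluster = 1, duplications = 1,
                                   snp_rate = 0, allele_divergence = 0,
                                   indel_rate = 0))
  g <- loc$truth$genes
  expect_equal(nrow(g), 2L)
  s <- as.character(loc$sequences[[1]])
  seq_of <- function(i) substr(s, g$gene_start[i] + 1L, g$gene_end[i])
  expect_identical(seq_of(1), seq_of(2))
})

test_that("every generated gene satisfies the annotation grammar", {
  loc <- generate_locus(locus_spec(seed = 33, n_clusters = 2,
                                   genes_per_cluster = c(4, 3)))
  for (cn in names(loc$sequences)) {
    g <- annotate_genes(loc$sequences[[cn]], contig = cn)
    expect_equal(nrow(attr(g, "failures")), 0L, info = cn)
    tg <- loc$truth$genes[loc$truth$genes$contig == cn, ]
    expect_models_equal(g, tg)
    for (i in seq_len(nrow(g))) {
      expect_true(all(validate_gene_model(g[i, ], loc$sequences[[cn]])$pass))
    }
  }
})

test_that("programmed STR flanks and islands appear in the truth and the
           sequence", {
  loc <- generate_locus(locus_spec(seed = 14, n_clusters = 1,
                                   genes_per_cluster = 2, duplications = 0))
  isl <- loc$truth$islands
  big <- isl[isl$kind == "island", ]
  expect_equal(nrow(big), 2L)
  expect_true(all(big$length_nt >= 2500L))
  flank_ga <- isl[isl$kind == "flank" & isl$motif == "GA", ]
  expect_equal(nrow(flank_ga), 4L)  # two per gene unit
  s <- as.character(loc$sequences[[1]])
  for (i in seq_len(nrow(big))) {
    run <- substr(s, big$start[i] + 1L, big$end[i])
    expect_equal(run, substr(strrep("GA", ceiling(nchar(run) / 2) + 1), 1,
                             nchar(run)))
  }
})

test_that("explicit events apply in order and are validated", {
  ev <- list(list(type = "element_deletion", cluster = 1L, gene = 1L,
                  elements = c(5L, 6L)))
  loc <- generate_locus(locus_spec(seed = 18, n_clusters = 1,
                                   genes_per_cluster = 2, duplications = 0,
                                   gene_pool = "A2", events = ev))
  mask <- strsplit(loc$truth$genes$element_mask[1], "")[[1]] == "1"
  expect_false(any(mask[c(5, 6)]))
  expect_true("element_deletion" %in% loc$truth$events$event)
  ## deleting an absent element is a spec validation error
  ev_bad <- list(list(type = "element_deletion", cluster = 1L, gene = 1L,
                      elements = 8L))   # A2 pattern lacks element 8
  expect_error(generate_locus(locus_spec(seed = 18, n_clusters = 1,
                                         genes_per_cluster = 2,
                                         duplications = 0, gene_pool = "A2",
                                         events = ev_bad)),
               "already absent")
  ## inversion flips the strand of the unit's gene
  ev_inv <- list(list(type = "inversion", cluster = 1L, gene = 1L))
  base <- generate_locus(locus_spec(seed = 19, n_clusters = 1,
                                    genes_per_cluster = 2, duplications = 0))
  flip <- generate_locus(locus_spec(seed = 19, n_clusters = 1,
                                    genes_per_cluster = 2, duplications = 0,
                                    events = ev_inv))
  expect_true(base$truth$genes$strand[1] != flip$truth$genes$strand[1])
})

test_that("allelic perturbation changes island lengths and gene content by
           exactly the programmed amounts", {
  loc <- generate_locus(locus_spec(seed = 5, n_clusters = 2,
                                   genes_per_cluster = c(3, 2),
                                   duplications = 0))
  al <- perturb_alleles(loc, str_length_delta = c("2" = -130L),
                        gene_presence_mask = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                        seed = 9)
  expect_equal(nrow(al$truth$genes), nrow(loc$truth$genes) - 1L)
  ## pipeline recovers the programmed island-length difference exactly
  big <- function(l) {
    r <- summarize_islands(scan_str_islands(l$sequences[[1]], "GA",
                                            contig = "cluster1"))
    r$length_nt[!is.na(r$island_rank)]
  }
  expect_equal(big(loc)[2] - big(al)[2], 130L)
  expect_equal(big(loc)[1], big(al)[1])
  ## and the gene-count difference
  g_orig <- annotate_genes(loc$sequences[[1]], contig = "cluster1")
  g_alle <- annotate_genes(al$sequences[[1]], contig = "cluster1")
  expect_equal(nrow(g_orig) - nrow(g_alle), 1L)
  ## removing every gene is rejected
  expect_error(perturb_alleles(loc, gene_presence_mask = rep(FALSE, 5)),
               "remove all genes")
})
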