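test_that("probe pairs anchor candidates with the correct strand", {
  probes <- trf_probes()
  set.seed(3)
  core <- paste0(probes[["R1"]], rand_dna(800), probes[["F5"]])
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(core)))
  s <- paste0(rand_dna(400), rc, rand_dna(400))
  cands <- locate_gene_candidates(s, probes)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$strand, "-")
  expect_equal(cands$start, 400L)
  ## no hits -> empty
  expect_equal(nrow(locate_gene_candidates(rand_dna(2000), probes)), 0L)
  ## empty probe set -> parameter error
  expect_error(locate_gene_candidates(s, character(0)), "empty probe set")
})

test_that("single-probe regions are not reported as candidates", {
  probes <- trf_probes()
  set.seed(4)
  s <- paste0(rand_dna(300), probes[["F2"]], rand_dna(300))
  expect_equal(nrow(locate_gene_candidates(s, probes)), 0L)
})

test_that("annotation recovers generated gene models exactly", {
  for (seed in c(101, 202)) {
    loc <- generate_locus(locus_spec(seed = seed, n_clusters = 1,
                                     duplications = 0))
    g <- annotate_genes(loc$sequences[[1]], contig = "cluster1")
    expect_equal(nrow(attr(g, "failures")), 0L)
    expect_models_equal(g, loc$truth$genes)
  }
})

test_that("annotating the reverse complement mirrors the coordinates", {
  loc <- generate_locus(locus_spec(seed = 55, n_clusters = 1,
                                   genes_per_cluster = 2, duplications = 0))
  s <- loc$sequences[[1]]
  n <- length(s)
  g_f <- annotate_genes(s, contig = "c")
  g_r <- annotate_genes(Biostrings::reverseComplement(s), contig = "c")
  g_f <- g_f[order(g_f$gene_start), ]
  g_r <- g_r[order(-g_r$gene_start), ]
  expect_equal(nrow(g_f), nrow(g_r))
  for (i in seq_len(nrow(g_f))) {
    expect_equal(g_r$gene_start[i], n - g_f$gene_end[i])
    expect_equal(g_r$gene_end[i], n - g_f$gene_start[i])
    expect_true(g_r$strand[i] != g_f$strand[i])
    expect_equal(g_r$intron_len[i], g_f$intron_len[i])
    expect_equal(g_r$stop_class[i], g_f$stop_class[i])
    expect_equal(g_r$tx_start[i], n - 1L - g_f$tx_start[i])
  }
})

test_that("annotation failures carry explicit reasons, never silent skips", {
  loc <- generate_locus(locus_spec(seed = 77, n_clusters = 1,
                                   genes_per_cluster = 1, duplications = 0))
  s <- as.character(loc$sequences[[1]])
  m <- loc$truth$genes[1, ]
  ## break the TATA box of the (plus-strand oriented) gene
  stopifnot(m$strand %in% c("+", "-"))
  ch <- strsplit(s, "")[[1]]
  if (m$strand == "+") {
    tata_at <- m$tx_start - 32L
    ch[(tata_at + 1):(tata_at + 6)] <- c("C", "C", "C", "C", "C", "C")
  } else {
    tata_at <- m$tx_start + 32L
    ch[(tata_at - 5):(tata_at + 1)] <- "G"
  }
  broken <- paste(ch, collapse = "")
  g <- annotate_genes(broken, contig = "c")
  expect_equal(nrow(g), 0L)
  fails <- attr(g, "failures")
  expect_equal(nrow(fails), 1L)
  expect_match(fails$reason, "no TATA")
})

test_that("validate_gene_model flags broken splice signals and passes truth", {
  loc <- generate_locus(locus_spec(seed = 88, n_clusters = 1,
                                   genes_per_cluster = 1, duplications = 0))
  s <- loc$sequences[[1]]
  m <- loc$truth$genes[1, ]
  rep_ok <- validate_gene_model(m, s)
  expect_true(all(rep_ok$pass))
  ## shift the intron by 1 nt: GT check must fail
  m_bad <- m
  m_bad$intron_start <- m$intron_start + 1L
  rep_bad <- validate_gene_model(m_bad, s)
  expect_false(rep_bad$pass[rep_bad$check == "splice_gt"] &&
                 rep_bad$pass[rep_bad$check == "splice_ag"])
})
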