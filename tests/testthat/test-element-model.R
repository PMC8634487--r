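ref <- trf_reference("repeat_based")

test_that("the scheme consensus decomposes to an all-present pattern,
           deterministically", {
  p1 <- assign_element_pattern(ref$consensus, ref)
  expect_true(all(p1$presence))
  expect_equal(length(p1$presence), 27L)
  expect_equal(nrow(p1$junctions), 0L)
  p2 <- assign_element_pattern(ref$consensus, ref)
  expect_identical(p1$presence, p2$presence)
  expect_identical(p1$occupancy, p2$occupancy)
})

test_that("the cDNA-based scheme shares the consensus and keys on element 15", {
  cd <- trf_reference("cDNA_based")
  expect_equal(cd$consensus, ref$consensus)
  expect_equal(nrow(cd$elements), 26L)
  expect_equal(cd$key_element, 15L)
  ## block 15 spans exactly the repeat-based key element 10
  expect_equal(cd$elements$start[15], ref$elements$start[10])
  expect_equal(cd$elements$end[15], ref$elements$end[10])
  p <- assign_element_pattern(ref$consensus, cd)
  expect_true(all(p$presence))
})

test_that("an element-range deletion joining two partial fragments is
           reported as a junction with the retained lengths", {
  els <- ref$elements
  seg <- function(i) substr(ref$consensus, els$start[i] + 1L, els$end[i])
  ## keep element 1, first 10 nt of element 2, last 35 nt of element 5,
  ## then elements 6..27 (removed total is a codon multiple)
  ex2 <- paste0(seg(1), substr(seg(2), 1, 10),
                substr(seg(5), nchar(seg(5)) - 34L, nchar(seg(5))),
                paste(vapply(6:27, seg, character(1)), collapse = ""))
  p <- assign_element_pattern(ex2, ref)
  expect_false(any(p$presence[3:4]))
  expect_true(all(p$presence[c(1, 6:27)]))
  expect_true(nrow(p$junctions) >= 1L)
  j <- p$junctions[1, ]
  expect_equal(j$left_element, 2L)
  expect_equal(j$left_kept_nt, 10L)
  expect_equal(j$right_element, 5L)
  expect_equal(j$right_kept_nt, 35L)
})

test_that("generated element masks are recovered exactly without mutation", {
  loc <- generate_locus(locus_spec(seed = 31, n_clusters = 1,
                                   genes_per_cluster = 3, duplications = 0,
                                   snp_rate = 0))
  for (i in seq_len(nrow(loc$truth$genes))) {
    m <- loc$truth$genes[i, ]
    pat <- assign_element_pattern(truth_region(loc, m, "exon2"), ref)
    truth_mask <- strsplit(m$element_mask, "")[[1]] == "1"
    expect_identical(pat$presence, truth_mask, info = m$gene_id)
    expect_equal(pat$subtype, m$subtype, info = m$gene_id)
  }
})

test_that("deleting an element never makes an absent element present", {
  set.seed(5)
  els <- ref$elements
  seg <- function(i) substr(ref$consensus, els$start[i] + 1L, els$end[i])
  for (rep in 1:6) {
    drop1 <- sample(2:26, 3)
    mask1 <- setdiff(1:27, drop1)
    ex2a <- paste(vapply(mask1, seg, character(1)), collapse = "")
    pa <- assign_element_pattern(ex2a, ref)
    drop2 <- c(drop1, sample(setdiff(2:26, drop1), 2))
    mask2 <- setdiff(1:27, drop2)
    ex2b <- paste(vapply(mask2, seg, character(1)), collapse = "")
    pb <- assign_element_pattern(ex2b, ref)
    expect_true(all(!pa$presence | pb$presence | !pb$presence))
    ## monotonicity: nothing absent in a becomes present in b
    expect_true(all(!(!pa$presence & pb$presence)))
  }
})

test_that("severely diverged input is rejected as unalignable", {
  set.seed(9)
  expect_error(assign_element_pattern(rand_dna(1400), ref), "unalignable")
})

test_that("intron classification matches the nearest-reference oracle", {
  refs <- trf_reference_introns()
  ## each reference classifies as itself at 100%
  for (nm in names(refs)) {
    it <- classify_intron_type(refs[[nm]], refs)
    expect_equal(it$label, nm)
    expect_equal(it$identity, 100)
  }
  ## mutated copies classify as their source; argmax computed independently
  set.seed(13)
  for (nm in c("alpha", "gamma", "epsilon")) {
    ch <- strsplit(refs[[nm]], "")[[1]]
    idx <- sample(seq_along(ch), 25)
    ch[idx] <- sample(c("A", "C", "G", "T"), 25, TRUE)
    q <- paste(ch, collapse = "")
    it <- classify_intron_type(q, refs)
    oracle_ids <- vapply(refs, function(r) {
      Biostrings::pid(Biostrings::pairwiseAlignment(q, r, type = "global"))
    }, numeric(1))
    expect_equal(it$label, names(oracle_ids)[which.max(oracle_ids)])
  }
  expect_error(classify_intron_type("", refs), "empty intron")
})

test_that("a chimeric intron reports the alien central segment", {
  refs <- trf_reference_introns()
  beta <- refs[["beta"]]
  gamma <- refs[["gamma"]]
  chim <- paste0(substr(beta, 1, 180), substr(gamma, 150, 330),
                 substr(beta, 290, nchar(beta)))
  it <- classify_intron_type(chim, refs)
  expect_equal(it$label, "beta")
  expect_true(nrow(it$chimera) >= 1L)
  expect_true("gamma" %in% it$chimera$donor_type)
  ## the alien window overlaps the substituted region
  g <- it$chimera[it$chimera$donor_type == "gamma", ][1, ]
  expect_true(g$start < 380 && g$end > 160)
})

test_that("gene names derive from key-element subtype and catalogue patterns", {
  catalogue <- trf_pattern_catalogue()
  els <- ref$elements
  seg <- function(i, subtype = NULL) {
    if (!is.null(subtype) && i == ref$key_element) {
      return(ref$key_subtypes[[subtype]])
    }
    substr(ref$consensus, els$start[i] + 1L, els$end[i])
  }
  make_ex2 <- function(absent, subtype = NULL) {
    keep <- setdiff(1:27, absent)
    paste(vapply(keep, seg, character(1), subtype = subtype), collapse = "")
  }
  ## catalogued E2 pattern with subtype E -> "E2"
  e2 <- make_ex2(c(4:9, 12, 13, 17, 22, 23, 24), "E")
  p_e2 <- assign_element_pattern(e2, ref)
  expect_equal(derive_gene_name(p_e2, catalogue), "E2")
  ## key element absent -> name begins "0"
  o1 <- make_ex2(c(4:10, 12, 13, 17))
  p_o1 <- assign_element_pattern(o1, ref)
  expect_true(is.na(p_o1$subtype))
  expect_match(derive_gene_name(p_o1, catalogue), "^0")
  ## repeated identical pattern in one locus gets suffix letters
  nms <- derive_gene_names(list(p_e2, p_e2, p_o1), catalogue)
  expect_equal(nms[1], "E2")
  expect_equal(nms[2], "E2a")
})

test_that("element reference fixture files round-trip", {
  d <- tempfile("refdir")
  write_element_reference(ref, d)
  back <- read_element_reference(d, "repeat_based")
  expect_equal(back$consensus, ref$consensus)
  expect_equal(back$elements$start, ref$elements$start)
  expect_equal(back$stop_columns, ref$stop_columns)
  expect_equal(back$key_subtypes, ref$key_subtypes)
})
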