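test_that("codon alignment excludes gapped and ambiguous columns", {
  ca <- codon_alignment("ATGAAA---TTT", "ATGAAGNNNTTC")
  expect_equal(length(ca$codons_a), 3L)
  expect_equal(ca$excluded, 1L)
})

test_that("synonymous and nonsynonymous single changes are called from the
           genetic code", {
  p <- dnds_pair("TTTAAA", "TTCAAA")      # Phe TTT -> TTC, synonymous
  expect_equal(p$counts[["Sd"]], 1)
  expect_equal(p$counts[["Sn"]], 0)
  expect_equal(p$snps$totals[["n_synonymous"]], 1L)
  p2 <- dnds_pair("TTTAAA", "GTTAAA")     # Phe -> Val, nonsynonymous
  expect_equal(p2$counts[["Sd"]], 0)
  expect_equal(p2$counts[["Sn"]], 1)
  ## identical alignment: no SNPs, undefined ratio
  p3 <- dnds_pair("TTTAAA", "TTTAAA")
  expect_equal(p3$snps$totals[["n_snps"]], 0L)
  expect_true(p3$dnds$undefined)
})

test_that("multi-difference codons equal the exhaustive pathway oracle", {
  set.seed(8)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  pairs <- expand.grid(a = sample(sense, 12), b = sample(sense, 12),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  for (i in seq_len(nrow(pairs))) {
    got <- ng86_counts(codon_alignment(pairs$a[i], pairs$b[i]))
    want <- oracle_path_counts(pairs$a[i], pairs$b[i])
    if (is.null(want)) next
    expect_equal(got[["Sd"]], want[["sd"]],
                 info = paste(pairs$a[i], pairs$b[i]))
    expect_equal(got[["Sn"]], want[["sn"]],
                 info = paste(pairs$a[i], pairs$b[i]))
    ## conservation: steps sum to the base differences when no pathway is
    ## excluded
    ndiff <- sum(strsplit(pairs$a[i], "")[[1]] != strsplit(pairs$b[i], "")[[1]])
    expect_equal(got[["Sd"]] + got[["Sn"]], ndiff,
                 info = paste(pairs$a[i], pairs$b[i]))
  }
})

test_that("counts are symmetric in the two sequences", {
  set.seed(9)
  a <- "ATGTTTGGCAAACGA"
  b <- "ATGTTCGGGAAGCGT"
  ab <- ng86_counts(codon_alignment(a, b))
  ba <- ng86_counts(codon_alignment(b, a))
  expect_equal(ab, ba)
})

test_that("dN/dS is undefined at zero substitutions and follows the
           Jukes-Cantor correction otherwise", {
  r0 <- dnds_ratio(c(syn_sites = 50, nonsyn_sites = 150, Sd = 0, Sn = 0))
  expect_true(r0$undefined)
  expect_true(is.na(r0$ratio))
  r <- dnds_ratio(c(syn_sites = 50, nonsyn_sites = 150, Sd = 5, Sn = 6))
  expect_equal(r$dS, -0.75 * log(1 - 4 * (5 / 50) / 3))
  expect_equal(r$dN, -0.75 * log(1 - 4 * (6 / 150) / 3))
  expect_equal(r$ratio, r$dN / r$dS)
  expect_equal(r$selection, "purifying")
  ## saturation: 4p/3 >= 1 is undefined, not an error
  rs <- dnds_ratio(c(syn_sites = 4, nonsyn_sites = 150, Sd = 3, Sn = 1))
  expect_true(rs$undefined)
})

test_that("synonymous-only divergence drives the ratio to zero and
           nonsynonymous-only divergence above one", {
  ## sixty codons; mutate a modest number of sites so the Jukes-Cantor
  ## correction stays below saturation
  codons_syn <- c("GGT", "CCT", "ACT", "GCT", "CGT", "TCT")
  a_codons <- rep(codons_syn, 10)
  b_syn <- a_codons
  b_syn[seq(1, 60, by = 6)] <- sub("T$", "C", b_syn[seq(1, 60, by = 6)])
  r_syn <- dnds_pair(paste(a_codons, collapse = ""),
                     paste(b_syn, collapse = ""))$dnds
  expect_false(r_syn$undefined)
  expect_equal(r_syn$ratio, 0)
  ## a nonsynonymous-dominated pair (dS = 0 alone is undefined by
  ## construction, so keep one synonymous change to anchor the denominator)
  b_non <- a_codons
  b_non[seq(1, 60, by = 6)] <- "AGT"   # GGT (Gly) -> AGT (Ser), nonsynonymous
  b_non[2] <- sub("T$", "C", b_non[2]) # one synonymous change
  r_non <- dnds_pair(paste(a_codons, collapse = ""),
                     paste(b_non, collapse = ""))$dnds
  expect_false(r_non$undefined)
  expect_gt(r_non$ratio, 1)
  ## purely nonsynonymous divergence: dS = 0, flagged undefined rather than
  ## reported as a number
  b_only <- a_codons
  b_only[seq(1, 60, by = 6)] <- "AGT"
  expect_true(dnds_pair(paste(a_codons, collapse = ""),
                        paste(b_only, collapse = ""))$dnds$undefined)
})

test_that("SNP catalogue reports amino-acid property shifts", {
  ## GAA (Glu, acidic) -> AAA (Lys, basic): one SNP, charge shift
  p <- dnds_pair("ATGGAA", "ATGAAA")
  expect_equal(p$snps$totals[["n_nonsynonymous"]], 1L)
  expect_equal(p$snps$totals[["n_property_shift"]], 1L)
  expect_equal(p$snps$snps$charge_a, "acidic")
  expect_equal(p$snps$snps$charge_b, "basic")
  ## Leu -> Ile: hydropathically similar, neutral charge and pI both sides
  q <- dnds_pair("CTTAAA", "ATTAAA")
  expect_equal(q$snps$totals[["n_aa_changes"]], 1L)
  expect_equal(q$snps$totals[["n_property_shift"]], 0L)
})
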