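test_that("identical sequences give identity 100 and coverage 100", {
  set.seed(2)
  s <- rand_dna(1000)
  expect_equal(identity_and_coverage(s, s),
               c(identity = 100, coverage = 100))
  expect_error(identity_and_coverage("", s), "empty")
})

test_that("identity and coverage respond separately to mismatches and
           truncation", {
  set.seed(3)
  s <- rand_dna(1000)
  ch <- strsplit(s, "")[[1]]
  ch[seq(10, 1000, by = 50)] <- "N"   # scattered mismatches, full span
  ic <- identity_and_coverage(s, paste(ch, collapse = ""))
  expect_lt(ic[["identity"]], 100)
  expect_equal(ic[["coverage"]], 100)
  ## query half-contained in subject: coverage ~50
  ic2 <- identity_and_coverage(s, substr(s, 1, 500))
  expect_equal(ic2[["identity"]], 100)
  expect_equal(ic2[["coverage"]], 50)
})

test_that("identity matrix treats gaps per the fifth-state flag", {
  expect_equal(identity_matrix(c(a = "AC-T", b = "ACGT"), TRUE)["a", "b"], 3 / 4)
  expect_equal(identity_matrix(c(a = "AC-T", b = "ACGT"), FALSE)["a", "b"], 1)
  ## gap-gap counts as identity with the flag
  expect_equal(identity_matrix(c(a = "AC-T", b = "AC-T"), TRUE)["a", "b"], 1)
  ## flagged and unflagged differ only when gaps are present
  set.seed(4)
  x <- rand_dna(60); y <- rand_dna(60)
  m1 <- identity_matrix(c(a = x, b = y), TRUE)
  m2 <- identity_matrix(c(a = x, b = y), FALSE)
  expect_equal(m1, m2)
  expect_error(identity_matrix(c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("percent mismatch follows 100*p/ln(2) and is zero for identical
           rows", {
  aln <- c(g1 = "ACGTACGTAC", g2 = "ACGTACGTAC")
  pm <- percent_mismatch(aln)
  expect_equal(pm$pairs$percent_mismatch, 0)
  ## p = 0.15 -> 21.64%
  expect_equal(round(100 * 0.15 / log(2), 2), 21.64)
  aln2 <- c(a = paste(rep("A", 100), collapse = ""),
            b = paste(c(rep("C", 15), rep("A", 85)), collapse = ""))
  pm2 <- percent_mismatch(aln2)
  expect_equal(round(pm2$pairs$percent_mismatch, 2), 21.64)
})

test_that("percent mismatch is linear in p: doubling length at fixed
           mismatches halves it", {
  mk <- function(len, nmis) {
    a <- paste(rep("A", len), collapse = "")
    b <- paste(c(rep("G", nmis), rep("A", len - nmis)), collapse = "")
    percent_mismatch(c(a = a, b = b))$pairs$percent_mismatch
  }
  expect_equal(mk(2000, 30), mk(1000, 30) / 2)
})

test_that("per-gene averages equal a direct all-pairs recomputation", {
  set.seed(6)
  base <- rand_dna(300)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- sample(c("A", "C", "G", "T"), k, TRUE)
    paste(ch, collapse = "")
  }
  aln <- c(a = base, b = mut(base, 10), c = mut(base, 25), d = mut(base, 40),
           e = mut(base, 60))
  pm <- percent_mismatch(aln)
  ## independent recomputation
  nm <- names(aln)
  for (g in nm) {
    vals <- vapply(setdiff(nm, g), function(h) {
      x <- strsplit(aln[[g]], "")[[1]]; y <- strsplit(aln[[h]], "")[[1]]
      keep <- x != "-" & y != "-"
      100 * mean(x[keep] != y[keep]) / log(2)
    }, numeric(1))
    expect_equal(pm$per_gene$mean_percent_mismatch[pm$per_gene$gene == g],
                 mean(vals))
  }
  ## symmetry of the pair table
  p <- pm$pairs
  for (i in seq_len(nrow(p))) {
    rev_val <- percent_mismatch(aln[c(p$gene_b[i], p$gene_a[i])])
    expect_equal(rev_val$pairs$percent_mismatch, p$percent_mismatch[i])
  }
})

test_that("all-gap pairs are flagged incomparable and excluded from averages", {
  aln <- c(a = "----", b = "ACGT", c = "ACGA")
  pm <- percent_mismatch(aln)
  ab <- pm$pairs[pm$pairs$gene_a == "a" & pm$pairs$gene_b == "b", ]
  expect_false(ab$comparable)
  expect_true(is.na(pm$per_gene$mean_percent_mismatch[pm$per_gene$gene == "a"]))
  bc <- pm$per_gene$mean_percent_mismatch[pm$per_gene$gene == "b"]
  expect_false(is.na(bc))
})
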