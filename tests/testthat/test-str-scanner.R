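test_that("a pure repeat is one island spanning the whole run", {
  out <- scan_str_islands(strrep("GA", 5), "GA")
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 0L)
  expect_equal(out$end, 10L)
  expect_equal(out$mismatches, 0L)
  out3 <- scan_str_islands(strrep("GAT", 4), "GAT")
  expect_equal(out3$length_nt, 12L)
})

test_that("sequences without a seed yield no islands", {
  expect_equal(nrow(scan_str_islands(strrep("C", 50), "GA")), 0L)
  expect_equal(nrow(scan_str_islands("GAGAG", "GA")), 0L)  # below seed length
})

test_that("unknown motif is a parameter error", {
  expect_error(scan_str_islands("GAGAGA", "CT"))
})

test_that("scanner equals the exhaustive-window oracle on random sequences", {
  set.seed(42)
  for (rep in 1:25) {
    s <- rand_dna(800)
    ## implant repeat patches with scattered mismatches
    if (rep %% 2 == 0) {
      patch <- strrep("GA", 30)
      pc <- strsplit(patch, "")[[1]]
      pc[sample(60, 3)] <- "T"
      at <- sample(700, 1)
      s <- paste0(substr(s, 1, at), paste(pc, collapse = ""),
                  substr(s, at + 1, 800))
    }
    for (motif in c("GA", "GAT")) {
      got <- scan_str_islands(s, motif, merge_gap = 10L)
      want <- oracle_str_islands(s, motif, merge_gap = 10L)
      expect_equal(got$start, want$start, info = paste("rep", rep, motif))
      expect_equal(got$end, want$end, info = paste("rep", rep, motif))
      expect_equal(got$mismatches, want$mismatches,
                   info = paste("rep", rep, motif))
    }
  }
})

test_that("islands are sorted, non-overlapping, and contain a seed", {
  set.seed(7)
  s <- paste0(rand_dna(200), strrep("GA", 20), rand_dna(100),
              strrep("GA", 8), rand_dna(200))
  out <- scan_str_islands(s, "GA", merge_gap = 20L)
  expect_true(all(diff(out$start) > 0))
  expect_true(all(utils::head(out$end, -1) <= utils::tail(out$start, -1)))
  expect_true(all(out$length_nt >= 6L))
})

test_that("increasing merge_gap never increases the island count", {
  set.seed(11)
  s <- paste0(strrep("GA", 10), rand_dna(30), strrep("GA", 10),
              rand_dna(80), strrep("GA", 10))
  counts <- vapply(c(0L, 10L, 40L, 100L, 500L), function(g) {
    nrow(scan_str_islands(s, "GA", merge_gap = g))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("both-strands wrapper reports GA runs on the reverse strand", {
  set.seed(2)
  s <- paste0(rand_dna(50), strrep("TC", 12), rand_dna(50))
  fwd_only <- scan_str_islands(s, "GA", merge_gap = 0L)
  both <- scan_str_both_strands(s, "GA", merge_gap = 0L)
  expect_equal(nrow(fwd_only), 0L)
  expect_equal(nrow(both), 1L)
  expect_equal(both$strand, "-")
  ## single-mismatch windows may pick up a couple of flanking bases
  expect_true(abs(both$start - 50L) <= 4L)   # forward-strand coordinates
  expect_true(both$end - both$start >= 24L &&
                both$end - both$start <= 30L)
})

test_that("summarize_islands ranks large islands 5' to 3' and separates flanking STRs", {
  isl <- data.frame(contig = "c", start = c(0L, 5000L, 6000L, 12000L),
                    end = c(4293L, 5120L, 9869L, 14633L), motif = "GA",
                    length_nt = c(4293L, 120L, 3869L, 2633L),
                    mismatches = 0L)
  rep <- summarize_islands(isl, min_island_length = 1000L)
  expect_equal(rep$island_rank[rep$class == "island"],
               c("STR1", "STR2", "STR3"))
  expect_equal(rep$length_nt[which(rep$island_rank == "STR1")], 4293L)
  expect_equal(rep$length_nt[which(rep$island_rank == "STR2")], 3869L)
  expect_equal(rep$length_nt[which(rep$island_rank == "STR3")], 2633L)
  expect_equal(sum(rep$class == "flanking"), 1L)
  expect_equal(nrow(summarize_islands(isl[0, ])), 0L)
})
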