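## Independent brute-force oracles used by the unit and acceptance tests.
## These deliberately share no code with the package implementations.

## exhaustive-window STR island oracle: enumerate every window of the seed
## length, count mismatches against the seed by explicit character
## comparison, union the passing windows, then apply the same merge rule.
oracle_str_islands <- function(seq_chr, motif, merge_gap = 50L) {
  unit <- c(GA = "GA", GAT = "GAT")[[motif]]
  seed <- strrep(unit, 3L)
  L <- nchar(seed)
  ch <- strsplit(seq_chr, "")[[1]]
  n <- length(ch)
  if (n < L) return(data.frame(start = integer(0), end = integer(0),
                               mismatches = integer(0)))
  sc <- strsplit(seed, "")[[1]]
  ## mismatch count of every window via shifted comparisons
  mm <- rep(0L, n - L + 1L)
  for (j in seq_len(L)) {
    mm <- mm + (ch[seq.int(j, n - L + j)] != sc[j])
  }
  hits <- which(mm <= 1L)
  if (length(hits) == 0L) return(data.frame(start = integer(0),
                                            end = integer(0),
                                            mismatches = integer(0)))
  ## union of windows -> runs
  covered <- rep(FALSE, n)
  for (h in hits) covered[h:(h + L - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  ## per-run best-phase mismatch count (explicit loop over phases)
  uc <- strsplit(unit, "")[[1]]
  k <- length(uc)
  run_mm <- apply(runs, 1, function(rg) {
    s <- ch[rg[1]:rg[2]]
    best <- Inf
    for (p in 0:(k - 1)) {
      pat <- uc[((seq_along(s) - 1L + p) %% k) + 1L]
      best <- min(best, sum(s != pat))
    }
    best
  })
  ## merge runs with gap <= merge_gap, summing mismatches
  out <- list()
  cs <- runs[1, 1]; ce <- runs[1, 2]; cm <- run_mm[1]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs[i, 1] - ce - 1L <= merge_gap) {
      ce <- runs[i, 2]; cm <- cm + run_mm[i]
    } else {
      out[[length(out) + 1L]] <- c(cs, ce, cm)
      cs <- runs[i, 1]; ce <- runs[i, 2]; cm <- run_mm[i]
    }
  }
  out[[length(out) + 1L]] <- c(cs, ce, cm)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1] - 1L, end = m[, 2], mismatches = m[, 3])
}

## exhaustive pathway-enumeration oracle for NG86 substitution counts of a
## single codon pair (recursive depth-first enumeration, independent of the
## package's permutation code)
oracle_path_counts <- function(ca, cb) {
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  diff <- which(a != b)
  if (length(diff) == 0) return(c(sd = 0, sn = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, sn) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1L]] <<- c(sd, sn)
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      pos <- remaining[i]
      nxt <- cur; nxt[pos] <- b[pos]
      nxtc <- paste(nxt, collapse = "")
      curc <- paste(cur, collapse = "")
      if (nxtc %in% stops && nxtc != cb) next
      step_syn <- !(curc %in% stops) && !(nxtc %in% stops) &&
        code[[curc]] == code[[nxtc]]
      step_non <- !step_syn
      walk(nxt, remaining[-i], sd + as.integer(step_syn),
           sn + as.integer(step_non))
    }
  }
  walk(a, diff, 0, 0)
  if (length(paths) == 0) return(NULL)  # all pathways cross stops
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), sn = mean(m[, 2]))
}

## random test DNA (plain sampling, independent of package helpers)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## read a FASTA alignment fixture into a named character vector
read_aln_fixture <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  stats::setNames(lines[heads + 1L], sub("^>", "", lines[heads]))
}

## recover oriented region sequence of a truth gene-model row
truth_region <- function(locus, row, what = c("exon2", "intron")) {
  what <- match.arg(what)
  s <- as.character(locus$sequences[[row$contig]])
  iv <- switch(what,
               exon2 = c(row$exon2_start, row$exon2_end),
               intron = c(row$intron_start, row$intron_end))
  x <- substr(s, iv[1] + 1L, iv[2])
  if (row$strand == "-") {
    x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  x
}

## gene-model columns compared in recovery checks
MODEL_COLS <- c("strand", "tx_start", "gene_start", "gene_end",
                "utr5_len", "exon1_len", "intron_len", "exon2_len", "utr3_len",
                "exon1_start", "exon1_end", "intron_start", "intron_end",
                "exon2_start", "exon2_end", "stop_class",
                "polya_can_offset", "polya_var_offset")

expect_models_equal <- function(found, truth) {
  found <- found[order(found$gene_start), MODEL_COLS]
  truth <- truth[order(truth$gene_start), MODEL_COLS]
  rownames(found) <- rownames(truth) <- NULL
  expect_equal(found, truth)
}
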