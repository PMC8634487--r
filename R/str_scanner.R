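## str_scanner: GA / GAT short-tandem-repeat run detection and island calling.
##
## The search strings are the classic GAGAGA (GA) and GATGATGAT (GAT) seeds,
## matched allowing a single mismatch.  Overlapping/adjacent seed windows are
## chained into runs; runs separated by at most `merge_gap` nt are merged into
## islands (mismatch counts summed).  Islands may start at any phase of the
## repeat unit.

STR_UNITS <- c(GA = "GA", GAT = "GAT")

str_seed <- function(motif) strrep(STR_UNITS[[motif]], 3L)

#' Scan one strand of a contig for GA or GAT STR islands
#'
#' @param seq contig sequence: character scalar, [Biostrings::DNAString], or a
#'   length-1 [Biostrings::DNAStringSet].
#' @param motif `"GA"` or `"GAT"`.
#' @param merge_gap runs separated by at most this many nt are merged
#'   (default 50).
#' @param contig contig id recorded in the output (defaults to the sequence
#'   name if available).
#' @return data.frame with columns `contig, start, end, motif, length_nt,
#'   mismatches` (0-based half-open coordinates), sorted by `start`,
#'   non-overlapping.
#' @export
scan_str_islands <- function(seq, motif = c("GA", "GAT"), merge_gap = 50L,
                             contig = NULL) {
  motif <- match.arg(motif)
  assert_that(merge_gap >= 0, "merge_gap must be >= 0")
  if (is(seq, "DNAStringSet")) {
    if (is.null(contig)) contig <- names(seq)[1] %||% "seq"
    seq <- seq[[1]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (is.null(contig)) contig <- "seq"
  seed <- str_seed(motif)
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      length_nt = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (length(seq) < nchar(seed)) return(empty)
  hits <- Biostrings::matchPattern(seed, seq, max.mismatch = 1L)
  if (length(hits) == 0L) return(empty)
  win <- IRanges::IRanges(Biostrings::start(hits), Biostrings::end(hits))
  ## matchPattern may report windows hanging over the sequence ends
  win <- win[IRanges::start(win) >= 1L & IRanges::end(win) <= length(seq)]
  if (length(win) == 0L) return(empty)
  runs <- IRanges::reduce(win)                       # chained seed windows
  seq_chr <- as.character(seq)
  run_mm <- vapply(seq_len(length(runs)), function(i) {
    s <- substr(seq_chr, IRanges::start(runs)[i], IRanges::end(runs)[i])
    str_run_mismatches(s, STR_UNITS[[motif]])
  }, numeric(1))
  ## merge runs with gap <= merge_gap, summing mismatch counts
  merged <- IRanges::reduce(runs, min.gapwidth = merge_gap + 1L)
  ov <- IRanges::findOverlaps(runs, merged)
  mm <- tapply(run_mm[S4Vectors::queryHits(ov)],
               S4Vectors::subjectHits(ov), sum)
  data.frame(
    contig = contig,
    start = IRanges::start(merged) - 1L,
    end = IRanges::end(merged),
    motif = motif,
    length_nt = IRanges::width(merged),
    mismatches = as.integer(mm[as.character(seq_len(length(merged)))]),
    stringsAsFactors = FALSE
  )
}

## Hamming distance of a run against the best-phase periodic extension of the
## repeat unit.
str_run_mismatches <- function(run, unit) {
  rc <- dna_chars(run)
  k <- nchar(unit)
  uc <- dna_chars(unit)
  min(vapply(seq_len(k) - 1L, function(p) {
    pat <- uc[((seq_along(rc) - 1L + p) %% k) + 1L]
    sum(rc != pat)
  }, numeric(1)))
}

#' Scan both strands for STR islands
#'
#' The scanner itself is strand-specific (GA on the reverse strand reads TC on
#' the forward strand); this convenience wrapper unions the forward scan with
#' the scan of the reverse complement, reporting both in forward-strand
#' coordinates with a `strand` column.
#'
#' @inheritParams scan_str_islands
#' @return data.frame as [scan_str_islands()] plus a `strand` column.
#' @export
scan_str_both_strands <- function(seq, motif = c("GA", "GAT"), merge_gap = 50L,
                                  contig = NULL) {
  motif <- match.arg(motif)
  if (is(seq, "DNAStringSet")) {
    if (is.null(contig)) contig <- names(seq)[1] %||% "seq"
    seq <- seq[[1]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  fwd <- scan_str_islands(seq, motif, merge_gap, contig)
  rev <- scan_str_islands(Biostrings::reverseComplement(seq), motif,
                          merge_gap, contig)
  n <- length(seq)
  if (nrow(fwd) > 0) fwd$strand <- "+"
  if (nrow(rev) > 0) {
    new_start <- n - rev$end
    rev$end <- n - rev$start
    rev$start <- new_start
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Summarize STR islands into ranked large islands and gene-flanking STRs
#'
#' Islands at least `min_island_length` nt long are the multi-kb cluster
#' boundary islands and receive 5'->3' ranks (STR1, STR2, ...); shorter
#' islands are reported as gene-flanking STRs.
#'
#' @param islands data.frame from [scan_str_islands()] (one contig).
#' @param min_island_length length threshold separating the large islands
#'   from gene-flanking STRs (default 1000 nt).
#' @return data.frame with added columns `class` (`"island"` or
#'   `"flanking"`) and `island_rank` (`"STR1"` ... or NA).
#' @export
summarize_islands <- function(islands, min_island_length = 1000L) {
  islands <- as.data.frame(islands)
  if (nrow(islands) == 0L) {
    islands$class <- character(0)
    islands$island_rank <- character(0)
    return(islands)
  }
  assert_that(length(unique(islands$contig)) == 1L,
              "summarize_islands expects islands from one contig")
  islands <- islands[order(islands$start), , drop = FALSE]
  big <- islands$length_nt >= min_island_length
  islands$class <- ifelse(big, "island", "flanking")
  islands$island_rank <- NA_character_
  islands$island_rank[big] <- paste0("STR", seq_len(sum(big)))
  rownames(islands) <- NULL
  islands
}
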