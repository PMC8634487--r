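## pairwise_stats: identity/coverage (local alignment), identity matrices
## with gaps as a fifth character state, p-distances and the percent-mismatch
## statistic (100 * p / ln(n), with n the number of sequences compared; ln 2
## for pairwise values).

#' Validate and normalize a region alignment
#'
#' A region alignment is a named character vector of aligned sequences
#' (gaps `-`), all the same length, with at least two members.
#'
#' @param aln named character vector or DNAStringSet/ BStringSet.
#' @return named uppercase character vector.
#' @export
as_region_alignment <- function(aln) {
  if (is(aln, "XStringSet")) aln <- setNames(as.character(aln), names(aln))
  assert_that(is.character(aln) && length(aln) >= 2,
              "alignment needs at least 2 members")
  assert_that(length(unique(nchar(aln))) == 1L,
              "ragged alignment: members have different aligned lengths")
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  toupper(aln)
}

#' BLAST-like percent identity and coverage for a sequence pair
#'
#' Local alignment with BLASTN-like scoring (match +2, mismatch -3, gap open
#' 5, gap extend 2 by default).  Identity is identical columns over aligned
#' columns; coverage is the aligned query span over the query length; both
#' rounded to whole percent.
#'
#' @param a query sequence; @param b subject sequence.
#' @param match,mismatch,gap_opening,gap_extension scoring parameters.
#' @return named numeric `c(identity=, coverage=)`.
#' @export
identity_and_coverage <- function(a, b, match = 2, mismatch = -3,
                                  gap_opening = 5, gap_extension = 2) {
  a <- as.character(a); b <- as.character(b)
  assert_that(nchar(a) > 0 && nchar(b) > 0, "empty input sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_opening,
                                      gapExtension = gap_extension)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(pa)))
  ident <- round(100 * Biostrings::nmatch(pa) / ncol_aln)
  qspan <- Biostrings::width(Biostrings::pattern(pa))
  cover <- round(100 * qspan / nchar(a))
  c(identity = ident, coverage = cover)
}

#' Pairwise identity matrix over an alignment
#'
#' With `gaps_as_fifth_state = TRUE` a gap aligned to a residue counts as a
#' mismatch and gap-gap columns count as identities (the gap is a fifth
#' character state); with `FALSE`, columns containing a gap in either member
#' are excluded before computing the fraction identical.
#'
#' @param aln region alignment (see [as_region_alignment()]).
#' @param gaps_as_fifth_state logical flag.
#' @return symmetric numeric matrix of identity fractions, diagonal 1.
#' @export
identity_matrix <- function(aln, gaps_as_fifth_state = TRUE) {
  aln <- as_region_alignment(aln)
  n <- length(aln)
  chars <- lapply(aln, dna_chars)
  out <- matrix(1, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- chars[[i]]; y <- chars[[j]]
      if (gaps_as_fifth_state) {
        v <- mean(x == y)
      } else {
        keep <- x != "-" & y != "-"
        v <- if (any(keep)) mean(x[keep] == y[keep]) else NA_real_
      }
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}

#' p-distance matrix with pairwise deletion of gap columns
#'
#' @param aln region alignment.
#' @return symmetric matrix of p-distances (NA for all-gap pairs).
#' @export
p_distance_matrix <- function(aln) {
  aln <- as_region_alignment(aln)
  n <- length(aln)
  chars <- lapply(aln, dna_chars)
  out <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- chars[[i]]; y <- chars[[j]]
      keep <- x != "-" & y != "-"
      out[i, j] <- out[j, i] <-
        if (any(keep)) mean(x[keep] != y[keep]) else NA_real_
    }
  }
  out
}

#' Percent mismatch per pair and per gene
#'
#' Percent mismatch is 100 * p / ln(n) with p the pairwise distance and n the
#' number of sequences compared (n = 2 for a pair, so ln 2).  The per-gene
#' value is the average over all partners.  Pairs with no comparable columns
#' are flagged incomparable and excluded from averages.
#'
#' @param aln region alignment.
#' @param region optional region label carried into the output.
#' @return list with `pairs` (data.frame `gene_a, gene_b, p_distance,
#'   percent_mismatch, comparable`) and `per_gene` (data.frame `gene,
#'   mean_percent_mismatch`).
#' @export
percent_mismatch <- function(aln, region = NA_character_) {
  aln <- as_region_alignment(aln)
  pm <- p_distance_matrix(aln)
  nm <- names(aln)
  n <- length(nm)
  pairs <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    do.call(rbind, lapply((i + 1):n, function(j) {
      p <- pm[i, j]
      data.frame(region = region, gene_a = nm[i], gene_b = nm[j],
                 p_distance = p,
                 percent_mismatch = 100 * p / log(2),
                 comparable = !is.na(p), stringsAsFactors = FALSE)
    }))
  }))
  per_gene <- data.frame(
    gene = nm,
    mean_percent_mismatch = vapply(seq_len(n), function(i) {
      vals <- 100 * pm[i, -i] / log(2)
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, per_gene = per_gene)
}
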