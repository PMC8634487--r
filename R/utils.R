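## Internal helpers shared across modules.  All genomic coordinates inside the
## package are 0-based half-open on the forward strand; GFF3 emission converts
## to 1-based inclusive.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## DNA string helpers operating on plain character scalars -------------------

dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_dna <- function(x) paste(x, collapse = "")

#' Reverse complement of a plain character DNA string (IUPAC aware)
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

subseq_chr <- function(x, start0, end0) {
  ## 0-based half-open extraction from a character scalar
  substr(x, start0 + 1L, end0)
}

#' Deterministic RNG scope: evaluates `expr` under a local seed and restores
#' the caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Random DNA of length n (uniform or GC-weighted), character scalar
#' @noRd
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars_dna(sample(names(p), n, replace = TRUE, prob = p))
}

## Genetic code helpers ------------------------------------------------------

GENETIC_CODE_STD <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) unname(GENETIC_CODE_STD[codon])

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

## Amino acid property classes used when cataloguing nonsynonymous SNPs.
## Charge: acidic {D,E}, basic {K,R,H}, neutral otherwise.  pI terciles of the
## twenty residues (low < 5.5, high > 7.5) follow standard free-residue pI
## tables; both are configurable at the call sites that use them.
AA_PI <- c(A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.07, E = 3.22,
           Q = 5.65, G = 5.97, H = 7.59, I = 6.02, L = 5.98, K = 9.74,
           M = 5.74, F = 5.48, P = 6.30, S = 5.68, T = 5.60, W = 5.89,
           Y = 5.66, V = 5.96)

aa_charge_class <- function(aa) {
  unname(ifelse(aa %in% c("D", "E"), "acidic",
                ifelse(aa %in% c("K", "R", "H"), "basic", "neutral")))
}

aa_pi_class <- function(aa) {
  pi <- unname(AA_PI[aa])
  unname(ifelse(is.na(pi), NA_character_,
                ifelse(pi < 5.5, "low", ifelse(pi > 7.5, "high", "neutral"))))
}
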