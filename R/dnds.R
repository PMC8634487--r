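## dnds: SNP cataloguing between same-element-pattern genes and NG86
## (Nei-Gojobori) dN/dS with Jukes-Cantor correction, following the pathway
## counting used by SNAP: codons differing at k bases contribute the average
## over all k! substitution orderings, pathways through stop codons excluded.

#' Build a codon alignment from two aligned coding sequences
#'
#' Input sequences must be aligned (equal length, `-` gaps allowed) and in
#' frame.  Codon columns containing a gap, an ambiguity code, or an
#' incomplete codon in either member are excluded and counted.
#'
#' @param a,b aligned coding sequences (character / DNAString).
#' @return `trf_codon_alignment`: list `codons_a`, `codons_b` (character
#'   vectors), `excluded` (count of excluded codon columns).
#' @export
codon_alignment <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  assert_that(nchar(a) == nchar(b), "aligned sequences must have equal length")
  n <- (nchar(a) %/% 3L) * 3L
  ca <- substring(a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(b, seq(1, n, 3), seq(3, n, 3))
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  structure(list(codons_a = ca[ok], codons_b = cb[ok],
                 excluded = sum(!ok) + as.integer(nchar(a) %% 3L > 0)),
            class = "trf_codon_alignment")
}

## per-codon synonymous site count: at each position, the fraction of
## non-stop single-base changes that are synonymous (changes to stop codons
## are disregarded, as in NG86)
syn_sites_codon <- function(codon) {
  if (is_stop_codon(codon)) return(0)
  aa <- translate_codon(codon)
  ch <- dna_chars(codon)
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), ch[pos])
    nsyn <- 0; nvalid <- 0
    for (alt in alts) {
      mut <- ch; mut[pos] <- alt
      mc <- chars_dna(mut)
      if (is_stop_codon(mc)) next
      nvalid <- nvalid + 1
      if (translate_codon(mc) == aa) nsyn <- nsyn + 1
    }
    if (nvalid > 0) s <- s + nsyn / nvalid
  }
  s
}

## pathway-averaged (Sd, Sn) contribution of one codon pair
path_counts_codon <- function(ca, cb) {
  diff_pos <- which(dna_chars(ca) != dna_chars(cb))
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, sn = 0))
  orders <- if (k == 1L) list(diff_pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    perms(diff_pos)
  }
  acc <- matrix(0, nrow = 0, ncol = 2)
  for (ord in orders) {
    cur <- dna_chars(ca)
    tgt <- dna_chars(cb)
    sd <- 0; sn <- 0; ok <- TRUE
    for (pos in ord) {
      prev <- chars_dna(cur)
      cur[pos] <- tgt[pos]
      nxt <- chars_dna(cur)
      if (is_stop_codon(nxt) && nxt != cb) { ok <- FALSE; break }
      if (is_stop_codon(prev) || is_stop_codon(nxt)) {
        ## endpoint stop (e.g. terminal codon): count as nonsynonymous step
        sn <- sn + 1
      } else if (translate_codon(prev) == translate_codon(nxt)) {
        sd <- sd + 1
      } else {
        sn <- sn + 1
      }
    }
    if (ok) acc <- rbind(acc, c(sd, sn))
  }
  if (nrow(acc) == 0L) {
    ## all pathways cross stops: fall back to the direct per-base coding
    ## effect of each change applied alone
    sd <- 0; sn <- 0
    for (pos in diff_pos) {
      mut <- dna_chars(ca); mut[pos] <- dna_chars(cb)[pos]
      mc <- chars_dna(mut)
      if (!is_stop_codon(ca) && !is_stop_codon(mc) &&
          translate_codon(ca) == translate_codon(mc)) sd <- sd + 1 else sn <- sn + 1
    }
    return(c(sd = sd, sn = sn))
  }
  c(sd = mean(acc[, 1]), sn = mean(acc[, 2]))
}

#' NG86 site and substitution counts for a codon alignment
#'
#' Sites: each codon position contributes its fraction of possible synonymous
#' single-base changes, averaged over the two sequences.  Substitutions:
#' pathway-averaged synonymous (Sd) and nonsynonymous (Sn) step counts.
#'
#' @param aln a `trf_codon_alignment`.
#' @return named numeric `c(syn_sites, nonsyn_sites, Sd, Sn)`.
#' @export
ng86_counts <- function(aln) {
  stopifnot(inherits(aln, "trf_codon_alignment"))
  sa <- sum(vapply(aln$codons_a, syn_sites_codon, numeric(1)))
  sb <- sum(vapply(aln$codons_b, syn_sites_codon, numeric(1)))
  S <- (sa + sb) / 2
  N <- 3 * length(aln$codons_a) - S
  sd <- 0; sn <- 0
  for (i in seq_along(aln$codons_a)) {
    pc <- path_counts_codon(aln$codons_a[i], aln$codons_b[i])
    sd <- sd + pc[["sd"]]
    sn <- sn + pc[["sn"]]
  }
  c(syn_sites = S, nonsyn_sites = N, Sd = sd, Sn = sn)
}

#' Jukes-Cantor corrected dN/dS from NG86 counts
#'
#' pS = Sd/S and pN = Sn/N are corrected as d = -(3/4) ln(1 - 4p/3); the
#' ratio is dN/dS.  The ratio is undefined (not an error) when there are no
#' substitutions, when dS = 0, or when 4p/3 >= 1 makes the correction
#' inapplicable.  Selection is labeled purifying (< 1) or diversifying (> 1).
#'
#' @param counts output of [ng86_counts()].
#' @return `trf_dnds`: list `syn_sites, nonsyn_sites, Sd, Sn, pS, pN, dS, dN,
#'   ratio, undefined, selection`.
#' @export
dnds_ratio <- function(counts) {
  S <- counts[["syn_sites"]]; N <- counts[["nonsyn_sites"]]
  Sd <- counts[["Sd"]]; Sn <- counts[["Sn"]]
  jc <- function(p) if (is.na(p) || 4 * p / 3 >= 1) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Sn / N else NA_real_
  dS <- jc(pS); dN <- jc(pN)
  undefined <- (Sd + Sn) == 0 || is.na(dS) || is.na(dN) || dS == 0
  ratio <- if (undefined) NA_real_ else dN / dS
  selection <- if (undefined) NA_character_ else
    if (ratio > 1) "diversifying" else if (ratio < 1) "purifying" else "neutral"
  structure(list(syn_sites = S, nonsyn_sites = N, Sd = Sd, Sn = Sn,
                 pS = pS, pN = pN, dS = dS, dN = dN,
                 ratio = ratio, undefined = undefined, selection = selection),
            class = "trf_dnds")
}

#' Catalogue SNPs between two aligned coding sequences
#'
#' Reports every differing codon-alignment site with its bases, the
#' synonymous/nonsynonymous call of the single-base change applied alone, the
#' encoded amino acids, and whether the change alters the charge class
#' (acidic / basic / neutral) or the pI class (low / neutral / high terciles
#' of the twenty residues).
#'
#' @param aln a `trf_codon_alignment`.
#' @return list `snps` (data.frame), `totals` (named counts: n_snps,
#'   n_synonymous, n_nonsynonymous, n_aa_changes, n_property_shift,
#'   excluded_columns).
#' @export
catalog_snps <- function(aln) {
  stopifnot(inherits(aln, "trf_codon_alignment"))
  rows <- list()
  aa_changes <- 0L
  prop_shift <- 0L
  for (i in seq_along(aln$codons_a)) {
    ca <- aln$codons_a[i]; cb <- aln$codons_b[i]
    if (ca == cb) next
    aa_a <- translate_codon(ca); aa_b <- translate_codon(cb)
    if (aa_a != aa_b) {
      aa_changes <- aa_changes + 1L
      shift <- !identical(aa_charge_class(aa_a), aa_charge_class(aa_b)) ||
        !identical(aa_pi_class(aa_a), aa_pi_class(aa_b))
      if (isTRUE(shift)) prop_shift <- prop_shift + 1L
    }
    pos <- which(dna_chars(ca) != dna_chars(cb))
    for (p in pos) {
      mut <- dna_chars(ca); mut[p] <- dna_chars(cb)[p]
      mc <- chars_dna(mut)
      syn <- !is_stop_codon(ca) && !is_stop_codon(mc) &&
        translate_codon(ca) == translate_codon(mc)
      rows[[length(rows) + 1L]] <- data.frame(
        codon_index = i, position = 3L * (i - 1L) + p,
        base_a = dna_chars(ca)[p], base_b = dna_chars(cb)[p],
        synonymous = syn, aa_a = aa_a, aa_b = aa_b,
        charge_a = aa_charge_class(aa_a), charge_b = aa_charge_class(aa_b),
        pi_a = aa_pi_class(aa_a), pi_b = aa_pi_class(aa_b),
        stringsAsFactors = FALSE)
    }
  }
  snps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(codon_index = integer(0), position = integer(0),
               base_a = character(0), base_b = character(0),
               synonymous = logical(0), aa_a = character(0),
               aa_b = character(0), charge_a = character(0),
               charge_b = character(0), pi_a = character(0),
               pi_b = character(0), stringsAsFactors = FALSE)
  list(snps = snps,
       totals = c(n_snps = nrow(snps),
                  n_synonymous = sum(snps$synonymous),
                  n_nonsynonymous = sum(!snps$synonymous),
                  n_aa_changes = aa_changes,
                  n_property_shift = prop_shift,
                  excluded_columns = aln$excluded))
}

#' Full dN/dS analysis for an aligned coding sequence pair
#'
#' @param a,b aligned in-frame coding sequences.
#' @return list `counts`, `dnds` (a `trf_dnds`), `snps` (from
#'   [catalog_snps()]).
#' @export
dnds_pair <- function(a, b) {
  aln <- codon_alignment(a, b)
  counts <- ng86_counts(aln)
  list(counts = counts, dnds = dnds_ratio(counts), snps = catalog_snps(aln))
}
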