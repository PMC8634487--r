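## element_model: mosaic element-pattern decomposition of exon 2, intron
## typing against the alpha-epsilon reference set, and gene naming.

NUC_MAT <- local({
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                baseOnly = FALSE)
  m
})

## Align `query` against `subject` and return the per-query-position mapping
## to 0-based subject columns (NA for query insertions), plus the alignment
## score and percent identity.  type "global-local": the whole query is
## aligned within a local window of the subject.
align_map <- function(query, subject, type = "global-local",
                      gap_opening = 10, gap_extension = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = type,
    substitutionMatrix = NUC_MAT,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pat <- dna_chars(as.character(Biostrings::alignedPattern(pa)))
  sub <- dna_chars(as.character(Biostrings::alignedSubject(pa)))
  s0 <- Biostrings::start(Biostrings::subject(pa)) - 1L  # 0-based subject offset
  map <- integer(0)
  qi <- 0L
  si <- s0
  map <- rep(NA_integer_, sum(pat != "-"))
  for (k in seq_along(pat)) {
    p <- pat[k]; s <- sub[k]
    if (p != "-" && s != "-") {
      qi <- qi + 1L
      map[qi] <- si
      si <- si + 1L
    } else if (p != "-") {
      qi <- qi + 1L
    } else if (s != "-") {
      si <- si + 1L
    }
  }
  list(map = map, score = Biostrings::score(pa), pid = Biostrings::pid(pa))
}

#' Decompose an exon-2 sequence into its element pattern
#'
#' Globally aligns exon 2 against the scheme consensus (affine gaps) and calls
#' each element present when at least `presence_threshold` of its consensus
#' columns are occupied by query residues.  Runs of missing or partially
#' occupied elements are reported as deletion junctions with the retained
#' fragment lengths of the boundary elements.
#'
#' @param exon2 exon-2 DNA (character or DNAString); typically the genomic
#'   exon-2 region of a validated gene model.
#' @param ref a `trf_element_ref` from [trf_reference()].
#' @param presence_threshold fraction of consensus columns that must be
#'   occupied to call an element present (default 0.5).
#' @param gene_id optional label carried through to the result.
#' @return `trf_element_pattern`: list with `gene_id`, `scheme`, `presence`
#'   (logical vector over elements), `occupancy` (fractions), `subtype` (key
#'   element subtype letter or NA), `subtype_identity`, `ambiguous_subtype`,
#'   `junctions` (data.frame), `pid` (alignment percent identity).
#' @export
assign_element_pattern <- function(exon2, ref, presence_threshold = 0.5,
                                   gene_id = NA_character_) {
  exon2 <- as.character(exon2)
  assert_that(nchar(exon2) > 0, "empty exon 2")
  am <- align_map(exon2, ref$consensus)
  if (am$pid < 40 || am$score <= 0) {
    stop("unalignable exon 2: alignment identity below floor", call. = FALSE)
  }
  els <- ref$elements
  ne <- nrow(els)
  occ_counts <- integer(ne)
  cols <- am$map[!is.na(am$map)]
  for (i in seq_len(ne)) {
    occ_counts[i] <- sum(cols >= els$start[i] & cols < els$end[i])
  }
  span <- els$end - els$start
  occupancy <- occ_counts / span
  presence <- occupancy >= presence_threshold
  ## deletion junctions: maximal runs of not-fully-occupied elements that
  ## contain at least one absent element
  partial <- occupancy < 0.95
  junctions <- data.frame(left_element = integer(0), left_kept_nt = integer(0),
                          right_element = integer(0), right_kept_nt = integer(0),
                          elements_absent = character(0),
                          stringsAsFactors = FALSE)
  r <- rle(partial)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i <- pos[k]; j <- pos[k + 1L] - 1L
    if (!any(!presence[i:j])) next
    junctions <- rbind(junctions, data.frame(
      left_element = i, left_kept_nt = occ_counts[i],
      right_element = j, right_kept_nt = occ_counts[j],
      elements_absent = paste(which(!presence[i:j] | FALSE) [FALSE], collapse = ","),
      stringsAsFactors = FALSE))
    junctions$elements_absent[nrow(junctions)] <-
      paste((i:j)[!presence[i:j]], collapse = ",")
  }
  ## key element subtype
  subtype <- NA_character_
  subtype_identity <- NA_real_
  ambiguous <- FALSE
  ke <- ref$key_element
  if (presence[ke]) {
    seg_idx <- which(!is.na(am$map) & am$map >= els$start[ke] &
                       am$map < els$end[ke])
    seg <- chars_dna(dna_chars(exon2)[seg_idx])
    ids <- vapply(ref$key_subtypes, function(s) {
      Biostrings::pid(Biostrings::pairwiseAlignment(
        seg, s, type = "global", substitutionMatrix = NUC_MAT,
        gapOpening = 10, gapExtension = 0.5))
    }, numeric(1))
    ord <- order(ids, decreasing = TRUE)
    subtype <- names(ids)[ord[1]]
    subtype_identity <- ids[ord[1]]
    ambiguous <- length(ids) > 1 && (ids[ord[1]] - ids[ord[2]]) < 2
  }
  structure(list(
    gene_id = gene_id, scheme = ref$scheme,
    presence = presence, occupancy = occupancy,
    subtype = subtype, subtype_identity = subtype_identity,
    ambiguous_subtype = ambiguous,
    junctions = junctions, pid = am$pid
  ), class = "trf_element_pattern")
}

#' Map a stop codon to its stop class (a-d) via the element reference
#'
#' Aligns the exon-2 coding sequence (ending at and including the stop codon)
#' to the scheme consensus and assigns the class of the nearest reference
#' stop column.
#'
#' @param exon2_cds coding part of exon 2 including the terminal stop codon.
#' @param ref a `trf_element_ref`.
#' @return list `class` (one of a-d), `column` (mapped consensus column of the
#'   stop codon start), `offset_error` (nt distance to the assigned column).
#' @export
stop_class_from_alignment <- function(exon2_cds, ref) {
  exon2_cds <- as.character(exon2_cds)
  n <- nchar(exon2_cds)
  assert_that(n >= 3, "exon-2 CDS shorter than one codon")
  am <- align_map(exon2_cds, ref$consensus)
  stop_cols <- am$map[(n - 2L):n]
  col <- stop_cols[!is.na(stop_cols)][1]
  if (is.na(col) || length(col) == 0L) {
    ## fall back to the last mapped column
    mapped <- am$map[!is.na(am$map)]
    col <- mapped[length(mapped)] - 2L
  }
  d <- abs(ref$stop_columns - col)
  cls <- names(ref$stop_columns)[which.min(d)]
  list(class = cls, column = col, offset_error = unname(min(d)))
}

#' Classify an intron into type alpha-epsilon
#'
#' Global-alignment identity against each typed reference intron; the label is
#' the type of the highest-identity reference.  Sliding windows whose best
#' matching type differs from the global label are reported as chimera
#' segments (the windows are merged into maximal runs).
#'
#' @param intron intron DNA.
#' @param refs named character vector of typed reference introns (names are
#'   the type labels), e.g. [trf_reference_introns()].
#' @param window,step chimera scan window and step in nt (defaults 75/25).
#' @param gene_id optional label.
#' @return `trf_intron_type`: list with `label`, `identity`, `identities`
#'   (per reference), `chimera` (data.frame of segments: start/end 0-based
#'   half-open within the intron, donor type), `gene_id`.
#' @export
classify_intron_type <- function(intron, refs = trf_reference_introns(),
                                 window = 75L, step = 25L,
                                 gene_id = NA_character_) {
  intron <- as.character(intron)
  assert_that(nchar(intron) > 0, "empty intron")
  assert_that(length(refs) >= 1, "need at least one reference intron")
  ids <- vapply(refs, function(r) {
    Biostrings::pid(Biostrings::pairwiseAlignment(
      intron, r, type = "global", substitutionMatrix = NUC_MAT,
      gapOpening = 10, gapExtension = 0.5))
  }, numeric(1))
  label <- names(ids)[which.max(ids)]
  ## chimera scan
  n <- nchar(intron)
  chim <- data.frame(start = integer(0), end = integer(0),
                     donor_type = character(0), stringsAsFactors = FALSE)
  if (n >= window) {
    starts <- seq(0L, n - window, by = step)
    wtypes <- vapply(starts, function(s) {
      w <- substr(intron, s + 1L, s + window)
      sc <- vapply(refs, function(r) {
        Biostrings::score(Biostrings::pairwiseAlignment(
          w, r, type = "local", substitutionMatrix = NUC_MAT,
          gapOpening = 10, gapExtension = 0.5))
      }, numeric(1))
      names(sc)[which.max(sc)]
    }, character(1))
    alien <- wtypes != label
    if (any(alien)) {
      r <- rle(alien)
      pos <- cumsum(c(1L, r$lengths))
      for (k in seq_along(r$values)) {
        if (!r$values[k]) next
        i <- pos[k]; j <- pos[k + 1L] - 1L
        chim <- rbind(chim, data.frame(
          start = starts[i], end = min(starts[j] + window, n),
          donor_type = wtypes[i], stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(gene_id = gene_id, label = label,
                 identity = unname(max(ids)), identities = ids,
                 chimera = chim),
            class = "trf_intron_type")
}

#' Derive a family name from an element pattern
#'
#' The letter class comes from the key-element subtype (A-E), or `"0"` when
#' the key element is absent; the numeral comes from the closest catalogued
#' pattern of that letter class (Hamming distance on the presence vector).
#' Ambiguous subtype calls are flagged with a trailing `"?"` rather than
#' silently guessed.
#'
#' @param pattern a `trf_element_pattern`.
#' @param catalogue pattern catalogue, see [trf_pattern_catalogue()].
#' @return character name, e.g. `"E2"` or `"01"`, possibly suffixed `"?"`.
#' @export
derive_gene_name <- function(pattern, catalogue = trf_pattern_catalogue()) {
  pres <- paste(ifelse(pattern$presence, "1", "0"), collapse = "")
  letter <- if (is.na(pattern$subtype)) "0" else pattern$subtype
  cand <- catalogue[catalogue$letter == letter, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- catalogue
  ham <- vapply(cand$pattern, function(p) {
    sum(dna_chars(p) != dna_chars(pres))
  }, numeric(1))
  numeral <- cand$numeral[which.min(ham)]
  name <- paste0(letter, numeral)
  if (isTRUE(pattern$ambiguous_subtype)) name <- paste0(name, "?")
  name
}

#' Name a set of genes in locus order, suffixing repeated patterns
#'
#' Applies [derive_gene_name()] to each pattern and appends suffix letters
#' (`a`, `b`, ...) to the second and later occurrences of the same base name,
#' matching the family's locus naming convention (A2, A2a, ...).
#'
#' @param patterns list of `trf_element_pattern` in locus order.
#' @param catalogue pattern catalogue.
#' @return character vector of names.
#' @export
derive_gene_names <- function(patterns, catalogue = trf_pattern_catalogue()) {
  base <- vapply(patterns, derive_gene_name, character(1), catalogue = catalogue)
  out <- base
  for (nm in unique(base)) {
    idx <- which(base == nm)
    if (length(idx) > 1) {
      out[idx[-1]] <- paste0(nm, letters[seq_len(length(idx) - 1L)])
    }
  }
  out
}
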