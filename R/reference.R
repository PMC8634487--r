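## reference: element-scheme references, typed reference introns, the probe
## set, and the element-pattern catalogue.
##
## The real curation of this gene family rests on two manual alignment
## schemes of exon 2 (a repeat-based 27-element scheme and a cDNA-based
## 26-element scheme), a set of typed reference introns (alpha..epsilon), and
## conserved primer probes.  The reference objects shipped with this package
## are SYNTHETIC stand-ins with the same structure, generated deterministically
## here; users with access to curated alignments can supply their own via the
## fixture-file readers.

ELEMENT_LENGTHS_REPEAT <- c(48L, 45L, 51L, 48L, 45L, 54L, 48L, 36L, 51L, 60L,
                            48L, 45L, 51L, 48L, 57L, 45L, 36L, 51L, 48L, 54L,
                            45L, 48L, 51L, 45L, 48L, 54L, 210L)

## six imperfect repeat types over the elements (synthetic assignment)
ELEMENT_REPEAT_TYPES <- local({
  ty <- rep("-", 27L)
  ty[c(2, 3, 4, 5)] <- "type1"
  ty[c(6, 7, 9)] <- "type2"
  ty[c(11, 12, 13)] <- "type3"
  ty[c(15, 16, 18, 19)] <- "type4"
  ty[c(20, 21, 22, 23, 24)] <- "type5"
  ty[c(25, 26)] <- "type6"
  ty
})

## stop-codon columns within the terminal element (0-based nt offsets into the
## element; codon-aligned).  Class d is the 5'-most (the premature Trp->stop
## class); a, b, c follow in 3' order as in the terminal-element grammar.
STOP_OFFSETS_IN_TERMINAL <- c(d = 21L, a = 138L, b = 168L, c = 198L)

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

random_orf <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Build the synthetic element reference for a scheme
#'
#' Constructs the exon-2 element reference deterministically (fixed internal
#' seed): the element consensus is an open reading frame partitioned into 27
#' (repeat-based) or 26 (cDNA-based) ordered elements; the terminal element
#' carries the four stop-codon columns a-d; the key element used for gene
#' naming (element 10 repeat-based / element 15 cDNA-based) has five subtype
#' variants A-E.  Both schemes share one consensus sequence and differ in the
#' block partition, mirroring how the two manual alignments partition the same
#' exon.
#'
#' @param scheme `"repeat_based"` (27 elements) or `"cDNA_based"` (26).
#' @return an object of class `trf_element_ref`: list with `scheme`,
#'   `consensus`, `elements` (data.frame id/start/end/repeat_type; 0-based
#'   half-open columns), `key_element`, `key_subtypes` (named A-E sequence
#'   vector), `stop_columns` (named a-d absolute 0-based consensus offsets),
#'   `terminal_element`.
#' @export
trf_reference <- function(scheme = c("repeat_based", "cDNA_based")) {
  scheme <- match.arg(scheme)
  base <- build_repeat_reference()
  if (scheme == "repeat_based") return(base)
  cdna_reference_from_repeat(base)
}

build_repeat_reference <- function() {
  with_seed(20210744L, {
    lens <- ELEMENT_LENGTHS_REPEAT
    els <- lapply(lens / 3L, random_orf)
    ## terminal element: sense codons with designated stop columns; classes
    ## d/a/b hold stop-adjacent sense codons (TGG, CAA, CAA) so that a single
    ## substitution realizes the stop; class c holds the consensus stop TAA.
    term <- dna_chars(els[[27L]])
    put <- function(chars, off, codon) {
      chars[(off + 1L):(off + 3L)] <- dna_chars(codon)
      chars
    }
    term <- put(term, STOP_OFFSETS_IN_TERMINAL[["d"]], "TGG")
    term <- put(term, STOP_OFFSETS_IN_TERMINAL[["a"]], "CAA")
    term <- put(term, STOP_OFFSETS_IN_TERMINAL[["b"]], "CAA")
    term <- put(term, STOP_OFFSETS_IN_TERMINAL[["c"]], "TAA")
    els[[27L]] <- chars_dna(term)
    consensus <- paste(unlist(els), collapse = "")
    ends <- cumsum(lens)
    starts <- c(0L, head(ends, -1L))
    key_len <- lens[10L]
    base_key <- els[[10L]]
    subtypes <- c(A = base_key)
    for (s in c("B", "C", "D", "E")) {
      ch <- dna_chars(base_key)
      idx <- sample(seq_len(key_len / 3L))          # codons to mutate
      nmut <- round(key_len / 3L * 0.3)
      for (cdn in idx[seq_len(nmut)]) {
        ch[(3 * cdn - 2):(3 * cdn)] <- dna_chars(sample(SENSE_CODONS, 1))
      }
      subtypes[[s]] <- chars_dna(ch)
    }
    structure(list(
      scheme = "repeat_based",
      consensus = consensus,
      elements = data.frame(id = seq_len(27L), start = starts, end = ends,
                            repeat_type = ELEMENT_REPEAT_TYPES,
                            stringsAsFactors = FALSE),
      key_element = 10L,
      key_subtypes = subtypes,
      stop_columns = starts[27L] + STOP_OFFSETS_IN_TERMINAL,
      terminal_element = 27L
    ), class = "trf_element_ref")
  })
}

## The cDNA-based scheme re-partitions the same consensus into 26 blocks such
## that block 15 spans exactly the repeat-based key element 10.
cdna_reference_from_repeat <- function(base) {
  b <- base$elements
  blocks <- list()
  half <- function(i) {
    len <- b$end[i] - b$start[i]
    h <- (len %/% 6L) * 3L
    list(c(b$start[i], b$start[i] + h), c(b$start[i] + h, b$end[i]))
  }
  split_at <- c(2L, 4L, 6L, 8L, 9L)
  for (i in 1:9) {
    if (i %in% split_at) {
      blocks <- c(blocks, half(i))
    } else {
      blocks <- c(blocks, list(c(b$start[i], b$end[i])))
    }
  }
  blocks <- c(blocks, list(c(b$start[10], b$end[10])))   # block 15 = key
  merges <- list(c(11L, 12L), c(13L, 14L), c(15L, 16L), c(17L, 18L),
                 c(19L, 20L), c(21L, 22L))
  for (m in merges) blocks <- c(blocks, list(c(b$start[m[1]], b$end[m[2]])))
  for (i in 23:27) blocks <- c(blocks, list(c(b$start[i], b$end[i])))
  starts <- vapply(blocks, `[`, numeric(1), 1)
  ends <- vapply(blocks, `[`, numeric(1), 2)
  out <- base
  out$scheme <- "cDNA_based"
  out$elements <- data.frame(id = seq_along(blocks), start = as.integer(starts),
                             end = as.integer(ends),
                             repeat_type = "-", stringsAsFactors = FALSE)
  out$key_element <- 15L
  out$terminal_element <- length(blocks)
  out
}

#' Synthetic typed reference introns (alpha-epsilon)
#'
#' Five reference intron sequences, one per type, generated deterministically.
#' All begin `GT` and end `AG`.
#'
#' @return named character vector `alpha, beta, gamma, delta, epsilon`.
#' @export
trf_reference_introns <- function() {
  with_seed(744783L, {
    lens <- c(alpha = 400L, beta = 410L, gamma = 405L, delta = 398L,
              epsilon = 402L)
    out <- vapply(lens, function(n) {
      body <- random_dna(n - 4L, gc = 0.4)
      paste0("GT", body, "AG")
    }, character(1))
    names(out) <- names(lens)
    out
  })
}

#' Synthetic probe set used to anchor gene candidates
#'
#' Named after the conserved primers of the family (R1, F2, F5, F6, R9), with
#' sequences drawn from the synthetic ancestral gene template so that every
#' generated gene carries them: R1 in the 5'UTR, F2 in exon 1, F5/F6 in
#' conserved exon-2 elements, R9 near the exon-2 terminus.
#'
#' @return named character vector of 24-nt probes.
#' @export
trf_probes <- function() {
  tpl <- ancestral_template()
  ref <- trf_reference("repeat_based")
  el <- function(i) ref$elements$start[i]
  c(
    R1 = substr(tpl$utr5, 61, 84),
    F2 = substr(tpl$exon1, 16, 39),
    F5 = substr(tpl$exon2, el(6) + 1, el(6) + 24),
    F6 = substr(tpl$exon2, el(20) + 1, el(20) + 24),
    R9 = substr(tpl$exon2, el(26) + 1, el(26) + 24)
  )
}

#' Catalogue of named element patterns (repeat-based scheme)
#'
#' Synthetic stand-in for the curated pattern catalogue: presence vectors over
#' the 27 repeat-based elements for the canonical family names, plus the key
#' element subtype that defines the letter class.  `0` names have the key
#' element deleted.
#'
#' @return data.frame with columns `name`, `letter`, `numeral`, `subtype`,
#'   `pattern` ("1"/"0" string of length 27).
#' @export
trf_pattern_catalogue <- function() {
  absent <- list(
    A2 = c(8L, 17L),
    B8 = c(3L, 8L, 13L, 17L, 21L),
    C4 = c(3L, 4L, 8L, 17L),
    D1 = c(5L, 6L, 8L, 12L, 17L, 21L, 23L),
    E2 = c(4L, 5L, 6L, 7L, 8L, 9L, 12L, 13L, 17L, 22L, 23L, 24L),
    `01` = c(4L, 5L, 6L, 7L, 8L, 9L, 10L, 12L, 13L, 17L)
  )
  subtype <- c(A2 = "A", B8 = "B", C4 = "C", D1 = "D", E2 = "E", `01` = NA)
  pat <- vapply(absent, function(a) {
    v <- rep("1", 27L)
    v[a] <- "0"
    paste(v, collapse = "")
  }, character(1))
  data.frame(
    name = names(absent),
    letter = c("A", "B", "C", "D", "E", "0"),
    numeral = c("2", "8", "4", "1", "2", "1"),
    subtype = unname(subtype[names(absent)]),
    pattern = unname(pat),
    stringsAsFactors = FALSE
  )
}

## ---------------------------------------------------------------------------
## Fixture-file IO (FASTA consensus + TSV element map), so users can swap in
## their own curated references.

#' Write an element reference as fixture files
#'
#' Writes `consensus_<scheme>.fasta`, `element_map_<scheme>.tsv`,
#' `key_subtypes_<scheme>.fasta`, and `stop_columns_<scheme>.tsv` under `dir`.
#'
#' @param ref a `trf_element_ref`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_element_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- ref$scheme
  writeLines(c(sprintf(">consensus_%s", tag), ref$consensus),
             file.path(dir, sprintf("consensus_%s.fasta", tag)))
  write.table(ref$elements, file.path(dir, sprintf("element_map_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.vector(rbind(paste0(">", names(ref$key_subtypes)),
                             unname(ref$key_subtypes))),
             file.path(dir, sprintf("key_subtypes_%s.fasta", tag)))
  sc <- data.frame(class = names(ref$stop_columns),
                   column = as.integer(ref$stop_columns))
  write.table(sc, file.path(dir, sprintf("stop_columns_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(field = c("scheme", "key_element", "terminal_element"),
                     value = c(ref$scheme, ref$key_element,
                               ref$terminal_element))
  write.table(meta, file.path(dir, sprintf("meta_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an element reference from fixture files written by
#' [write_element_reference()]
#'
#' @param dir directory holding the fixture files.
#' @param scheme scheme tag to read.
#' @return a `trf_element_ref`.
#' @export
read_element_reference <- function(dir, scheme = c("repeat_based", "cDNA_based")) {
  scheme <- match.arg(scheme)
  fa <- read_sequences(file.path(dir, sprintf("consensus_%s.fasta", scheme)))
  elements <- read.table(file.path(dir, sprintf("element_map_%s.tsv", scheme)),
                         sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  subs <- read_sequences(file.path(dir, sprintf("key_subtypes_%s.fasta", scheme)))
  sc <- read.table(file.path(dir, sprintf("stop_columns_%s.tsv", scheme)),
                   sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  meta <- read.table(file.path(dir, sprintf("meta_%s.tsv", scheme)),
                     sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  mv <- setNames(meta$value, meta$field)
  structure(list(
    scheme = unname(mv[["scheme"]]),
    consensus = as.character(fa[[1]]),
    elements = elements,
    key_element = as.integer(mv[["key_element"]]),
    key_subtypes = setNames(as.character(subs), names(subs)),
    stop_columns = setNames(as.integer(sc$column), sc$class),
    terminal_element = as.integer(mv[["terminal_element"]])
  ), class = "trf_element_ref")
}
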