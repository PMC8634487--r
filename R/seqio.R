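## seqio: reading genomic sequences and writing/reading GFF3 annotations.
##
## Internal coordinates everywhere in this package are 0-based half-open on
## the forward strand; minus-strand features are stored in forward-strand
## coordinates with a strand flag.  GFF3 output is 1-based inclusive.

VALID_DNA_CHARS <- c("A", "C", "G", "T", "N",
                     "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read genomic sequences from FASTA or GenBank flat files
#'
#' Sequences are uppercased on ingest and RNA `U` is mapped to `T`.  Any
#' character other than the IUPAC nucleotide codes triggers a validation
#' error naming the offending record.  GenBank flat files are parsed from the
#' local file (LOCUS/ORIGIN blocks); no network access is attempted.
#'
#' @param path path to the sequence file.
#' @param format `"fasta"` or `"genbank"`.
#' @return a [Biostrings::DNAStringSet] with one entry per record, in file
#'   order.
#' @export
read_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("cannot read '%s': no such file", path))
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    if (!any(nzchar(trimws(lines)))) stop("empty input: no records in ", path, call. = FALSE)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("empty input: no records in ", path, call. = FALSE)
    seqs <- toupper(as.character(raw))
    names(seqs) <- sub("\\s.*$", "", names(raw))
  } else {
    seqs <- read_genbank_flat(path)
  }
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(dna_chars(seqs[[i]])), VALID_DNA_CHARS)
    if (length(bad) > 0) {
      stop(sprintf("record '%s' contains non-DNA characters: %s",
                   names(seqs)[i], paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  assert_that(all(nzchar(names(seqs))), "sequence ids must be non-empty")
  Biostrings::DNAStringSet(seqs)
}

## Minimal GenBank flat-file parser: record id from the LOCUS (or ACCESSION)
## line, residues from the ORIGIN block.  Handles multi-record files separated
## by '//'.
read_genbank_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) stop("empty input: no records in ", path, call. = FALSE)
  rec_end <- grep("^//", lines)
  rec_start <- c(1L, head(rec_end, -1L) + 1L)
  if (length(rec_end) == 0L) {
    rec_start <- 1L
    rec_end <- length(lines)
  }
  ids <- character(0)
  seqs <- character(0)
  for (k in seq_along(rec_start)) {
    block <- lines[rec_start[k]:rec_end[k]]
    locus <- grep("^LOCUS", block, value = TRUE)
    acc <- grep("^ACCESSION", block, value = TRUE)
    id <- if (length(acc) > 0) {
      strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    } else if (length(locus) > 0) {
      strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
    } else next
    ori <- grep("^ORIGIN", block)
    if (length(ori) == 0L) {
      stop(sprintf("GenBank record '%s' has no ORIGIN block", id), call. = FALSE)
    }
    body <- block[(ori[1] + 1L):length(block)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[0-9 \t]", "", paste(body, collapse = "")))
    ids <- c(ids, id)
    seqs <- c(seqs, seq)
  }
  if (length(seqs) == 0L) stop("empty input: no GenBank records in ", path, call. = FALSE)
  setNames(seqs, ids)
}

## ---------------------------------------------------------------------------
## GFF3 annotation output / input

#' Write gene models and STR islands as GFF3
#'
#' Emits nested gene features (gene > exon1/intron/exon2 + five_prime_UTR /
#' three_prime_UTR + polyA_signal_sequence children linked by `Parent`) and
#' STR islands as `repeat_region` features.  Internal 0-based half-open
#' coordinates are converted to 1-based inclusive GFF3 coordinates.
#'
#' @param models data.frame of gene models as built by [annotate_gene_model()]
#'   (may be empty or NULL).
#' @param islands data.frame of STR islands from [scan_str_islands()]
#'   (may be empty or NULL).
#' @param path output file path.
#' @param seq_lengths optional named vector of contig lengths used to validate
#'   feature bounds.
#' @return invisibly, the path written.
#' @export
write_annotations <- function(models, islands, path, seq_lengths = NULL) {
  gr <- annotations_to_granges(models, islands, seq_lengths)
  if (length(gr) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

annotations_to_granges <- function(models, islands, seq_lengths = NULL) {
  feats <- list()
  add <- function(contig, start0, end0, type, id, parent = NA_character_,
                  strand = "*", extra = list()) {
    if (!is.null(seq_lengths) && contig %in% names(seq_lengths)) {
      assert_that(start0 >= 0 && end0 <= seq_lengths[[contig]],
                  sprintf("feature '%s' [%d,%d) beyond bounds of contig '%s'",
                          id, start0, end0, contig))
    }
    feats[[length(feats) + 1L]] <<- data.frame(
      contig = contig, start = start0 + 1L, end = end0, type = type,
      ID = id, Parent = parent, strand = strand,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(models) && nrow(as.data.frame(models)) > 0) {
    models <- as.data.frame(models)
    for (i in seq_len(nrow(models))) {
      m <- models[i, ]
      gid <- m$gene_id
      add(m$contig, m$gene_start, m$gene_end, "gene", gid, strand = m$strand)
      add(m$contig, m$utr5_start, m$utr5_end, "five_prime_UTR",
          paste0(gid, ":utr5"), gid, m$strand)
      add(m$contig, m$exon1_start, m$exon1_end, "exon",
          paste0(gid, ":exon1"), gid, m$strand)
      add(m$contig, m$intron_start, m$intron_end, "intron",
          paste0(gid, ":intron"), gid, m$strand)
      add(m$contig, m$exon2_start, m$exon2_end, "exon",
          paste0(gid, ":exon2"), gid, m$strand)
      add(m$contig, m$utr3_start, m$utr3_end, "three_prime_UTR",
          paste0(gid, ":utr3"), gid, m$strand)
      if (!is.na(m$polya_can_start)) {
        add(m$contig, m$polya_can_start, m$polya_can_start + 6L,
            "polyA_signal_sequence", paste0(gid, ":polyA"), gid, m$strand)
      }
      if (!is.na(m$polya_var_start)) {
        add(m$contig, m$polya_var_start, m$polya_var_start + 6L,
            "polyA_signal_sequence", paste0(gid, ":polyA_variant"), gid, m$strand)
      }
    }
  }
  if (!is.null(islands) && nrow(as.data.frame(islands)) > 0) {
    islands <- as.data.frame(islands)
    for (i in seq_len(nrow(islands))) {
      s <- islands[i, ]
      add(s$contig, s$start, s$end, "repeat_region",
          sprintf("%s:STR:%s:%d", s$contig, s$motif, s$start),
          extra = list())
    }
  }
  if (length(feats) == 0L) return(GenomicRanges::GRanges())
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr
}

#' Read back a GFF3 annotation file into 0-based half-open feature table
#'
#' Inverse of [write_annotations()] at the coordinate level: each feature row
#' carries `contig, start, end` (0-based half-open), `type`, `ID`, `Parent`,
#' `strand`.
#'
#' @param path GFF3 file.
#' @return data.frame of features.
#' @export
read_annotations <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) GenomicRanges::GRanges())
  if (length(gr) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      ID = character(0), Parent = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  parent <- S4Vectors::mcols(gr)$Parent
  if (is(parent, "List")) {
    parent <- vapply(parent, function(x) if (length(x)) as.character(x[1]) else "",
                     character(1))
  }
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    type = as.character(S4Vectors::mcols(gr)$type),
    ID = as.character(S4Vectors::mcols(gr)$ID),
    Parent = parent %||% "",
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
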