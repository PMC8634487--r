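## gene_annotator: locating gene candidates from conserved probes and building
## full two-exon gene models from the conserved motif grammar:
## TATA box -> Inr (+1 A = transcription start) -> ATG at 140-155 nt ->
## GT donor at exon1 51/54 -> AG acceptor -> ORF through a stop in the
## terminal element -> polyA signals (AATAAA / ATTAAA).

TATA_VARIANTS <- c("TATAAA", "TATATA")
INR_REGEX <- "^T[CA]AGTT"
TATA_TO_A <- 32L     # +1 A sits 27 nt 3' of the TATA box (TATA start + 32)
UTR5_RANGE <- c(140L, 155L)
EXON1_CANDIDATES <- c(54L, 51L, 48L, 57L, 60L)
ACCEPTOR_RANGE <- c(380L, 700L)
POLYA_SEARCH <- 520L
UTR3_TRIM <- 16L     # cleavage convention: signal offset + 16 nt

#' Locate gene candidate anchors from probe matches
#'
#' Matches each probe on both strands (up to `max_mismatch` mismatches) and
#' reports every region where at least two distinct probes co-occur within
#' `cluster_gap` nt as one candidate anchor with an inferred strand.
#'
#' @param seq contig (character / DNAString / length-1 DNAStringSet).
#' @param probes named character vector of probe sequences (15-30 nt),
#'   e.g. [trf_probes()].
#' @param max_mismatch per-probe mismatch tolerance (default 2).
#' @param cluster_gap maximum gap between probe hits of one candidate
#'   (default 3000 nt).
#' @return data.frame `start, end, strand, n_probes` (0-based half-open),
#'   sorted by position.
#' @export
locate_gene_candidates <- function(seq, probes, max_mismatch = 2L,
                                   cluster_gap = 3000L) {
  assert_that(length(probes) > 0, "empty probe set")
  assert_that(all(nchar(probes) >= 15 & nchar(probes) <= 30),
              "probes must be 15-30 nt")
  if (is(seq, "DNAStringSet")) seq <- seq[[1]]
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  n <- length(seq)
  hits <- list()
  for (pn in names(probes)) {
    p <- Biostrings::DNAString(probes[[pn]])
    for (st in c("+", "-")) {
      pat <- if (st == "+") p else Biostrings::reverseComplement(p)
      m <- Biostrings::matchPattern(pat, seq, max.mismatch = max_mismatch)
      if (length(m) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
          probe = pn, strand = st, stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_probes = integer(0),
                      stringsAsFactors = FALSE)
  if (length(hits) == 0L) return(empty)
  h <- do.call(rbind, hits)
  h <- h[order(h$start), , drop = FALSE]
  grp <- cumsum(c(1L, diff(h$start) > cluster_gap))
  out <- do.call(rbind, lapply(split(h, grp), function(g) {
    if (length(unique(g$probe)) < 2L) return(NULL)
    data.frame(start = min(g$start), end = max(g$end),
               strand = names(sort(table(g$strand), decreasing = TRUE))[1],
               n_probes = length(unique(g$probe)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## forward-coordinate conversion of a local (oriented) half-open interval
.fwd <- function(s, e, w0, wn, strand) {
  if (strand == "+") c(w0 + s, w0 + e) else c(w0 + wn - e, w0 + wn - s)
}

#' Annotate a full gene model at a candidate anchor
#'
#' Performs the ordered motif search on the anchor strand and returns a
#' one-row data.frame gene model (all coordinates 0-based half-open on the
#' forward strand).  Fails with reason `"no TATA"` when no TATA box with a
#' valid initiator geometry is found, and `"no ORF"` when no donor/acceptor
#' pair yields an open reading frame through a stop codon.
#'
#' @param seq contig sequence.
#' @param anchor one-row data.frame (or list) with `start`, `end`, `strand`
#'   from [locate_gene_candidates()].
#' @param ref element reference used to place the stop class,
#'   [trf_reference()].
#' @param gene_id id recorded in the model.
#' @param contig contig id recorded in the model.
#' @return one-row data.frame gene model.
#' @export
annotate_gene_model <- function(seq, anchor, ref = trf_reference(),
                                gene_id = "gene1", contig = "seq") {
  if (is(seq, "DNAStringSet")) seq <- seq[[1]]
  seq_chr <- if (is.character(seq)) seq else as.character(seq)
  n <- nchar(seq_chr)
  w0 <- max(0L, anchor$start - 1500L)
  w1 <- min(n, anchor$end + 3500L)
  win <- subseq_chr(seq_chr, w0, w1)
  wn <- nchar(win)
  strand <- anchor$strand
  if (strand == "-") win <- revcomp_chr(win)
  wc <- dna_chars(win)

  ## 1) TATA + Inr -> transcription start (+1 A)
  tata_pos <- sort(unique(unlist(lapply(TATA_VARIANTS, function(v) {
    as.integer(gregexpr(v, win, fixed = TRUE)[[1]])
  }))))
  tata_pos <- tata_pos[tata_pos > 0] - 1L       # 0-based
  tss <- integer(0)
  tatas <- integer(0)
  for (t in tata_pos) {
    a <- t + TATA_TO_A
    if (a - 2L < 0L || a + 4L > wn) next
    inr <- substr(win, a - 1L, a + 4L)          # 6-mer starting a-2 (1-based a-1)
    if (grepl(INR_REGEX, inr)) {
      tss <- c(tss, a)
      tatas <- c(tatas, t)
    }
  }
  if (length(tss) == 0L) {
    stop(sprintf("annotation failure for %s: no TATA", gene_id), call. = FALSE)
  }

  ## 2) enumerate (tss, ATG, donor, acceptor) candidates
  cand <- list()
  for (k in seq_along(tss)) {
    a <- tss[k]
    for (m in (a + UTR5_RANGE[1]):(a + UTR5_RANGE[2])) {
      if (m + 3L > wn) next
      if (substr(win, m + 1L, m + 3L) != "ATG") next
      for (e1 in EXON1_CANDIDATES) {
        d <- m + e1
        if (d + 2L > wn) next
        if (substr(win, d + 1L, d + 2L) != "GT") next
        q_lo <- m + ACCEPTOR_RANGE[1]
        q_hi <- min(m + ACCEPTOR_RANGE[2], wn)
        if (q_lo >= q_hi) next
        acc_region <- substr(win, q_lo - 1L, q_hi)
        ags <- as.integer(gregexpr("AG", acc_region, fixed = TRUE)[[1]])
        ags <- ags[ags > 0]
        for (ag in ags) {
          q <- (q_lo - 2L) + ag + 1L            # 0-based end of acceptor AG
          if (q <= d + 20L) next                # minimum intron length guard
          cds <- paste0(substr(win, m + 1L, m + e1),
                        substr(win, q + 1L, wn))
          nc <- nchar(cds) %/% 3L
          codons <- substring(cds, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
          stop_i <- which(codons %in% c("TAA", "TAG", "TGA"))[1]
          if (is.na(stop_i)) next
          exon2_cds_len <- 3L * stop_i - e1
          if (exon2_cds_len < 300L) next
          cand[[length(cand) + 1L]] <- list(
            tata = tatas[k], a = a, m = m, e1 = e1, q = q,
            stop_local = q + exon2_cds_len,     # 0-based start of last codon + ... see below
            exon2_cds_len = exon2_cds_len)
        }
      }
    }
  }
  if (length(cand) == 0L) {
    stop(sprintf("annotation failure for %s: no ORF", gene_id), call. = FALSE)
  }

  ## candidates must overlap the probe anchor (a neighboring gene's grammar
  ## can fall inside the search window)
  overlaps_anchor <- vapply(cand, function(z) {
    span <- .fwd(z$a, z$q + z$exon2_cds_len, w0, wn, strand)
    span[1] < anchor$end && span[2] > anchor$start
  }, logical(1))
  if (any(overlaps_anchor)) cand <- cand[overlaps_anchor]

  ## 3) selection: furthest stop, then exon-2 prefix match to the element
  ## reference start, then closeness to the ~550 nt acceptor expectation.
  stop_end_local <- vapply(cand, function(z) z$q + z$exon2_cds_len, numeric(1))
  best_stop <- max(stop_end_local)
  keep <- which(stop_end_local == best_stop)
  ref_prefix <- dna_chars(substr(ref$consensus, 1L, 24L))
  pref_score <- vapply(keep, function(i) {
    z <- cand[[i]]
    frag <- dna_chars(substr(win, z$q + 1L, z$q + 24L))
    if (length(frag) < 24L) return(-1L)
    sum(frag == ref_prefix)
  }, numeric(1))
  keep <- keep[pref_score == max(pref_score)]
  dev <- vapply(keep, function(i) abs((cand[[i]]$q - cand[[i]]$m) - 550L), numeric(1))
  keep <- keep[dev == min(dev)]
  z <- cand[[keep[which.max(vapply(keep, function(i) cand[[i]]$q, numeric(1))) ]]]

  ## 4) derived coordinates (local, oriented)
  a <- z$a; m <- z$m; e1 <- z$e1; q <- z$q
  utr5_len <- m - a
  intron_len <- q - (m + e1)
  exon2_len <- z$exon2_cds_len
  stop_start <- q + exon2_len - 3L
  stop_end <- q + exon2_len

  ## 5) polyA signals downstream of the stop
  pa_window <- substr(win, stop_end + 1L, min(stop_end + POLYA_SEARCH, wn))
  find_first <- function(sig) {
    p <- as.integer(regexpr(sig, pa_window, fixed = TRUE))
    if (p < 1) NA_integer_ else p               # offset: first nt after stop = 1
  }
  off_can <- find_first("AATAAA")
  off_var <- find_first("ATTAAA")
  utr3_len <- if (!is.na(off_can)) off_can + UTR3_TRIM else if (!is.na(off_var))
    off_var + UTR3_TRIM else 0L
  utr3_end <- stop_end + utr3_len

  ## 6) stop class via the element reference
  exon2_cds <- substr(win, q + 1L, stop_end)
  sc <- stop_class_from_alignment(exon2_cds, ref)

  build_gene_model_row(
    gene_id = gene_id, contig = contig, strand = strand,
    w0 = w0, wn = wn,
    tata = z$tata, a = a, m = m, e1 = e1, q = q,
    stop_end = stop_end, utr3_len = utr3_len,
    stop_class = sc$class, off_can = off_can, off_var = off_var
  )
}

## Shared gene-model row constructor: converts oriented local offsets into
## forward-strand absolute 0-based half-open intervals.  Used by both the
## annotator and the synthetic generator's truth writer so that the two agree
## column-for-column.
build_gene_model_row <- function(gene_id, contig, strand, w0, wn,
                                 tata, a, m, e1, q, stop_end, utr3_len,
                                 stop_class, off_can, off_var) {
  utr5_len <- m - a
  intron_len <- q - (m + e1)
  exon2_len <- stop_end - q
  utr3_end <- stop_end + utr3_len
  iv <- function(s, e) .fwd(s, e, w0, wn, strand)
  utr5 <- iv(a, m); ex1 <- iv(m, m + e1); intr <- iv(m + e1, q)
  ex2 <- iv(q, stop_end); utr3 <- iv(stop_end, utr3_end)
  gene <- iv(a, utr3_end)
  tx <- if (strand == "+") w0 + a else w0 + wn - a - 1L
  pa_can <- if (is.na(off_can)) c(NA_integer_, NA_integer_) else
    iv(stop_end + off_can - 1L, stop_end + off_can + 5L)
  pa_var <- if (is.na(off_var)) c(NA_integer_, NA_integer_) else
    iv(stop_end + off_var - 1L, stop_end + off_var + 5L)
  data.frame(
    gene_id = gene_id, contig = contig, strand = strand,
    gene_start = gene[1], gene_end = gene[2], tx_start = tx,
    utr5_start = utr5[1], utr5_end = utr5[2],
    exon1_start = ex1[1], exon1_end = ex1[2],
    intron_start = intr[1], intron_end = intr[2],
    exon2_start = ex2[1], exon2_end = ex2[2],
    utr3_start = utr3[1], utr3_end = utr3[2],
    utr5_len = utr5_len, exon1_len = e1, intron_len = intron_len,
    exon2_len = exon2_len, utr3_len = utr3_len,
    full_transcript_len = utr5_len + e1 + exon2_len + utr3_len,
    stop_class = stop_class,
    polya_can_offset = off_can, polya_var_offset = off_var,
    polya_can_start = pa_can[1], polya_var_start = pa_var[1],
    stringsAsFactors = FALSE
  )
}

#' Annotate all gene candidates on a contig
#'
#' Convenience wrapper: [locate_gene_candidates()] followed by
#' [annotate_gene_model()] on every anchor.  Annotation failures are collected
#' (never silently dropped) and attached as the `failures` attribute.
#'
#' @inheritParams locate_gene_candidates
#' @inheritParams annotate_gene_model
#' @param id_prefix prefix for generated gene ids.
#' @return data.frame of gene models (possibly 0 rows) with attribute
#'   `failures`: data.frame `anchor_start, reason`.
#' @export
annotate_genes <- function(seq, probes = trf_probes(), ref = trf_reference(),
                           contig = "seq", max_mismatch = 2L,
                           id_prefix = NULL) {
  cands <- locate_gene_candidates(seq, probes, max_mismatch)
  models <- list()
  failures <- data.frame(anchor_start = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  prefix <- id_prefix %||% paste0(contig, ".g")
  for (i in seq_len(nrow(cands))) {
    gid <- paste0(prefix, i)
    res <- tryCatch(
      annotate_gene_model(seq, cands[i, ], ref, gene_id = gid, contig = contig),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- rbind(failures, data.frame(
        anchor_start = cands$start[i],
        reason = sub(".*: ", "", res), stringsAsFactors = FALSE))
    } else {
      models[[length(models) + 1L]] <- res
    }
  }
  out <- if (length(models)) do.call(rbind, models) else
    build_gene_model_row("x", "x", "+", 0L, 10L, 0L, 0L, 5L, 1L, 6L, 9L, 0L,
                         "a", NA_integer_, NA_integer_)[0, ]
  attr(out, "failures") <- failures
  out
}

#' Validate a gene model against its contig sequence
#'
#' Report-only checks: splice GT/AG ends, translation start and in-frame
#' stop, exon-1 length in {51, 54}, presence of at least one polyA signal.
#'
#' @param model one-row gene model data.frame.
#' @param seq contig sequence.
#' @return data.frame `check`, `pass`.
#' @export
validate_gene_model <- function(model, seq) {
  if (is(seq, "DNAStringSet")) seq <- seq[[1]]
  seq_chr <- if (is.character(seq)) seq else as.character(seq)
  get_iv <- function(s, e) {
    x <- subseq_chr(seq_chr, s, e)
    if (model$strand == "-") revcomp_chr(x) else x
  }
  intron <- get_iv(model$intron_start, model$intron_end)
  exon1 <- get_iv(model$exon1_start, model$exon1_end)
  exon2 <- get_iv(model$exon2_start, model$exon2_end)
  cds <- paste0(exon1, exon2)
  nc <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  internal_stops <- which(codons[-nc] %in% c("TAA", "TAG", "TGA"))
  checks <- data.frame(
    check = c("splice_gt", "splice_ag", "starts_atg", "in_frame",
              "open_reading_frame", "terminal_stop", "exon1_length",
              "polya_present"),
    pass = c(
      substr(intron, 1, 2) == "GT",
      substr(intron, nchar(intron) - 1L, nchar(intron)) == "AG",
      substr(cds, 1, 3) == "ATG",
      nchar(cds) %% 3L == 0L,
      length(internal_stops) == 0L,
      codons[nc] %in% c("TAA", "TAG", "TGA"),
      model$exon1_len %in% c(51L, 54L),
      !is.na(model$polya_can_offset) || !is.na(model$polya_var_offset)
    ),
    stringsAsFactors = FALSE
  )
  checks
}
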