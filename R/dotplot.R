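## dotplot_dup: seed-and-extend dot-plot comparison (forward and inverted)
## and segmental-duplication block inference with STR-anchored edges.
##
## Word seeds (default 9-mers) are joined between query and subject, grouped
## per diagonal, chained, and extended without gaps under an X-drop rule with
## YASS-like scoring (match +5, mismatch -4, X-drop 30).  Significance uses
## the ungapped Karlin-Altschul approximation with lambda solved numerically
## for the score matrix (K fixed at 0.1); this approximates the dot-plot
## tool's statistic rather than reproducing it bit-for-bit.

karlin_lambda <- function(match = 5, mismatch = -4) {
  f <- function(l) (4 * exp(l * match) + 12 * exp(l * mismatch)) / 16 - 1
  uniroot(f, c(1e-6, 5))$root
}

## low-complexity seed filter: k-mers periodic with period <= 3
is_lowcomp_kmer <- function(kmers) {
  per <- function(s, p) {
    n <- nchar(s)
    substr(s, 1L, n - p) == substr(s, p + 1L, n)
  }
  per(kmers, 1L) | per(kmers, 2L) | per(kmers, 3L)
}

kmer_table <- function(seq_chr, word) {
  n <- nchar(seq_chr)
  if (n < word) {
    return(data.table::data.table(kmer = character(0), pos = integer(0)))
  }
  starts <- seq_len(n - word + 1L)
  data.table::data.table(kmer = substring(seq_chr, starts, starts + word - 1L),
                         pos = starts - 1L)
}

## chain + extend seeds on one diagonal set; returns matches in 0-based
## half-open query/subject coordinates of the comparison frame
extend_diagonals <- function(seeds, qc, sc, word, match, mismatch, xdrop) {
  if (nrow(seeds) == 0L) return(NULL)
  seeds <- seeds[order(offset, qpos)]
  seeds[, diag_id := cumsum(c(1L, diff(offset) != 0L |
                                diff(qpos) > (word + xdrop)))]
  nq <- length(qc); ns <- length(sc)
  grp_off <- seeds[, .(off = offset[1], qs = min(qpos), qe = max(qpos) + word),
                   by = diag_id]
  ng <- nrow(grp_off)
  v_qs <- integer(ng); v_qe <- integer(ng); v_sc <- numeric(ng)
  for (r in seq_len(ng)) {
    off <- grp_off$off[r]
    qs <- grp_off$qs[r]; qe <- grp_off$qe[r]      # 0-based half-open
    ## ungapped X-drop extension to the left
    best <- 0; cur <- 0; j <- qs - 1L
    while (j >= 0L && j + off >= 0L) {
      cur <- cur + if (qc[j + 1L] == sc[j + off + 1L]) match else mismatch
      if (cur > best) { best <- cur; qs <- j }
      if (best - cur > xdrop) break
      j <- j - 1L
    }
    ## right extension
    best <- 0; cur <- 0; j <- qe
    while (j <= nq - 1L && j + off <= ns - 1L) {
      cur <- cur + if (qc[j + 1L] == sc[j + off + 1L]) match else mismatch
      if (cur > best) { best <- cur; qe <- j + 1L }
      if (best - cur > xdrop) break
      j <- j + 1L
    }
    idx <- seq.int(qs + 1L, qe)
    nmatch <- sum(qc[idx] == sc[idx + off])
    v_qs[r] <- qs; v_qe[r] <- qe
    v_sc[r] <- nmatch * match + (length(idx) - nmatch) * mismatch
  }
  res <- data.table::data.table(qstart = v_qs, qend = v_qe,
                                sstart = v_qs + grp_off$off,
                                send = v_qe + grp_off$off, score = v_sc)
  ## merge overlapping matches on the same diagonal
  res[, offset := sstart - qstart]
  res <- res[order(offset, qstart)]
  keep <- res[, {
    m <- .SD[order(qstart)]
    merged <- list()
    cs <- m$qstart[1]; ce <- m$qend[1]; sc_ <- m$score[1]
    if (nrow(m) > 1) for (r in 2:nrow(m)) {
      if (m$qstart[r] <= ce) {
        ce <- max(ce, m$qend[r]); sc_ <- max(sc_, m$score[r])
      } else {
        merged[[length(merged) + 1L]] <- c(cs, ce, sc_)
        cs <- m$qstart[r]; ce <- m$qend[r]; sc_ <- m$score[r]
      }
    }
    merged[[length(merged) + 1L]] <- c(cs, ce, sc_)
    mm <- do.call(rbind, merged)
    list(qstart = mm[, 1], qend = mm[, 2], score = mm[, 3])
  }, by = offset]
  keep[, `:=`(sstart = qstart + offset, send = qend + offset)]
  keep
}

#' Seed-and-extend dot-plot matches between two sequences
#'
#' @param q,s query and subject sequences (character / DNAString /
#'   length-1 DNAStringSet).
#' @param evalue_threshold keep matches with e-value at or below this
#'   (must be > 0).
#' @param word seed word size (default 9).
#' @param match,mismatch,xdrop extension scoring (defaults +5 / -4 / 30).
#' @param mask_lowcomplexity drop seeds whose word is periodic with period
#'   <= 3 (keeps STR islands from flooding the seed join; default TRUE).
#' @return data.frame `qstart, qend, sstart, send, orientation, score,
#'   evalue` (0-based half-open; subject coordinates always on the subject
#'   forward strand; `orientation` is `"forward"` or `"inverted"`), sorted by
#'   decreasing score.
#' @export
dotplot_matches <- function(q, s, evalue_threshold = 10, word = 9L,
                            match = 5, mismatch = -4, xdrop = 30,
                            mask_lowcomplexity = TRUE) {
  assert_that(evalue_threshold > 0, "evalue_threshold must be > 0")
  to_chr <- function(x) {
    if (is(x, "DNAStringSet")) x <- x[[1]]
    if (!is.character(x)) x <- as.character(x)
    toupper(x)
  }
  qchr <- to_chr(q); schr <- to_chr(s)
  qc <- dna_chars(qchr)
  lambda <- karlin_lambda(match, mismatch)
  K <- 0.1
  mn <- as.numeric(nchar(qchr)) * nchar(schr)
  res_all <- list()
  for (orient in c("forward", "inverted")) {
    scur <- if (orient == "forward") schr else revcomp_chr(schr)
    sc <- dna_chars(scur)
    qt <- kmer_table(qchr, word)
    st <- kmer_table(scur, word)
    if (mask_lowcomplexity) {
      qt <- qt[!is_lowcomp_kmer(kmer)]
      st <- st[!is_lowcomp_kmer(kmer)]
    }
    seeds <- merge(qt, st, by = "kmer", allow.cartesian = TRUE,
                   suffixes = c("_q", "_s"))
    if (nrow(seeds) == 0L) next
    data.table::setnames(seeds, c("pos_q", "pos_s"), c("qpos", "spos"))
    seeds[, offset := spos - qpos]
    m <- extend_diagonals(seeds[, .(qpos, offset)], qc, sc, word,
                          match, mismatch, xdrop)
    if (is.null(m) || nrow(m) == 0L) next
    m[, evalue := K * mn * exp(-lambda * score)]
    m <- m[evalue <= evalue_threshold]
    if (nrow(m) == 0L) next
    if (orient == "inverted") {
      ns <- nchar(schr)
      new_s <- ns - m$send
      m[, send := ns - sstart]
      m[, sstart := new_s]
    }
    m[, orientation := orient]
    res_all[[orient]] <- m
  }
  if (length(res_all) == 0L) {
    return(data.frame(qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      orientation = character(0), score = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  res <- data.table::rbindlist(res_all, fill = TRUE)
  res <- res[order(-score)]
  as.data.frame(res[, .(qstart, qend, sstart, send, orientation, score, evalue)])
}

#' Infer segmental-duplication blocks from dot-plot matches
#'
#' Off-diagonal forward matches at least `min_unit_length` long are clustered
#' by diagonal offset; each cluster is reported as a duplication block with
#' its unit intervals, total unit length, contained genes, and the nearest
#' STR island within `edge_search` nt of each block edge (motif label and
#' signed distance; negative = island begins before the edge).
#'
#' @param matches data.frame from [dotplot_matches()] of a self- or
#'   cross-comparison.
#' @param islands data.frame of STR islands on the query contig (e.g. from
#'   [scan_str_islands()]); islands shorter than `min_anchor_len` are ignored
#'   as anchors.
#' @param genes data.frame of gene models on the query contig (may be NULL).
#' @param min_unit_length minimum match length (default 1000 nt).
#' @param offset_bin diagonal-offset clustering bin (default 100 nt).
#' @param edge_search edge anchor search radius (default 500 nt).
#' @param min_anchor_len minimum island length to act as an edge anchor
#'   (default 30 nt).
#' @return data.frame, one row per block, sorted by decreasing unit length:
#'   `offset, unit_start, unit_end, unit_len, n_units, units, genes,
#'   edge5_motif, edge5_dist, edge3_motif, edge3_dist`.
#' @export
detect_duplication_blocks <- function(matches, islands = NULL, genes = NULL,
                                      min_unit_length = 1000L,
                                      offset_bin = 100L, edge_search = 500L,
                                      min_anchor_len = 30L) {
  all_m <- as.data.frame(matches)
  all_m <- all_m[all_m$orientation == "forward", , drop = FALSE]
  all_m$offset <- all_m$sstart - all_m$qstart
  ## for self-comparisons both mirror images appear; keep offset > 0
  all_m <- all_m[all_m$offset >= offset_bin, , drop = FALSE]
  m <- all_m[(all_m$qend - all_m$qstart) >= min_unit_length, , drop = FALSE]
  empty <- data.frame(offset = numeric(0), unit_start = integer(0),
                      unit_end = integer(0), unit_len = integer(0),
                      n_units = integer(0), units = character(0),
                      genes = character(0), edge5_motif = character(0),
                      edge5_dist = integer(0), edge3_motif = character(0),
                      edge3_dist = integer(0), stringsAsFactors = FALSE)
  if (nrow(m) == 0L) return(empty)
  ## cluster the seeding matches by diagonal offset: consecutive sorted
  ## offsets within offset_bin belong to one cluster (indels between copies
  ## shift the diagonal by a few nt)
  m <- m[order(m$offset), , drop = FALSE]
  m$bin <- cumsum(c(1L, diff(m$offset) > offset_bin))
  anchors <- NULL
  if (!is.null(islands) && nrow(as.data.frame(islands)) > 0) {
    anchors <- as.data.frame(islands)
    anchors <- anchors[anchors$length_nt >= min_anchor_len, , drop = FALSE]
  }
  nearest_anchor <- function(pos) {
    if (is.null(anchors) || nrow(anchors) == 0L) {
      return(list(motif = NA_character_, dist = NA_integer_))
    }
    d <- ifelse(pos < anchors$start, anchors$start - pos,
                ifelse(pos > anchors$end, anchors$end - pos, 0L))
    i <- which.min(abs(d))
    if (abs(d[i]) > edge_search) {
      return(list(motif = NA_character_, dist = NA_integer_))
    }
    list(motif = anchors$motif[i], dist = as.integer(d[i]))
  }
  blocks <- lapply(split(m, m$bin), function(g) {
    ## attach every consistent forward match (any length) whose offset falls
    ## within offset_bin of the seeded cluster: indels between copies break
    ## one duplication into several slightly shifted segments
    ## attach all consistent-offset matches (indels between copies split one
    ## duplication into slightly shifted fragments, some below the seeding
    ## length)
    lo <- min(g$offset) - offset_bin
    hi <- max(g$offset) + offset_bin
    g <- all_m[all_m$offset >= lo & all_m$offset <= hi, , drop = FALSE]
    ## indel fragments are bridged by a 150-nt merge; the unit length is the
    ## widest merged query-side interval, and the copy count follows from
    ## the width of the contiguous duplicated region containing it
    qiv <- IRanges::reduce(IRanges::IRanges(g$qstart + 1L, g$qend),
                           min.gapwidth = 150L)
    siv <- IRanges::reduce(IRanges::IRanges(g$sstart + 1L, g$send),
                           min.gapwidth = 150L)
    allv <- IRanges::reduce(c(qiv, siv), min.gapwidth = 150L)
    main_q <- qiv[which.max(IRanges::width(qiv))]
    unit_len <- IRanges::width(main_q)
    main <- allv[S4Vectors::subjectHits(
      IRanges::findOverlaps(main_q, allv))[1]]
    span_s <- IRanges::start(main) - 1L
    span_e <- IRanges::end(main)
    n_units <- max(2L, as.integer(round((span_e - span_s) / unit_len)))
    gene_str <- ""
    if (!is.null(genes) && nrow(as.data.frame(genes)) > 0) {
      gdf <- as.data.frame(genes)
      inside <- gdf$gene_start >= span_s - 50L & gdf$gene_end <= span_e + 50L
      gene_str <- paste(gdf$gene_id[inside], collapse = ",")
    }
    e5 <- nearest_anchor(span_s)
    e3 <- nearest_anchor(span_e)
    fmt_iv <- function(iv) paste(sprintf("[%d,%d)", IRanges::start(iv) - 1L,
                                         IRanges::end(iv)), collapse = ";")
    data.frame(offset = g$offset[1], unit_start = span_s, unit_end = span_e,
               unit_len = unit_len, n_units = n_units,
               units = paste(fmt_iv(qiv), fmt_iv(siv), sep = "|"),
               genes = gene_str,
               edge5_motif = e5$motif, edge5_dist = e5$dist,
               edge3_motif = e3$motif, edge3_dist = e3$dist,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- out[order(-out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}
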