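## synthetic_locus: seeded generator of synthetic gene clusters with exact
## truth annotations.  Implements the family's event grammar -- tandem
## duplication, ectopic insertion, inversion, element deletion, SNPs, indels,
## STR flanks and STR islands -- over an ancestral gene template built from
## the element reference, so that every pipeline stage can be exercised
## against known truth without external data.

STOP_SET <- c("TAA", "TAG", "TGA")

## ---------------------------------------------------------------------------
## ancestral template (deterministic, memoized)

.tpl_cache <- new.env(parent = emptyenv())

#' Ancestral gene template
#'
#' Deterministically built canonical parts of the ancestral gene: promoter
#' region (TATA box at a fixed offset, initiator spanning the +1 A), a
#' canonical 148-nt 5'UTR, a 54-nt exon 1, the exon-2 element consensus, and
#' a scrubbed 3'UTR core used for polyA placement.
#'
#' @return list `prom, utr5, exon1, exon2, utr3_core`.
#' @export
ancestral_template <- function() {
  if (!is.null(.tpl_cache$tpl)) return(.tpl_cache$tpl)
  ref <- trf_reference("repeat_based")
  tpl <- with_seed(55100L, {
    prom <- paste0(random_dna(28, 0.4), "TATAAA", random_dna(24, 0.4), "TC")
    prom <- scrub_motifs(prom, TATA_VARIANTS, protect = cbind(28L, 34L))
    utr5 <- paste0("AGTT", random_dna(144, 0.4))
    utr5 <- scrub_motifs(utr5, c(TATA_VARIANTS, "ATG"), protect = cbind(0L, 4L))
    exon1 <- paste0("ATG", "GAA",
                    paste(sample(setdiff(SENSE_CODONS, "ATG"), 16,
                                 replace = TRUE), collapse = ""))
    utr3_core <- scrub_motifs(random_dna(560, 0.4), c("AATAAA", "ATTAAA"))
    list(prom = prom, utr5 = utr5, exon1 = exon1,
         exon2 = ref$consensus, utr3_core = utr3_core)
  })
  .tpl_cache$tpl <- tpl
  tpl
}

## Break every occurrence of `motifs` in `s` outside protected [start,end)
## ranges by swapping one internal base.
scrub_motifs <- function(s, motifs, protect = NULL) {
  ch <- dna_chars(s)
  for (iter in 1:25) {
    hit <- FALSE
    for (m in motifs) {
      pos <- as.integer(gregexpr(m, chars_dna(ch), fixed = TRUE)[[1]])
      pos <- pos[pos > 0] - 1L
      for (p in pos) {
        if (!is.null(protect) &&
            any(p < protect[, 2] & (p + nchar(m)) > protect[, 1])) next
        i <- p + max(2L, nchar(m) %/% 2L)
        ch[i + 1L] <- if (ch[i + 1L] == "C") "G" else "C"
        hit <- TRUE
      }
    }
    if (!hit) break
  }
  chars_dna(ch)
}

make_str_seq <- function(motif, len) {
  unit <- STR_UNITS[[motif]]
  substr(strrep(unit, ceiling(len / nchar(unit))), 1L, len)
}

## ---------------------------------------------------------------------------
## gene construction

## Per-pattern variants of the non-coding template parts.  Flanking regions
## of genes with different element patterns are substantially diverged in the
## family (roughly 16-57% mismatch), while same-pattern copies stay nearly
## identical; an ~8% deterministic per-pattern divergence of promoter, 5'UTR
## and 3' tail emulates that.
.pattern_tpl_cache <- new.env(parent = emptyenv())

pattern_template <- function(pattern_name, tpl = ancestral_template()) {
  key <- pattern_name
  if (!is.null(.pattern_tpl_cache[[key]])) return(.pattern_tpl_cache[[key]])
  seed <- 901000L + sum(utf8ToInt(pattern_name) * seq_len(nchar(pattern_name)))
  out <- with_seed(seed, {
    mut <- function(s, rate, protect = NULL) {
      ch <- dna_chars(s)
      k <- rbinom(1L, length(ch), rate)
      if (k > 0) {
        at <- sample.int(length(ch), k)
        if (!is.null(protect)) {
          at <- at[!(at - 1L >= protect[1] & at - 1L < protect[2])]
        }
        for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
      }
      chars_dna(ch)
    }
    prom <- mut(tpl$prom, 0.08, protect = c(28L, 34L))
    substr(prom, 59, 60) <- "TC"      # initiator upstream dinucleotide
    prom <- scrub_motifs(prom, TATA_VARIANTS, protect = cbind(28L, 34L))
    utr5 <- mut(tpl$utr5, 0.08, protect = c(0L, 4L))
    utr5 <- scrub_motifs(utr5, c(TATA_VARIANTS, "ATG"), protect = cbind(0L, 4L))
    utr3 <- scrub_motifs(mut(tpl$utr3_core, 0.08), c("AATAAA", "ATTAAA"))
    list(prom = prom, utr5 = utr5, exon1 = tpl$exon1, exon2 = tpl$exon2,
         utr3_core = utr3)
  })
  .pattern_tpl_cache[[key]] <- out
  out
}

## sample per-gene parameters given a catalogue pattern name
sample_gene_params <- function(pattern_name, catalogue, strand = NULL) {
  row <- catalogue[catalogue$name == pattern_name, ]
  mask <- dna_chars(row$pattern) == "1"
  intron_of <- c(A = "gamma", B = "beta", C = "beta", D = "alpha",
                 E = "delta", `0` = "delta")
  stop_of <- c(A = "c", B = "c", C = "b", D = "c", E = "a", `0` = "b")
  has_can <- runif(1) < 0.88
  has_var <- if (has_can) runif(1) < 0.86 else TRUE
  o_can <- sample(195:330, 1)
  o_var <- o_can + sample(c(-1, 1), 1) * sample(10:120, 1)
  o_var <- max(12L, min(480L, o_var))
  if (abs(o_var - o_can) < 8L) o_var <- o_can + 10L
  list(
    pattern_name = pattern_name,
    element_mask = mask,
    subtype = row$subtype,
    intron_type = unname(intron_of[row$letter]),
    stop_class = unname(stop_of[row$letter]),
    strand = strand %||% sample(c("+", "-"), 1),
    utr5_len = sample(146:149, 1),
    exon1_len = sample(c(51L, 54L), 1, prob = c(0.35, 0.65)),
    off_can = if (has_can) as.integer(o_can) else NA_integer_,
    off_var = if (has_var) as.integer(o_var) else NA_integer_
  )
}

## assemble the (plus-oriented) gene block and its layout
build_gene_block <- function(params, tpl = ancestral_template(),
                             ref = trf_reference("repeat_based"),
                             introns = trf_reference_introns(),
                             snp_rate = 0) {
  p <- params
  tpl <- pattern_template(p$pattern_name, tpl)
  prom <- tpl$prom
  utr5 <- adjust_utr5(tpl$utr5, p$utr5_len)
  exon1 <- if (p$exon1_len == 54L) tpl$exon1 else
    paste0(substr(tpl$exon1, 1, 3), substr(tpl$exon1, 7, 54))
  intron <- introns[[p$intron_type]]
  els <- ref$elements
  seqs <- lapply(seq_len(nrow(els)), function(i) {
    substr(ref$consensus, els$start[i] + 1L, els$end[i])
  })
  if (!is.na(p$subtype)) seqs[[ref$key_element]] <- ref$key_subtypes[[p$subtype]]
  assert_that(p$element_mask[1] && p$element_mask[ref$terminal_element],
              "element mask must keep the first and terminal elements")
  exon2g <- paste(unlist(seqs[p$element_mask]), collapse = "")
  ## realize the stop class
  term_start_realized <- sum(nchar(unlist(seqs[p$element_mask]))) -
    nchar(seqs[[ref$terminal_element]])
  stop_off <- term_start_realized + STOP_OFFSETS_IN_TERMINAL[[p$stop_class]]
  e2 <- dna_chars(exon2g)
  stop_codon <- if (p$stop_class == "d") "TGA" else "TAA"
  e2[(stop_off + 1L):(stop_off + 3L)] <- dna_chars(stop_codon)
  exon2g <- chars_dna(e2)
  exon2_cds_len <- stop_off + 3L
  ## post-stop tail long enough for the polyA search window
  ## tail always spans the full polyA search window so the scrubbed region
  ## covers everything the annotator will look at
  rest <- nchar(exon2g) - exon2_cds_len
  extra <- max(20L, POLYA_SEARCH + 20L - rest)
  tail_seq <- substr(tpl$utr3_core, 1L, extra)

  block <- paste0(prom, utr5, exon1, intron, exon2g, tail_seq)
  layout <- list(
    tata = 28L, a = 60L, m = 60L + p$utr5_len, e1 = p$exon1_len,
    q = 60L + p$utr5_len + p$exon1_len + nchar(intron),
    stop_end = 60L + p$utr5_len + p$exon1_len + nchar(intron) + exon2_cds_len,
    off_can = p$off_can, off_var = p$off_var,
    stop_class = p$stop_class,
    utr3_len = (if (!is.na(p$off_can)) p$off_can else p$off_var) + UTR3_TRIM
  )
  block <- fix_grammar(block, layout)
  if (snp_rate > 0) {
    block <- mutate_gene_seq(block, layout, snp_rate)
  }
  list(kind = "gene", oriented = block, strand = p$strand,
       seq = if (p$strand == "+") block else revcomp_chr(block),
       layout = layout, params = p)
}

adjust_utr5 <- function(utr5, target) {
  n <- nchar(utr5)
  if (target == n) return(utr5)
  if (target < n) {
    out <- paste0(substr(utr5, 1, 100), substr(utr5, 100 + (n - target) + 1L, n))
  } else {
    out <- paste0(substr(utr5, 1, 100), random_dna(target - n, 0.4),
                  substr(utr5, 101, n))
  }
  scrub_motifs(out, c(TATA_VARIANTS, "ATG"), protect = cbind(0L, 4L))
}

## Enforce the motif grammar invariants on a plus-oriented gene block:
## real motifs present, decoys broken, coding frame stop-free before the
## designated stop, polyA signals unique in the search window.
fix_grammar <- function(block, L) {
  ch <- dna_chars(block)
  set <- function(pos0, s) {
    ch[(pos0 + 1L):(pos0 + nchar(s))] <<- dna_chars(s)
  }
  ## canonical motifs
  stopifnot(substr(block, L$tata + 1L, L$tata + 6L) %in% TATA_VARIANTS)
  donor <- L$m + L$e1
  set(donor, "GT")
  set(L$q - 2L, "AG")
  ## break decoy GT at the alternate exon-1 offset
  alt <- if (L$e1 == 54L) L$m + 51L else L$m + 54L
  if (chars_dna(ch[(alt + 1L):(alt + 2L)]) == "GT") {
    ch[alt + 2L] <- "C"
    if (alt < donor) {  # inside exon 1: keep the codon sense
      cs <- L$m + 3L * ((alt - L$m) %/% 3L)
      if (chars_dna(ch[(cs + 1L):(cs + 3L)]) %in% STOP_SET) ch[cs + 3L] <- "C"
    }
  }
  ## no decoy in-frame AG in the last 90 nt of the intron (except terminal)
  lo <- max(donor + 2L, L$q - 92L)
  for (i in lo:(L$q - 4L)) {
    if (ch[i + 1L] == "A" && ch[i + 2L] == "G") ch[i + 2L] <- "C"
  }
  ## no decoy ATG between the true ATG and the end of the UTR5 search range
  for (i in (L$m + 1L):(L$a + UTR5_RANGE[2] - 2L)) {
    if (ch[i + 1L] == "A" && ch[i + 2L] == "T" && ch[i + 3L] == "G") {
      ch[i + 3L] <- "C"
    }
  }
  ## no decoy TATA upstream of the ATG (other than the real box)
  pre <- chars_dna(ch[1:L$m])
  pre <- scrub_motifs(pre, TATA_VARIANTS, protect = cbind(L$tata, L$tata + 6L))
  ch[1:L$m] <- dna_chars(pre)
  ## coding frame: no stop before the designated stop codon
  cds_pos <- c((L$m + 1L):(L$m + L$e1), (L$q + 1L):L$stop_end)
  codons <- matrix(ch[cds_pos], nrow = 3L)
  n_cod <- ncol(codons)
  for (k in seq_len(n_cod - 1L)) {
    if (paste(codons[, k], collapse = "") %in% STOP_SET) {
      idx <- cds_pos[3L * k]
      ch[idx] <- "C"            # TAA/TAG/TGA -> TAC/TAC/TGC, all sense
    }
  }
  set(L$stop_end - 3L, if (L$stop_class == "d") "TGA" else "TAA")
  ## polyA signals: scrub the search window then write the programmed ones
  win_end <- min(length(ch), L$stop_end + POLYA_SEARCH)
  tailseq <- chars_dna(ch[(L$stop_end + 1L):win_end])
  tailseq <- scrub_motifs(tailseq, c("AATAAA", "ATTAAA"))
  ch[(L$stop_end + 1L):win_end] <- dna_chars(tailseq)
  if (!is.na(L$off_can)) set(L$stop_end + L$off_can - 1L, "AATAAA")
  if (!is.na(L$off_var)) set(L$stop_end + L$off_var - 1L, "ATTAAA")
  chars_dna(ch)
}

## SNPs at `rate` over a gene block, avoiding the protected grammar; coding
## positions are mutated codon-aware (never creating a stop).
mutate_gene_seq <- function(block, L, rate) {
  ch <- dna_chars(block)
  n <- length(ch)
  protected <- rep(FALSE, n)
  prot <- function(s, e) protected[max(1L, s + 1L):min(n, e)] <<- TRUE
  prot(L$tata, L$tata + 6L)
  prot(L$a - 2L, L$a + 4L)
  prot(L$m, L$m + 3L)
  prot(L$m + L$e1 - 3L, L$m + L$e1 + 4L)       # donor region
  prot(L$q - 4L, L$q + 2L)                      # acceptor region
  prot(L$stop_end - 3L, L$stop_end)
  prot(L$m - 12L, L$m)                          # utr5 tail: ATG window guard
  if (!is.na(L$off_can)) prot(L$stop_end + L$off_can - 1L, L$stop_end + L$off_can + 5L)
  if (!is.na(L$off_var)) prot(L$stop_end + L$off_var - 1L, L$stop_end + L$off_var + 5L)
  cds_pos <- c((L$m + 1L):(L$m + L$e1), (L$q + 1L):L$stop_end)  # 1-based
  in_cds <- rep(FALSE, n)
  in_cds[cds_pos] <- TRUE
  k <- rbinom(1L, n, rate)
  if (k > 0) {
    sites <- sample.int(n, k)
    for (s in sites) {
      if (protected[s]) next
      old <- ch[s]
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      ch[s] <- new
      if (in_cds[s]) {
        ci <- which(cds_pos == s)
        cs <- ci - ((ci - 1L) %% 3L)
        codon <- paste(ch[cds_pos[cs:(cs + 2L)]], collapse = "")
        if (codon %in% STOP_SET) ch[s] <- old
      }
    }
  }
  fix_grammar(chars_dna(ch), L)
}

mutate_gene_block <- function(block, rate) {
  block$oriented <- mutate_gene_seq(block$oriented, block$layout, rate)
  block$seq <- if (block$strand == "+") block$oriented else
    revcomp_chr(block$oriented)
  block
}

## ---------------------------------------------------------------------------
## locus specification and generation

#' Specification for a synthetic locus
#'
#' The defaults emulate the family's observed genomic architecture: two
#' clusters of 2-7 genes on both strands, each gene flanked by GA and GAT
#' STRs, multi-kb GA STR islands at the cluster boundaries, genes derived from
#' a shared ancestral element sequence with element deletions, SNPs (~1%
#' divergence) and indels, plus one tandem segmental duplication.
#'
#' @param seed integer seed; identical (spec, seed) pairs generate identical
#'   output bytes.
#' @param n_clusters number of clusters (one output contig per cluster).
#' @param genes_per_cluster integer vector (recycled) or NULL to sample 2-7.
#' @param snp_rate per-base substitution rate applied to each gene relative
#'   to the ancestral template (conserved motifs are protected).
#' @param allele_divergence substitution rate applied to duplicated /
#'   perturbed copies.
#' @param indel_rate,indel_max indel rate (per filler base) and maximum
#'   indel length applied to intergenic filler.
#' @param island_length_range large GA island length range (nt).
#' @param flank_ga,flank_gat gene-flanking STR length ranges.
#' @param unit_filler,edge_filler intergenic filler length ranges (nt).
#' @param duplications number of tandem duplication events (default 1).
#' @param inversions number of gene-unit inversion events.
#' @param gene_pool catalogue pattern names genes are drawn from.
#' @param events optional explicit event list (see vignette); entries are
#'   lists with a `type` field among `tandem_duplication`,
#'   `ectopic_insertion`, `inversion`, `element_deletion`.
#' @return a `trf_locus_spec` list.
#' @export
locus_spec <- function(seed = 1L, n_clusters = 2L, genes_per_cluster = NULL,
                       snp_rate = 0.01, allele_divergence = 0.005,
                       indel_rate = 2e-4, indel_max = 15L,
                       island_length_range = c(2500L, 4500L),
                       flank_ga = c(90L, 150L), flank_gat = c(45L, 75L),
                       unit_filler = c(2400L, 3000L),
                       edge_filler = c(150L, 400L),
                       duplications = 1L, inversions = 0L,
                       gene_pool = c("D1", "E2", "A2", "B8", "C4", "01"),
                       distinct_patterns = FALSE,
                       events = NULL) {
  structure(as.list(environment()), class = "trf_locus_spec")
}

rint <- function(range) if (range[1] >= range[2]) as.integer(range[1]) else
  sample(range[1]:range[2], 1)

build_unit <- function(params, spec, tpl, ref, introns) {
  gene <- build_gene_block(params, tpl, ref, introns, snp_rate = spec$snp_rate)
  ## units begin at their 5' GA STR so that duplication spans copied at unit
  ## granularity have GA-anchored edges; the trailing filler is the IGR that
  ## travels with the unit in a tandem duplication
  blocks <- list(
    list(kind = "str", motif = "GA", seq = make_str_seq("GA", rint(spec$flank_ga))),
    list(kind = "str", motif = "GAT", seq = make_str_seq("GAT", rint(spec$flank_gat))),
    list(kind = "filler", seq = random_dna(150, 0.4)),
    gene,
    list(kind = "filler", seq = random_dna(150, 0.4)),
    list(kind = "str", motif = "GAT", seq = make_str_seq("GAT", rint(spec$flank_gat))),
    list(kind = "str", motif = "GA", seq = make_str_seq("GA", rint(spec$flank_ga))),
    list(kind = "filler", seq = random_dna(rint(spec$unit_filler), 0.4))
  )
  blocks
}

copy_unit <- function(unit, divergence) {
  lapply(unit, function(b) {
    if (b$kind == "gene" && divergence > 0) mutate_gene_block(b, divergence)
    else b
  })
}

invert_unit <- function(unit) {
  rev(lapply(unit, function(b) {
    b$seq <- revcomp_chr(b$seq)
    if (b$kind == "gene") b$strand <- if (b$strand == "+") "-" else "+"
    b
  }))
}

#' Generate a synthetic locus with truth annotations
#'
#' @param spec a `trf_locus_spec` from [locus_spec()].
#' @return `trf_locus`: list with `sequences` (DNAStringSet, one per
#'   cluster), `truth` (list of data.frames: `genes` -- full gene-model rows
#'   identical in shape to [annotate_gene_model()] output plus `pattern_name`
#'   and `intron_type`; `islands`; `duplications`; `events`), `spec`, and the
#'   internal `clusters` block lists used by [perturb_alleles()].
#' @export
generate_locus <- function(spec = locus_spec()) {
  assert_that(inherits(spec, "trf_locus_spec"), "spec must come from locus_spec()")
  tpl <- ancestral_template()
  ref <- trf_reference("repeat_based")
  introns <- trf_reference_introns()
  catalogue <- trf_pattern_catalogue()
  with_seed(spec$seed, {
    events_log <- list()
    note <- function(type, detail) {
      events_log[[length(events_log) + 1L]] <<-
        data.frame(event = type, detail = detail, stringsAsFactors = FALSE)
    }
    clusters <- vector("list", spec$n_clusters)
    for (k in seq_len(spec$n_clusters)) {
      ng <- if (is.null(spec$genes_per_cluster)) sample(2:7, 1) else
        as.integer(rep(spec$genes_per_cluster, length.out = spec$n_clusters)[k])
      names_k <- sample(spec$gene_pool, ng,
                        replace = !isTRUE(spec$distinct_patterns))
      units <- lapply(names_k, function(nm) {
        build_unit(sample_gene_params(nm, catalogue), spec, tpl, ref, introns)
      })
      note("cluster", sprintf("cluster %d: %d genes (%s)", k, ng,
                              paste(names_k, collapse = ",")))
      clusters[[k]] <- list(
        units = units,
        pre = list(
          list(kind = "island", motif = "GA",
               seq = make_str_seq("GA", rint(spec$island_length_range))),
          list(kind = "filler", seq = random_dna(rint(spec$edge_filler), 0.4))),
        post = list(
          list(kind = "filler", seq = random_dna(rint(spec$edge_filler), 0.4)),
          list(kind = "island", motif = "GA",
               seq = make_str_seq("GA", rint(spec$island_length_range))))
      )
    }
    dup_truth <- list()
    ## tandem duplications (recorded for dot-plot truth)
    for (d in seq_len(spec$duplications)) {
      k <- sample(seq_len(spec$n_clusters), 1)
      i <- sample(seq_along(clusters[[k]]$units), 1)
      cp <- copy_unit(clusters[[k]]$units[[i]], spec$allele_divergence)
      clusters[[k]]$units <- append(clusters[[k]]$units, list(cp), after = i)
      dup_truth[[length(dup_truth) + 1L]] <- list(cluster = k, unit = i)
      note("tandem_duplication", sprintf("cluster %d unit %d", k, i))
    }
    for (v in seq_len(spec$inversions)) {
      k <- sample(seq_len(spec$n_clusters), 1)
      i <- sample(seq_along(clusters[[k]]$units), 1)
      clusters[[k]]$units[[i]] <- invert_unit(clusters[[k]]$units[[i]])
      note("inversion", sprintf("cluster %d unit %d", k, i))
    }
    ## explicit events
    for (ev in spec$events %||% list()) {
      clusters <- apply_event(clusters, ev, spec, ref, note)
    }
    clusters <- apply_filler_indels(clusters, spec)
    assemble_locus(clusters, spec, dup_truth,
                   do.call(rbind, events_log) %||%
                     data.frame(event = character(0), detail = character(0)))
  })
}

apply_event <- function(clusters, ev, spec, ref, note) {
  type <- ev$type
  if (type == "tandem_duplication") {
    cp <- copy_unit(clusters[[ev$cluster]]$units[[ev$gene]],
                    spec$allele_divergence)
    clusters[[ev$cluster]]$units <-
      append(clusters[[ev$cluster]]$units, list(cp), after = ev$gene)
    note(type, sprintf("cluster %d unit %d", ev$cluster, ev$gene))
  } else if (type == "ectopic_insertion") {
    cp <- copy_unit(clusters[[ev$from_cluster]]$units[[ev$gene]],
                    spec$allele_divergence)
    clusters[[ev$to_cluster]]$units <-
      append(clusters[[ev$to_cluster]]$units, list(cp),
             after = ev$after %||% length(clusters[[ev$to_cluster]]$units))
    note(type, sprintf("cluster %d unit %d -> cluster %d",
                       ev$from_cluster, ev$gene, ev$to_cluster))
  } else if (type == "inversion") {
    clusters[[ev$cluster]]$units[[ev$gene]] <-
      invert_unit(clusters[[ev$cluster]]$units[[ev$gene]])
    note(type, sprintf("cluster %d unit %d", ev$cluster, ev$gene))
  } else if (type == "element_deletion") {
    unit <- clusters[[ev$cluster]]$units[[ev$gene]]
    gi <- which(vapply(unit, function(b) b$kind == "gene", logical(1)))
    p <- unit[[gi]]$params
    assert_that(all(p$element_mask[ev$elements]),
                "element_deletion of an element that is already absent")
    assert_that(!any(ev$elements %in% c(1L, ref$terminal_element)),
                "cannot delete the first or terminal element")
    p$element_mask[ev$elements] <- FALSE
    unit[[gi]] <- build_gene_block(p, snp_rate = spec$snp_rate)
    clusters[[ev$cluster]]$units[[ev$gene]] <- unit
    note(type, sprintf("cluster %d unit %d elements %s", ev$cluster, ev$gene,
                       paste(ev$elements, collapse = ",")))
  } else {
    stop("unknown event type: ", type, call. = FALSE)
  }
  clusters
}

## indels applied to stored filler blocks (so reassembly is reproducible)
apply_filler_indels <- function(clusters, spec) {
  if (spec$indel_rate <= 0) return(clusters)
  indel_one <- function(b) {
    if (b$kind != "filler") return(b)
    n <- nchar(b$seq)
    nind <- rbinom(1L, n, spec$indel_rate)
    for (j in seq_len(nind)) {
      len <- sample(seq_len(spec$indel_max), 1)
      at <- sample.int(max(1L, nchar(b$seq) - len), 1)
      if (runif(1) < 0.5) {
        b$seq <- paste0(substr(b$seq, 1, at), random_dna(len, 0.4),
                        substr(b$seq, at + 1L, nchar(b$seq)))
      } else {
        b$seq <- paste0(substr(b$seq, 1, at),
                        substr(b$seq, at + len + 1L, nchar(b$seq)))
      }
    }
    b
  }
  for (k in seq_along(clusters)) {
    clusters[[k]]$pre <- lapply(clusters[[k]]$pre, indel_one)
    clusters[[k]]$post <- lapply(clusters[[k]]$post, indel_one)
    clusters[[k]]$units <- lapply(clusters[[k]]$units,
                                  function(u) lapply(u, indel_one))
  }
  clusters
}

## final assembly: islands + edge fillers + units -> contigs + truth tables
assemble_locus <- function(clusters, spec, dup_truth, events_df) {
  seqs <- character(0)
  genes <- list()
  islands <- list()
  dups <- list()
  gene_no <- 0L
  for (k in seq_along(clusters)) {
    contig <- sprintf("cluster%d", k)
    blocks <- clusters[[k]]$pre
    unit_spans <- list()
    for (u in seq_along(clusters[[k]]$units)) {
      blocks <- c(blocks, lapply(clusters[[k]]$units[[u]], function(b) {
        b$unit <- u
        b
      }))
    }
    blocks <- c(blocks, clusters[[k]]$post)
    pos <- 0L
    unit_start <- list()
    for (b in blocks) {
      len <- nchar(b$seq)
      if (!is.null(b$unit)) {
        if (is.null(unit_start[[as.character(b$unit)]])) {
          unit_start[[as.character(b$unit)]] <- pos
        }
        unit_spans[[as.character(b$unit)]] <- c(unit_start[[as.character(b$unit)]],
                                                pos + len)
      }
      if (b$kind %in% c("island", "str")) {
        islands[[length(islands) + 1L]] <- data.frame(
          contig = contig, start = pos, end = pos + len, motif = b$motif,
          length_nt = len, kind = if (b$kind == "island") "island" else "flank",
          stringsAsFactors = FALSE)
      }
      if (b$kind == "gene") {
        gene_no <- gene_no + 1L
        L <- b$layout
        genes[[length(genes) + 1L]] <- cbind(
          build_gene_model_row(
            gene_id = sprintf("%s.g%d", contig,
                              sum(vapply(genes, function(g)
                                g$contig == contig, logical(1))) + 1L),
            contig = contig, strand = b$strand, w0 = pos, wn = len,
            tata = L$tata, a = L$a, m = L$m, e1 = L$e1, q = L$q,
            stop_end = L$stop_end, utr3_len = L$utr3_len,
            stop_class = L$stop_class, off_can = L$off_can,
            off_var = L$off_var),
          data.frame(pattern_name = b$params$pattern_name,
                     intron_type = b$params$intron_type,
                     subtype = b$params$subtype,
                     element_mask = paste(as.integer(b$params$element_mask),
                                          collapse = ""),
                     stringsAsFactors = FALSE))
      }
      pos <- pos + len
    }
    seqs[contig] <- paste(vapply(blocks, `[[`, character(1), "seq"),
                          collapse = "")
    for (d in dup_truth) {
      if (d$cluster != k) next
      s1 <- unit_spans[[as.character(d$unit)]]
      ## the copy was inserted immediately after; same length up to indels
      dups[[length(dups) + 1L]] <- data.frame(
        contig = contig, start1 = s1[1], end1 = s1[2],
        unit_len = s1[2] - s1[1], multiplicity = 2L,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    sequences = Biostrings::DNAStringSet(seqs),
    truth = list(
      genes = do.call(rbind, genes),
      islands = do.call(rbind, islands),
      duplications = if (length(dups)) do.call(rbind, dups) else
        data.frame(contig = character(0), start1 = integer(0),
                   end1 = integer(0), unit_len = integer(0),
                   multiplicity = integer(0)),
      events = events_df
    ),
    clusters = clusters,
    spec = spec
  ), class = "trf_locus")
}

#' Derive an allelic partner for a generated locus
#'
#' Produces a second haplotype differing by programmed STR-island length
#' changes and gene presence/absence, emulating allelic cluster pairs that
#' differ in gene content and island lengths.
#'
#' @param locus a `trf_locus` from [generate_locus()].
#' @param str_length_delta named integer vector: island index (in contig
#'   order across the locus, `"1"`, `"2"`, ...) -> length change in nt.
#' @param gene_presence_mask logical vector over the locus's genes (in truth
#'   order); `FALSE` deletes the gene unit.  NULL keeps all.
#' @param seed seed for the divergence substitutions applied to the allele.
#' @return a `trf_locus` for the second haplotype.
#' @export
perturb_alleles <- function(locus, str_length_delta = NULL,
                            gene_presence_mask = NULL, seed = 1L) {
  spec <- locus$spec
  clusters <- locus$clusters
  ng <- nrow(locus$truth$genes)
  if (!is.null(gene_presence_mask)) {
    assert_that(length(gene_presence_mask) == ng,
                "gene_presence_mask must cover every gene")
    assert_that(any(gene_presence_mask), "mask would remove all genes")
  }
  with_seed(seed, {
    gi <- 0L
    for (k in seq_along(clusters)) {
      keep <- logical(length(clusters[[k]]$units))
      for (u in seq_along(clusters[[k]]$units)) {
        gi <- gi + 1L
        keep[u] <- is.null(gene_presence_mask) || gene_presence_mask[gi]
        if (keep[u]) {
          clusters[[k]]$units[[u]] <- copy_unit(clusters[[k]]$units[[u]],
                                                spec$allele_divergence)
        }
      }
      clusters[[k]]$units <- clusters[[k]]$units[keep]
      assert_that(length(clusters[[k]]$units) > 0,
                  "mask would remove all genes in a cluster")
    }
    ## island length deltas: islands are indexed in contig order across the
    ## locus (pre island, post island per cluster)
    if (!is.null(str_length_delta)) {
      slots <- list()
      for (k in seq_along(clusters)) {
        slots[[length(slots) + 1L]] <- c(k, 1L)   # pre island
        slots[[length(slots) + 1L]] <- c(k, 2L)   # post island
      }
      for (nm in names(str_length_delta)) {
        slot <- slots[[as.integer(nm)]]
        delta <- as.integer(str_length_delta[[nm]])
        k <- slot[1]
        blk <- if (slot[2] == 1L) clusters[[k]]$pre[[1]] else
          clusters[[k]]$post[[2]]
        newlen <- nchar(blk$seq) + delta
        assert_that(newlen >= 9L, "delta would shrink island below seed length")
        blk$seq <- make_str_seq(blk$motif, newlen)
        if (slot[2] == 1L) clusters[[k]]$pre[[1]] <- blk else
          clusters[[k]]$post[[2]] <- blk
      }
    }
    allele <- assemble_locus(clusters, spec, list(),
                             data.frame(event = "allele",
                                        detail = "perturbed haplotype"))
    allele$spec <- spec
    allele$clusters <- clusters
    allele
  })
}

#' Write a generated locus to FASTA + truth GFF3
#'
#' @param locus a `trf_locus`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "locus.fasta")
  Biostrings::writeXStringSet(locus$sequences, fa)
  gff <- file.path(dir, "truth.gff3")
  write_annotations(locus$truth$genes, locus$truth$islands, gff)
  ev <- file.path(dir, "events.tsv")
  write.table(locus$truth$events, ev, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fa, gff, ev))
}
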