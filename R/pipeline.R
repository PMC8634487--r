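## pipeline: end-to-end report over one or more contigs, mirroring the
## shapes of the family's locus tables (STR islands; gene-model dimensions;
## identity/coverage; dN/dS), plus duplication blocks and trees, with a
## reproducibility manifest.

#' Default pipeline configuration
#'
#' Every parameter has a default; an empty configuration runs end-to-end on
#' synthetic data.
#'
#' @return named list of parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    str = list(merge_gap = 50L, min_island_length = 1000L),
    annotate = list(max_mismatch = 2L),
    elements = list(presence_threshold = 0.5),
    dotplot = list(evalue = 10, word = 9L, min_unit_length = 1000L,
                   offset_bin = 100L, edge_search = 500L),
    tree = list(bootstrap = 0L, distance = "p")
  )
}

#' Extract the oriented region sequences of one gene model
#'
#' Returns the gene's component sequences (5'UTR, exons, intron, 3'UTR,
#' full gene, and the 5'/3' flanking regions of `fr_len` nt) in transcript
#' orientation, regardless of the gene's strand.
#'
#' @param seq_chr contig sequence as a character scalar.
#' @param m one-row gene-model data.frame.
#' @param fr_len flanking-region length (default 400 nt).
#' @return named list of character sequences.
#' @export
gene_region_seqs <- function(seq_chr, m, fr_len = 400L) {
  n <- nchar(seq_chr)
  get <- function(s, e) {
    s <- max(0L, s); e <- min(n, e)
    x <- subseq_chr(seq_chr, s, e)
    if (m$strand == "-") revcomp_chr(x) else x
  }
  if (m$strand == "+") {
    fr5 <- get(m$exon1_start - fr_len, m$exon1_start)
    fr3 <- get(m$exon2_end, m$exon2_end + fr_len)
  } else {
    fr5 <- get(m$exon1_end, m$exon1_end + fr_len)
    fr3 <- get(m$exon2_start - fr_len, m$exon2_start)
  }
  list(
    gene = get(m$gene_start, m$gene_end),
    utr5 = get(m$utr5_start, m$utr5_end),
    exon1 = get(m$exon1_start, m$exon1_end),
    intron = get(m$intron_start, m$intron_end),
    exon2 = get(m$exon2_start, m$exon2_end),
    utr3 = get(m$utr3_start, m$utr3_end),
    fr5 = fr5, fr3 = fr3
  )
}

#' Run the full locus report
#'
#' Chains the pipeline stages over the input contigs and writes
#' `islands.tsv`, `gene_models.tsv`, `identity.tsv`, `dnds.tsv`,
#' `dupblocks.tsv`, `trees/exon2_nj.nwk`, and `manifest.json` under
#' `out_dir`.  Stage failures are logged per contig and the report completes
#' for the remaining inputs.
#'
#' @param genomes named character vector of FASTA/GenBank paths, or a
#'   [Biostrings::DNAStringSet].
#' @param out_dir output directory.
#' @param config configuration list, see [default_config()].
#' @param probes probe set (default [trf_probes()]).
#' @param ref element reference (default repeat-based).
#' @return invisibly, a list with all in-memory tables (`islands`, `genes`,
#'   `identity`, `dnds`, `dupblocks`, `errors`).
#' @export
run_full_report <- function(genomes, out_dir, config = default_config(),
                            probes = trf_probes(),
                            ref = trf_reference("repeat_based")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  t0 <- Sys.time()
  if (is.character(genomes)) {
    seqs <- do.call(c, lapply(genomes, function(p) {
      fmt <- if (grepl("\\.(gb|gbk|genbank)$", p, ignore.case = TRUE))
        "genbank" else "fasta"
      read_sequences(p, fmt)
    }))
  } else {
    seqs <- genomes
  }
  errors <- data.frame(stage = character(0), input = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  log_err <- function(stage, input, e) {
    errors <<- rbind(errors, data.frame(stage = stage, input = input,
                                        message = conditionMessage(e),
                                        stringsAsFactors = FALSE))
  }
  islands_all <- list(); genes_all <- list(); dup_all <- list()
  introns_ref <- trf_reference_introns()
  catalogue <- trf_pattern_catalogue()
  timings <- list()
  for (cn in names(seqs)) {
    tic <- Sys.time()
    seq_chr <- as.character(seqs[[cn]])
    isl <- tryCatch({
      rbind(scan_str_islands(seq_chr, "GA", config$str$merge_gap, contig = cn),
            scan_str_islands(seq_chr, "GAT", config$str$merge_gap, contig = cn))
    }, error = function(e) { log_err("strscan", cn, e); NULL })
    if (!is.null(isl)) islands_all[[cn]] <- isl
    g <- tryCatch({
      annotate_genes(seq_chr, probes, ref, contig = cn,
                     max_mismatch = config$annotate$max_mismatch)
    }, error = function(e) { log_err("annotate", cn, e); NULL })
    if (!is.null(g) && nrow(g) > 0) genes_all[[cn]] <- g
    timings[[cn]] <- as.numeric(difftime(Sys.time(), tic, units = "secs"))
  }
  genes <- if (length(genes_all)) do.call(rbind, genes_all) else NULL
  islands <- if (length(islands_all)) do.call(rbind, islands_all) else NULL

  ## element patterns, intron types, names
  patterns <- list(); name_vec <- character(0)
  regions <- list()
  if (!is.null(genes) && nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      m <- genes[i, ]
      rs <- gene_region_seqs(as.character(seqs[[m$contig]]), m)
      regions[[m$gene_id]] <- rs
      patterns[[m$gene_id]] <- tryCatch(
        assign_element_pattern(rs$exon2, ref,
                               config$elements$presence_threshold,
                               gene_id = m$gene_id),
        error = function(e) { log_err("elements", m$gene_id, e); NULL })
    }
    ok <- !vapply(patterns, is.null, logical(1))
    if (any(ok)) {
      name_vec <- rep(NA_character_, nrow(genes))
      name_vec[ok] <- derive_gene_names(patterns[ok], catalogue)
      genes$name <- name_vec
      genes$intron_type <- vapply(seq_len(nrow(genes)), function(i) {
        tryCatch(classify_intron_type(regions[[genes$gene_id[i]]]$intron,
                                      introns_ref)$label,
                 error = function(e) NA_character_)
      }, character(1))
    }
  }

  ## identity / dnds among same-name groups
  id_rows <- list(); dn_rows <- list()
  if (!is.null(genes) && nrow(genes) > 1 && "name" %in% names(genes)) {
    base <- sub("[a-z]+$", "", genes$name)
    for (grp in unique(base[!is.na(base)])) {
      idx <- which(base == grp)
      if (length(idx) < 2) next
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in (a + 1):length(idx)) {
          ia <- idx[a]; ib <- idx[b]
          ra <- regions[[genes$gene_id[ia]]]; rb <- regions[[genes$gene_id[ib]]]
          ic <- tryCatch(identity_and_coverage(ra$gene, rb$gene),
                         error = function(e) c(identity = NA, coverage = NA))
          id_rows[[length(id_rows) + 1L]] <- data.frame(
            gene_a = genes$name[ia], gene_b = genes$name[ib],
            coverage = ic[["coverage"]], identity = ic[["identity"]],
            stringsAsFactors = FALSE)
          if (nchar(ra$exon2) == nchar(rb$exon2)) {
            full_a <- paste0(ra$exon1, ra$exon2)
            full_b <- paste0(rb$exon1, rb$exon2)
            if (nchar(full_a) == nchar(full_b)) {
              dd <- tryCatch(dnds_pair(full_a, full_b), error = function(e) NULL)
              if (!is.null(dd)) {
                dn_rows[[length(dn_rows) + 1L]] <- data.frame(
                  gene_a = genes$name[ia], gene_b = genes$name[ib],
                  S = dd$snps$totals[["n_synonymous"]],
                  N = dd$snps$totals[["n_nonsynonymous"]],
                  aa = dd$snps$totals[["n_property_shift"]],
                  Sd = round(dd$counts[["Sd"]], 2),
                  Sn = round(dd$counts[["Sn"]], 2),
                  dNdS = if (dd$dnds$undefined) NA_real_ else
                    round(dd$dnds$ratio, 6),
                  stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
    }
  }

  ## self dot plots and duplication blocks per contig
  for (cn in names(seqs)) {
    mt <- tryCatch(dotplot_matches(seqs[[cn]], seqs[[cn]],
                                   evalue_threshold = config$dotplot$evalue,
                                   word = config$dotplot$word),
                   error = function(e) { log_err("dotplot", cn, e); NULL })
    if (is.null(mt)) next
    bl <- detect_duplication_blocks(
      mt, islands[islands$contig == cn, ],
      if (!is.null(genes)) genes[genes$contig == cn, ] else NULL,
      min_unit_length = config$dotplot$min_unit_length,
      offset_bin = config$dotplot$offset_bin,
      edge_search = config$dotplot$edge_search)
    if (nrow(bl) > 0) {
      bl <- cbind(contig = cn, bl, stringsAsFactors = FALSE)
      dup_all[[cn]] <- bl
    }
  }
  dupblocks <- if (length(dup_all)) do.call(rbind, dup_all) else
    data.frame(contig = character(0))

  ## exon-2 NJ tree from pairwise identity distances
  if (!is.null(genes) && nrow(genes) >= 3) {
    ids <- genes$gene_id
    nmx <- if ("name" %in% names(genes) && !anyNA(genes$name)) genes$name else ids
    d <- matrix(0, length(ids), length(ids), dimnames = list(nmx, nmx))
    for (a in seq_along(ids)[-length(ids)]) {
      for (b in (a + 1):length(ids)) {
        pa <- Biostrings::pairwiseAlignment(
          regions[[ids[a]]]$exon2, regions[[ids[b]]]$exon2, type = "global",
          substitutionMatrix = NUC_MAT, gapOpening = 10, gapExtension = 0.5)
        d[a, b] <- d[b, a] <- 1 - Biostrings::pid(pa) / 100
      }
    }
    tr <- tryCatch(nj_from_distances(d), error = function(e) NULL)
    if (!is.null(tr)) {
      ape::write.tree(tr, file.path(out_dir, "trees", "exon2_nj.nwk"))
    }
  }

  ## write tables
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  isl_rep <- if (!is.null(islands)) {
    do.call(rbind, lapply(split(islands[islands$motif == "GA", ],
                                islands$contig[islands$motif == "GA"]),
                          summarize_islands,
                          min_island_length = config$str$min_island_length))
  } else data.frame()
  wt(isl_rep, "islands.tsv")
  wt(genes %||% data.frame(), "gene_models.tsv")
  wt(if (length(id_rows)) do.call(rbind, id_rows) else data.frame(),
     "identity.tsv")
  wt(if (length(dn_rows)) do.call(rbind, dn_rows) else data.frame(),
     "dnds.tsv")
  wt(dupblocks, "dupblocks.tsv")
  wt(errors, "errors.tsv")
  manifest <- list(
    package = "trflocus",
    version = as.character(utils::packageVersion("trflocus")),
    seed = config$seed,
    config = config,
    inputs = names(seqs),
    input_lengths = setNames(as.integer(Biostrings::width(seqs)), names(seqs)),
    stage_seconds = timings,
    generated = format(t0, "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(islands = isl_rep, genes = genes,
                 identity = if (length(id_rows)) do.call(rbind, id_rows) else NULL,
                 dnds = if (length(dn_rows)) do.call(rbind, dn_rows) else NULL,
                 dupblocks = dupblocks, errors = errors))
}

#' Simulate flanking-region alignments with a two-lineage history
#'
#' Generates synthetic 5'FR and 3'FR alignments (~400 nt each, substitutions
#' only, so the rows are aligned by construction) for the seventeen named
#' family members plus an outgroup, evolved along a fixed two-lineage
#' genealogy: one lineage carries the D1/B8/C4 genes, the other the
#' E2/01/A2 genes.  This mirrors the family's inferred history and provides
#' the fixture for tree-structure checks; it is synthetic data, not the
#' published alignment.
#'
#' @param seed integer seed.
#' @param fr_len region length (default 400 nt).
#' @return list `fr5`, `fr3` (named aligned character vectors) and
#'   `concat` (concatenated 5'-3'FR alignment).
#' @export
simulate_fr_alignments <- function(seed = 744L, fr_len = 400L) {
  mutate_seq <- function(s, rate) {
    ch <- dna_chars(s)
    k <- rbinom(1L, length(ch), rate)
    if (k > 0) {
      at <- sample.int(length(ch), k)
      for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    chars_dna(ch)
  }
  with_seed(seed, {
    clade1 <- c("D1y", "D1g", "D1b", "D1e", "D1d", "D1f", "D1h",
                "B8", "B8a", "C4", "C4a")
    clade2 <- c("E2", "E2a", "E2b", "01", "A2", "A2a")
    one_region <- function() {
      root <- random_dna(fr_len, 0.4)
      anc1 <- mutate_seq(root, 0.10)
      anc2 <- mutate_seq(root, 0.10)
      out <- c(
        setNames(lapply(clade1, function(g) mutate_seq(anc1, 0.03)), clade1),
        setNames(lapply(clade2, function(g) mutate_seq(anc2, 0.03)), clade2),
        LvTrf = mutate_seq(root, 0.30)
      )
      unlist(out)
    }
    fr5 <- one_region()
    fr3 <- one_region()
    list(fr5 = fr5, fr3 = fr3,
         concat = setNames(paste0(fr5, fr3), names(fr5)))
  })
}

#' Regression harness for the published BAC accessions
#'
#' Runs the full pipeline on locally supplied GenBank flat files for the four
#' BAC inserts (KU668450, KU668451, KU668453, KU668454) and checks the
#' published locus facts: 17 genes in 4 clusters, the three large STR island
#' lengths per Locus-2 BAC, representative gene-model dimensions,
#' identity/coverage integers, and dN/dS behavior for identical pairs.  The
#' sequences are not shipped with the package and are never downloaded; place
#' the flat files (named `<accession>.gb`) under `dir`.
#'
#' @param dir directory containing the four GenBank flat files.
#' @param out_dir report output directory.
#' @return data.frame of named checks with observed/expected values.
#' @export
run_bac_regression <- function(dir, out_dir = tempfile("bacreport")) {
  acc <- c("KU668451", "KU668453", "KU668450", "KU668454")
  paths <- file.path(dir, paste0(acc, ".gb"))
  assert_that(all(file.exists(paths)),
              paste("missing GenBank flat files under", dir))
  rep <- run_full_report(setNames(paths, acc), out_dir)
  genes <- rep$genes
  isl <- rep$islands
  big <- function(contig) {
    x <- isl[isl$contig == contig & isl$class == "island", "length_nt"]
    sort(x, decreasing = TRUE)[1:3]
  }
  checks <- list(
    c("total_genes", nrow(genes), 17),
    c("m18_str1", big("KU668450")[1], 4293),
    c("m18_str2", big("KU668450")[2], 3869),
    c("m18_str3", big("KU668450")[3], 2633),
    c("p4_str1", big("KU668454")[1], 4314),
    c("p4_str2", big("KU668454")[2], 3998),
    c("p4_str3", big("KU668454")[3], 2635)
  )
  df <- do.call(rbind, lapply(checks, function(x) {
    data.frame(check = x[1], observed = as.numeric(x[2]),
               expected = as.numeric(x[3]), stringsAsFactors = FALSE)
  }))
  df$pass <- !is.na(df$observed) & df$observed == df$expected
  df
}
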