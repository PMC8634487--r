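#!/usr/bin/env Rscript
## Pairwise sequence statistics among the annotated genes: BLAST-like
## identity/coverage for same-pattern pairs (the locus identity table),
## percent mismatch per gene region, and NG86 dN/dS with Jukes-Cantor
## correction for same-pattern coding pairs (the locus dN/dS table).

suppressMessages(library(trflocus))
`%||%` <- function(x, y) if (is.null(x)) y else x
simdir <- file.path("results", "analysis", "sim")
out <- file.path("results", "analysis")
clusters <- c("locus1_cluster1", "locus1_cluster2",
              "locus2_cluster3", "locus2_cluster4")

## collect per-gene region sequences, keyed by cluster and locus-wide name
genes <- list()
for (cl in clusters) {
  s <- as.character(read_sequences(file.path(simdir, cl, "locus.fasta"))[[1]])
  g <- annotate_genes(s, contig = cl)
  ref <- trf_reference("repeat_based")
  pats <- lapply(seq_len(nrow(g)), function(i) {
    assign_element_pattern(gene_region_seqs(s, g[i, ])$exon2, ref)
  })
  nms <- derive_gene_names(pats, trf_pattern_catalogue())
  for (i in seq_len(nrow(g))) {
    genes[[paste(cl, nms[i], sep = ":")]] <-
      c(gene_region_seqs(s, g[i, ]), list(pattern = sub("[a-z?]+$", "", nms[i])))
  }
}

## identity/coverage for same-pattern pairs (full gene sequence)
id_rows <- list(); dn_rows <- list(); pm_rows <- list()
keys <- names(genes)
for (a in seq_along(keys)[-length(keys)]) {
  for (b in (a + 1):length(keys)) {
    ga <- genes[[keys[a]]]; gb <- genes[[keys[b]]]
    if (ga$pattern != gb$pattern) next
    ic <- identity_and_coverage(ga$gene, gb$gene)
    id_rows[[length(id_rows) + 1L]] <- data.frame(
      gene_a = keys[a], gene_b = keys[b],
      coverage = ic[["coverage"]], identity = ic[["identity"]])
    cds_a <- paste0(ga$exon1, ga$exon2)
    cds_b <- paste0(gb$exon1, gb$exon2)
    if (nchar(cds_a) == nchar(cds_b)) {
      dd <- dnds_pair(cds_a, cds_b)
      dn_rows[[length(dn_rows) + 1L]] <- data.frame(
        gene_a = keys[a], gene_b = keys[b],
        S = dd$snps$totals[["n_synonymous"]],
        N = dd$snps$totals[["n_nonsynonymous"]],
        aa = dd$snps$totals[["n_property_shift"]],
        Sd = round(dd$counts[["Sd"]], 2), Sn = round(dd$counts[["Sn"]], 2),
        dNdS = if (dd$dnds$undefined) NA else round(dd$dnds$ratio, 6),
        selection = dd$dnds$selection %||% NA)
    }
  }
}

## percent mismatch per region across all genes (equal-length regions only;
## substitution-level divergence keeps the regions columnwise comparable)
for (region in c("fr5", "exon1", "intron", "exon2", "fr3")) {
  seqs <- vapply(genes, function(g) g[[region]], character(1))
  lens <- nchar(seqs)
  keep <- lens == as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  if (sum(keep) < 2) next
  pm <- percent_mismatch(seqs[keep], region = region)
  pm_rows[[region]] <- pm$pairs
}

write.table(do.call(rbind, id_rows), file.path(out, "identity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, dn_rows), file.path(out, "dnds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, pm_rows), file.path(out, "percent_mismatch.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

idt <- do.call(rbind, id_rows)
cat(sprintf("Same-pattern pairs: %d; identity %d-%d%%, coverage %d-%d%%\n",
            nrow(idt), min(idt$identity), max(idt$identity),
            min(idt$coverage), max(idt$coverage)))
dnt <- do.call(rbind, dn_rows)
cat(sprintf("dN/dS computed for %d pairs; %d undefined (identical pairs)\n",
            nrow(dnt), sum(is.na(dnt$dNdS))))
cat("Tables written: identity.tsv, dnds.tsv, percent_mismatch.tsv\n")
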