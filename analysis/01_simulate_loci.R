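#!/usr/bin/env Rscript
## Simulate the study system: two loci, each an allelic pair of gene
## clusters.  Locus 1 carries a 7-gene and a 6-gene haplotype (one gene
## present in only one allele); Locus 2 carries two 2-gene haplotypes whose
## second STR island differs in length.  Truth annotations are written next
## to the sequences so later steps can be audited.

suppressMessages(library(trflocus))
out <- file.path("results", "analysis", "sim")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Locus 1: 7 genes, then an allele with one gene deleted
locus1 <- generate_locus(locus_spec(seed = 101L, n_clusters = 1,
                                    genes_per_cluster = 7, duplications = 0))
allele1 <- perturb_alleles(locus1,
                           gene_presence_mask = c(TRUE, TRUE, FALSE, TRUE,
                                                  TRUE, TRUE, TRUE),
                           seed = 102L)

## Locus 2: two tightly linked genes plus a tandem segmental duplication;
## the allele differs by 129 nt in its second large GA island
locus2 <- generate_locus(locus_spec(seed = 201L, n_clusters = 1,
                                    genes_per_cluster = 1, duplications = 1))
allele2 <- perturb_alleles(locus2, str_length_delta = c("2" = -129L),
                           seed = 202L)

write_locus(locus1, file.path(out, "locus1_cluster1"))
write_locus(allele1, file.path(out, "locus1_cluster2"))
write_locus(locus2, file.path(out, "locus2_cluster3"))
write_locus(allele2, file.path(out, "locus2_cluster4"))

cat("Simulated loci:\n")
cat(sprintf("  Locus 1 alleles: %d and %d genes\n",
            nrow(locus1$truth$genes), nrow(allele1$truth$genes)))
cat(sprintf("  Locus 2 alleles: %d genes each; programmed duplication unit %d nt\n",
            nrow(locus2$truth$genes), locus2$truth$duplications$unit_len[1]))
cat(sprintf("  Island-2 length difference between Locus 2 alleles: 129 nt\n"))
cat("Sequences and truth GFF3 under", out, "\n")
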