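#!/usr/bin/env Rscript
## Regenerates the synthetic reference fixtures shipped under inst/extdata.
## All objects are deterministic (internal fixed seeds), so re-running this
## script reproduces the files byte-for-byte.

library(trflocus)

root <- normalizePath(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), ".."))
ext <- file.path(root, "inst", "extdata")
dir.create(ext, showWarnings = FALSE, recursive = TRUE)

## element references (both schemes share one consensus)
refdir <- file.path(ext, "element_ref_synthetic")
write_element_reference(trf_reference("repeat_based"), refdir)
write_element_reference(trf_reference("cDNA_based"), refdir)

## typed reference introns
introns <- trf_reference_introns()
writeLines(as.vector(rbind(paste0(">", names(introns)), unname(introns))),
           file.path(ext, "reference_introns_synthetic.fasta"))

## probe set
probes <- trf_probes()
writeLines(as.vector(rbind(paste0(">", names(probes)), unname(probes))),
           file.path(ext, "probes_synthetic.fasta"))

## pattern catalogue
write.table(trf_pattern_catalogue(),
            file.path(ext, "pattern_catalogue_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## flanking-region alignments with the two-lineage history (tree fixture)
fr <- simulate_fr_alignments(seed = 744L)
wr_aln <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", names(aln)), unname(aln))), path)
}
frdir <- file.path(ext, "fr_alignments_synthetic")
dir.create(frdir, showWarnings = FALSE)
wr_aln(fr$fr5, file.path(frdir, "fr5_aln.fasta"))
wr_aln(fr$fr3, file.path(frdir, "fr3_aln.fasta"))

cat("fixtures written under", ext, "\n")
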