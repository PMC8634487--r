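# trflocus

Locus-level annotation and comparative analysis of the *SpTransformer*
(*SpTrf*) immune gene family of the purple sea urchin, *Strongylocentrotus
purpuratus*.

The *SpTrf* genes are small, two-exon immune-effector genes that occur in
tight genomic clusters. Each gene is flanked by GA (and usually GAT) short
tandem repeats, and multi-kilobase GA STR islands flank whole clusters —
an architecture thought to promote the duplications and deletions that
diversify the family. Exon 2 is a mosaic of 25–27 sequence blocks
("elements") whose presence/absence pattern defines the gene names (A, B,
C, D, E, and 0 classes), and the single intron falls into sequence types
α–ε. Characterizing a locus therefore means: finding the STR islands,
building full gene models from a conserved motif grammar, decomposing
exon 2 into its element pattern, typing the intron, quantifying pairwise
divergence, locating segmental duplications, and placing the genes on
trees.

`trflocus` implements that pipeline as a set of composable R functions plus
a seeded synthetic locus generator with exact truth annotations, so every
stage can be exercised and validated offline.

## What the package computes

* **STR islands** — `scan_str_islands()` maps GA/GAT runs from the GAGAGA /
  GATGATGAT seeds allowing a single mismatch, merges nearby runs, and
  `summarize_islands()` ranks the multi-kb cluster-flanking islands
  (STR1, STR2, ...) apart from the short gene-flanking STRs.
* **Gene models** — `locate_gene_candidates()` anchors genes from conserved
  probe co-occurrence; `annotate_gene_model()` builds the full model by
  ordered motif search: TATA box (TATAAA/TATATA) → initiator
  T(C/A)A(+1)GTT whose conserved A is the transcription start → ATG at a
  146–149 nt 5'UTR → GT donor at exon 1 length 51/54 nt → AG acceptor →
  open reading frame through a stop in the terminal element (stop classes
  a–d) → AATAAA/ATTAAA polyadenylation signals.
* **Element patterns** — `assign_element_pattern()` aligns exon 2 to the
  element-scheme consensus (repeat-based 27-element or cDNA-based
  26-element) and calls each element present at ≥ 50% column occupancy;
  `derive_gene_name()` maps key-element subtype and pattern to a family
  name. `classify_intron_type()` types introns against the α–ε references
  and scans for chimeric segments.
* **Pairwise statistics** — `identity_and_coverage()` (BLASTN-like local
  alignment, whole-percent output), `identity_matrix()` (gaps as a fifth
  character state), and `percent_mismatch()`, the family's statistic
  `100 · p / ln(n)` with `p` the pairwise distance and `n` the number of
  sequences compared (ln 2 for a pair).
* **dN/dS** — `ng86_counts()` implements Nei–Gojobori pathway counting
  (all substitution orderings averaged, stop-crossing pathways excluded)
  and `dnds_ratio()` applies the Jukes–Cantor correction
  `d = −(3/4)·ln(1 − 4p/3)`; identical pairs are reported "undefined", a
  value, not an error. `catalog_snps()` tabulates each SNP with its amino
  acid and charge/pI consequences.
* **Segmental duplications** — `dotplot_matches()` (9-mer seeds, both
  orientations, ungapped X-drop extension with match +5 / mismatch −4 /
  X-drop 30, Karlin–Altschul e-values) and `detect_duplication_blocks()`
  (offset clustering of ≥ 1 kb forward matches, copy counts, and the
  nearest GA/GAT STR at each block edge).
* **Trees** — `build_nj_tree()` / `bootstrap_support()`: neighbor-joining
  on p or Jukes–Cantor distances with pairwise gap deletion, seeded column
  bootstrap, and collapsing of nodes below 50% support.
* **Synthetic loci** — `generate_locus()` builds clusters of 2–7 genes on
  both strands from a shared ancestral gene (element deletions, SNPs,
  indels, STR flanks and islands, tandem duplications, ectopic insertions,
  inversions) with complete truth tables; `perturb_alleles()` derives
  allelic haplotypes differing in gene content and island lengths.

## Worked example

Generate a locus with one gene unit and its tandem segmental duplication,
then annotate it back:

```r
library(trflocus)
loc   <- generate_locus(locus_spec(seed = 11, n_clusters = 1,
                                   genes_per_cluster = 1, duplications = 1))
genes <- annotate_genes(loc$sequences[[1]], contig = "cluster1")
genes[, c("gene_id", "strand", "utr5_len", "exon1_len", "intron_len",
          "exon2_len", "utr3_len", "stop_class")]
#>      gene_id strand utr5_len exon1_len intron_len exon2_len utr3_len stop_class
#>  cluster1.g1      -      149        54        398       843      323          a
#>  cluster1.g2      -      149        54        398       843      323          a
```

Both annotated genes match the generator's truth exactly: a 149-nt 5'UTR,
the 54-nt exon 1, a 398-nt δ-type intron, an 843-nt coding exon 2 ending
at stop class "a". The cluster-flanking GA islands and the duplication are
recovered from the sequence alone:

```r
isl <- summarize_islands(scan_str_islands(loc$sequences[[1]], "GA",
                                          contig = "cluster1"))
isl[isl$class == "island", c("start", "end", "length_nt", "island_rank")]
#>    start   end length_nt island_rank
#> 1      0  3404      3404        STR1
#> 37 14909 19336      4427        STR2

m  <- dotplot_matches(loc$sequences[[1]], loc$sequences[[1]],
                      evalue_threshold = 1e-10)
bl <- detect_duplication_blocks(m, scan_str_islands(loc$sequences[[1]], "GA",
                                                    contig = "cluster1"), genes)
bl[, c("unit_len", "n_units", "edge5_motif", "edge5_dist",
       "edge3_motif", "edge3_dist")]
#>   unit_len n_units edge5_motif edge5_dist edge3_motif edge3_dist
#> 1     5560       2          GA          0          GA        136
```

The detected 5560-nt duplication unit equals the programmed truth
(`loc$truth$duplications$unit_len` is 5560), appears in two copies, and
both edges fall at GA STRs. Element decomposition and intron typing
identify the gene:

```r
rs <- gene_region_seqs(as.character(loc$sequences[[1]]), genes[1, ])
p  <- assign_element_pattern(rs$exon2, trf_reference("repeat_based"))
derive_gene_name(p)                      # "E2"
classify_intron_type(rs$intron)$label    # "delta"
```

## Analysis workflow

The `analysis/` directory holds the numbered study scripts, each a thin
driver over the package (run them from the repository root in order):

1. `01_simulate_loci.R` — simulate the two-locus study system: an allelic
   pair with 7 vs 6 genes, and an allelic pair of 2-gene clusters carrying
   a tandem segmental duplication and a programmed 129-nt island-length
   difference.
2. `02_annotate_clusters.R` — STR island and gene-model tables.
3. `03_pairwise_stats.R` — identity/coverage, percent mismatch per region,
   and dN/dS tables for same-pattern gene pairs.
4. `04_duplications.R` — dot plots and STR-anchored duplication blocks.
5. `05_trees.R` — bootstrapped NJ trees of the flanking-region alignments.

Outputs are written under `results/analysis/`. `run_full_report()` chains
the same stages programmatically over any set of contigs. For the
published BAC accessions, `run_bac_regression()` runs the pipeline on
locally supplied GenBank flat files.

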