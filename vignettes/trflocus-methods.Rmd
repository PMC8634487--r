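---
title: "Methods: locus annotation and comparative analysis of SpTrf gene clusters"
author: "trflocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus annotation and comparative analysis of SpTrf gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trflocus)
```

# The biological setting

The *SpTransformer* (*SpTrf*) genes of *Strongylocentrotus purpuratus* are
small immune genes with a fixed architecture: a short 5'UTR with a TATA box
and an initiator element, a 51/54-nt exon 1 encoding the leader, a single
~350–420 nt intron with canonical GT..AG splice signals, and a mosaic exon 2
built from a catalogue of sequence elements whose presence/absence pattern
identifies the gene. Genes sit in dense clusters, each gene framed by GA and
GAT short tandem repeats (STRs), and whole clusters are framed by
multi-kilobase GA STR islands. Segmental duplications whose edges coincide
with GA STRs, plus SNPs and indels, generate the family's diversity; allelic
haplotypes of one locus can differ both in gene content and in STR island
lengths.

This vignette documents the models and procedures behind each pipeline
stage, the tunable parameters, what the synthetic data generator does and
does not emulate, and the numerical conventions.

# Coordinates

All internal coordinates are 0-based half-open on the forward strand;
minus-strand features are stored in forward-strand coordinates with a strand
flag. GFF3 output converts to 1-based inclusive on emission and the
conversion is exercised on contig-boundary features in the tests.

# STR island scanning

The scanner matches the seed strings `GAGAGA` (GA) and `GATGATGAT` (GAT)
allowing one mismatch per window. Overlapping and adjacent windows chain
into runs; runs separated by at most `merge_gap` nt merge into islands, with
mismatch counts summed over the merged runs. A run's mismatch count is its
Hamming distance to the best-phase periodic extension of the repeat unit —
phase is free, because the search is substring-based, not a phased-array
model.

Parameters: `merge_gap` (default 50 nt) controls run merging, and
`min_island_length` (default 1000 nt) separates the large cluster-flanking
islands, ranked STR1, STR2, ... in 5'→3' order, from short gene-flanking
STRs. Neither threshold has a canonical value; both are exposed and the
defaults were chosen so multi-kb islands and ~100-nt flanks are cleanly
separated. The scanner is strand-specific by design (a GA run on the
reverse strand reads TC on the forward strand); `scan_str_both_strands()`
unions the forward scan with the scan of the reverse complement. Because
single-mismatch windows can hang over an island boundary, called islands can
exceed a pure repeat run by a few nucleotides on either side; differences
between alleles are unaffected since identical flanks extend identically.

# Gene-model annotation

Candidate genes are anchored by co-occurrence of at least two distinct
conserved probes within 3 kb (`locate_gene_candidates()`), with the strand
taken by majority over probe-hit strands. The model is then assembled by
ordered motif search on the anchor strand:

1. **TATA box**: `TATAAA` or `TATATA` (the two observed variants; the set
   is configurable).
2. **Initiator**: `T(C|A)AGTT`, whose conserved `A` is the transcription
   start (+1). The +1 A sits 27 nt 3' of the TATA box, i.e. at TATA start
   + 32; this canonical TATA→TSS spacing, combined with the observed
   146–149 nt 5'UTR, places the TATA box ~180 nt upstream of the start
   codon. (Statements that place the TATA box 101–111 nt from the start
   codon are arithmetically incompatible with a 146–149 nt 5'UTR and an
   initiator at +1; the package follows the 5'UTR lengths and the
   initiator geometry, which are mutually consistent.)
3. **Start codon**: ATG at 140–155 nt downstream of the +1 A (accepted
   models in practice fall in 146–149).
4. **Splice donor**: GT at exon-1 offsets taken from {54, 51} first, then
   48–60 as fallback.
5. **Splice acceptor**: AG ending 380–700 nt downstream of the ATG. The
   observed intron lengths (~340–420 nt) plus exon 1 put the acceptor at
   ~400–470 nt from the ATG; the window brackets that range generously.
6. **Selection** among donor/acceptor candidates: (i) maximize the reached
   in-frame stop (wrong-frame acceptors terminate early); (ii) among ties,
   maximize the Hamming match of the 24 nt after the acceptor to the
   element-reference start — exon 2 begins with element 1, which is also
   how curators anchor the exon; (iii) smallest deviation from the ~550 nt
   acceptor expectation; (iv) 3'-most. This is deterministic.
7. **Stop class**: the stop codon's alignment column in the element
   reference is matched to the four stop columns (a–d) of the terminal
   element — positional, not offset-based, so element deletions upstream
   do not shift the call.
8. **Polyadenylation**: first `AATAAA` (canonical) and `ATTAAA` (variant)
   within 520 nt downstream of the stop, offsets counted from the first
   nucleotide after the stop codon.

The 3'UTR length cannot be read from genomic sequence alone (it is a
transcript property), so the package uses the convention
`utr3_len = first polyA signal offset + 16 nt`; the generator uses the same
convention, making the column comparable but approximate for real data.

Candidates that do not overlap their probe anchor are discarded, which
prevents a neighboring gene inside the ±(1.5 kb, 3.5 kb) search window from
being annotated in place of the anchored one. Failures are explicit
(`"no TATA"`, `"no ORF"`) and collected per anchor, never silently dropped.
`validate_gene_model()` re-checks splice ends, frame, start/stop, exon-1
length, and polyA presence from the sequence.

# Element patterns, intron types, names

Exon 2 is aligned globally (affine gaps, match +2/mismatch −2, open 10,
extend 0.5) against the scheme consensus; an element is present when at
least `presence_threshold` (default 0.5) of its consensus columns are
occupied by query residues. Runs of incompletely occupied elements
containing at least one absent element are reported as deletion junctions
with the retained fragment lengths of the boundary elements — e.g. an
engineered deletion joining the first 10 nt of element 2 to the last 35 nt
of element 5 is reported exactly so. Input that aligns below 40% identity is
rejected as unalignable rather than decomposed.

Intron typing is nearest-reference: global alignment identity against each
typed reference intron (α–ε), label = argmax, identities reported so
borderline calls are auditable; no fixed identity cutoffs are imposed
because none are canonical. Chimera detection slides a 75-nt window at
25-nt steps (both configurable) and reports maximal runs of windows whose
best local-alignment type differs from the global label.

Gene names combine the key-element subtype (letter A–E; `0` when the key
element — element 10 repeat-based, 15 cDNA-based — is absent), the numeral
of the closest catalogued pattern by Hamming distance, and suffix letters
for repeated names in locus order. Ambiguous subtype calls (top two
subtypes within 2% identity) are flagged with `?`, never silently resolved.

**Reference fixtures are synthetic.** The element maps, key-element
subtypes, typed reference introns, probe set and pattern catalogue shipped
under `inst/extdata` are deterministic synthetic stand-ins with the correct
structure (27/26-element schemes sharing one consensus; stop columns in the
terminal element; five intron types; probes named after the conserved
primers). They let the whole pipeline run and be validated offline; users
with curated references can supply their own through the fixture readers.

# Pairwise statistics

* `identity_and_coverage()` uses local alignment with BLASTN-like scores
  (match +2, mismatch −3, gap open 5, gap extend 2); identity = identical
  columns / aligned columns, coverage = aligned query span / query length,
  both rounded to whole percent, matching how such tables are printed.
* `identity_matrix()` implements the fifth-state convention: a gap aligned
  to a residue is a mismatch, gap–gap is an identity; without the flag,
  gapped columns are excluded.
* `percent_mismatch()` is `100 · p / ln(n)` with `p` the p-distance under
  pairwise deletion of gap columns and `n` the number of sequences compared
  (ln 2 for pairwise values). This statistic is deliberately nonstandard —
  the divisor is the natural log of the number of sequences compared, not a
  substitution-model correction — and is implemented exactly as defined.
  Per-gene values average over all partners; all-gap pairs are flagged
  incomparable and excluded from averages.

# dN/dS (NG86 with Jukes–Cantor correction)

Synonymous site counts per codon position are the fraction of non-stop
single-base changes that are synonymous (changes to stop codons are
disregarded), averaged over the two sequences; nonsynonymous sites are
3 × codons − synonymous sites. Substitutions between codons differing at
k bases enumerate all k! orderings with equal weight, skip pathways through
stop codons, and average the synonymous/nonsynonymous step counts; when
every pathway crosses a stop, the column falls back to the direct per-base
coding effect. pS = Sd/S and pN = Sn/N are corrected as
d = −(3/4)·ln(1 − 4p/3). The ratio is undefined — a reported state, not an
error — when there are no substitutions, dS = 0, or 4p/3 ≥ 1. Selection is
labeled purifying (< 1) or diversifying (> 1). SNP property shifts use
charge classes {D,E} acidic / {K,R,H} basic / else neutral and pI terciles
(< 5.5 low, > 7.5 high) of free-residue pI values; both are documented here
because no thresholds are canonical.

# Dot plots and duplication blocks

Seeds are exact 9-mers in both orientations, joined via a k-mer table;
9-mers periodic with period ≤ 3 are masked so STR islands do not flood the
join. Same-diagonal seeds chain and extend ungapped under an X-drop rule
(match +5, mismatch −4, X-drop 30). The transition/transversion split of
the reference scoring (−3/−4) is collapsed to a single mismatch −4, and the
extension is ungapped — a documented approximation; indels between copies
split a duplication into slightly offset fragments, which the block caller
re-joins. Significance uses the ungapped Karlin–Altschul formula with λ
solved numerically for the score matrix and K fixed at 0.1, an approximation
adequate for thresholding.

Duplication blocks: forward matches ≥ `min_unit_length` (default 1 kb) and
positive diagonal offset seed clusters of consecutive offsets within
`offset_bin` (default 100 nt); all consistent-offset matches attach to the
cluster, fragments bridged by a 150-nt merge. The unit length is the widest
merged query-side interval; the copy count is the width of the contiguous
duplicated region divided by the unit length; each block edge reports the
nearest STR island within `edge_search` (default 500 nt), with islands
shorter than 30 nt ignored as anchors. For tandem arrays beyond two copies
the primary cluster measures two copies and higher-order offsets appear as
separate blocks — a known limitation. When two non-duplicated genes of
similar sequence happen to sit at a spacing within one offset bin of a real
duplication, their similarity merges into the block and biases the measured
unit length; the generator's variable intergenic spacing makes this rare,
and the validation loci use a single duplicated unit so the programmed copy
is the only repeated structure.

# Trees

Neighbor joining runs on p or Jukes–Cantor distances with pairwise gap
deletion. Negative branch lengths are clamped to zero with the deficit
moved to the sibling edge, preserving path lengths through the parent.
Bootstrap resamples alignment columns with replacement under a fixed seed;
support is the percentage of replicate trees containing each internal
bipartition; edges below `collapse_below` (default 50%) collapse into
polytomies. On additive distance matrices NJ reproduces the generating
topology and path lengths exactly (tested up to 6 taxa against enumeration
via cophenetic distances). Only the distance/NJ branch is implemented:
likelihood and parsimony alternatives produce concordant structures on this
family and are out of scope. Outgroup rooting is a display choice; trees
are built unrooted.

The shipped flanking-region alignments are simulated (substitutions only,
so rows are columnwise aligned) along a fixed two-lineage genealogy — one
lineage carrying the D1/B8/C4 genes, the other E2/01/A2 — with ~3%
within-lineage, ~10% stem, and ~30% outgroup divergence. They exist to
validate tree behavior (the two-lineage split is recovered at ≥ 95% of
runs' retained support over 500 replicates); they are not the historical
alignments.

# The synthetic locus generator

`generate_locus()` is first-class, tested code, and the package's ground
truth. It emulates:

* clusters of 2–7 genes on both strands, one output contig per cluster;
* genes built from one ancestral template: promoter with TATA at a fixed
  offset, initiator spanning the +1 A, 146–149 nt 5'UTR, 51/54 nt exon 1,
  typed intron (340–420 nt), exon 2 assembled from the element consensus
  under a catalogue pattern mask with a key-element subtype, stop class
  realized in the terminal element, and one or two polyA signals
  (both present in ~76% of genes);
* GA and GAT STRs flanking each gene, multi-kb GA islands (2.5–4.5 kb) at
  cluster edges;
* per-pattern divergence (~8%) of promoter, 5'UTR and 3' tail — flanking
  regions of different element patterns are substantially diverged in this
  family while same-pattern copies stay nearly identical;
* ~1% SNP divergence per gene against the template and ~0.5% between
  duplicated/allelic copies, with indels in intergenic filler and intron
  interiors;
* the event grammar: tandem duplication (the copied span includes the
  flanking STRs and intergenic filler, so duplication edges fall at GA
  STRs), ectopic insertion, inversion, element deletion — applied in order
  and logged; `perturb_alleles()` derives a second haplotype with
  programmed island-length deltas and gene presence/absence.

Deliberate idealizations, hence what passing tests do *not* show about real
data: substitutions avoid the conserved motif grammar (TATA, initiator,
start/stop, splice sites, polyA signals) — emulating the observed
conservation of these motifs across all family members, but meaning the
annotator is never tested against a degenerate promoter; the splice
neighborhood is kept locally unambiguous (no decoy GT at the alternative
exon-1 offset, no decoy in-frame AG in the last 90 nt of the intron);
intergenic filler is i.i.d. uniform DNA at 40% GC, scrubbed of accidental
promoter grammar, with none of the repeat landscape of a real genome; and
coding indels do not occur, so all same-pattern coding pairs stay
length-matched. Real contigs will violate several of these at once, which
is why the accession regression against the published BAC records exists as
a separate check (it requires the user to supply the GenBank flat files
locally; nothing is downloaded).

Identical `(spec, seed)` pairs generate byte-identical output; all
randomness flows from the single seed, and the generator restores the
caller's RNG state.

# Problem sizes and determinism

The validation suite runs at desk scale: 100 seeded loci (one gene unit
plus its tandem duplication, ~19 kb each) for exact gene-model and
duplication recovery; 100 two-gene loci at zero SNP rate for exact
element-mask recovery; 1,000 random 5-kb sequences against the
exhaustive-window STR oracle; all sense-codon pairs (≤ 3 differences)
against the pathway-enumeration oracle; 30 random additive matrices of 4–6
taxa; and 500 bootstrap replicates on the shipped 800-column
flanking-region alignment. These sizes were chosen to make every check
exhaustive or near-exhaustive at its scale while the whole suite completes
in a few minutes. All stochastic steps are seeded; reruns are
byte-identical.

# Known limitations

* The GenBank reader handles the LOCUS/ACCESSION/ORIGIN flat-file subset
  only — enough for locally saved records; rich feature parsing is not
  attempted.
* Copy counts for tandem arrays of more than two units are reported per
  offset cluster rather than as one array.
* The 3'UTR length convention (polyA offset + 16 nt) is an approximation;
  transcript evidence is needed for exact UTR ends.
* Element decomposition assumes exon 2 starts at element 1 and ends in the
  terminal element; schemes violating that need new fixtures.
* The e-value is an ungapped approximation; thresholds are comparable
  within this package, not across tools.
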