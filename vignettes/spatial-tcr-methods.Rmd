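---
title: "Methods: spot-resolved TCR clonotype mapping and its statistics"
author: "spotTCR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot-resolved TCR clonotype mapping and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotTCR)
```

## The problem

Spatial gene-expression platforms capture polyadenylated transcripts on a
hexagonal lattice of barcoded spots, but standard libraries sample the T cell
receptor (TCR) locus too sparsely to recover clonotypes. A targeted
re-amplification of the spatial cDNA with pooled TRBV forward primers yields a
second library in which read 1 still carries the spot barcode and unique
molecular identifier (UMI) while read 2 covers the rearranged
V(D)J junction. spotTCR turns such paired reads into a clone-by-spot UMI
matrix, links the spatial clones to single-cell-defined phenotypes, and
computes the repertoire and localization statistics used to ask where
phenotypically distinct T cell clones sit relative to the tumor parenchyma.

## Clonotype identity

Two records belong to the same TCR&beta; clonotype when they share the TRBV
gene *family*, the TRBJ gene *family*, and the CDR3 amino-acid sequence.
Family-level identity (the segment name truncated at the first hyphen, after
stripping the `*NN` allele suffix; the first gene of a multi-gene annotation
such as `TRBV20-1/TRBV20OR9-2`) makes clone keys comparable across platforms
that disagree on subfamily-level gene calls: bulk immunoSEQ-style tables
often report only families, while single-cell contig annotations report
full gene names. CDR3 sequences containing a stop (`*`) or frameshift (`_`)
mark non-productive rearrangements and are rejected from clonotype
construction: phenotyped, cytokine-secreting cells carry productive
receptors, and non-productive chains would otherwise create artifactual
singleton clones.

Cells with a determined TCR&alpha; but undetermined TCR&beta; are rescued:
such a cell is assigned to clone K if and only if every other cell carrying
that &alpha; chain and having a determined &beta; maps to K (and at least one
such cell exists). Two deliberate strictness choices, made where the rule's
resolution was open:

* &alpha; identity for rescue is the exact (V gene, J gene, CDR3 nucleotide)
  triple — stricter than the family-level &beta; clone identity — so that a
  shared &alpha; family never causes a false rescue.
* only directly observed &beta; chains provide rescue evidence; rescued cells
  do not themselves vouch for further cells. This makes the operation
  idempotent and order-independent, at the cost of forgoing transitive
  rescues (which would depend on iteration order and compound any error).

## From reads to the clone-by-spot matrix

Read 1 is split positionally into a 16-nt spot barcode and a 12-nt UMI (the
platform's v1 layout; both lengths are parameters). Observed barcodes are
corrected against the slide's whitelist: an exact member maps to itself,
otherwise a barcode with exactly one whitelist entry at Hamming distance 1
maps to that entry, and everything else — including ties and `N`-containing
sequences beyond one mismatch — is discarded as unassignable. One
substitution without quality weighting mirrors the platform's standard
demultiplexing practice; because real whitelists are sparse in sequence
space, one-mismatch neighborhoods essentially never collide (and the
synthetic whitelists enforce pairwise distance &ge; 3, which makes them
provably disjoint).

Clone assignment of read 2 comes from either (a) an external caller's
per-clone supporting-read export, the route used with production callers, or
(b) the built-in lite caller (below). Each read with a clone and a corrected
barcode contributes the triple (clone, spot, UMI); the UMI count of a
(clone, spot) cell is the number of *distinct* UMI sequences, so PCR
duplicates collapse. No UMI error network is built beyond exact string
identity: the targeted library is shallow per molecule and the conservative
reading avoids merging genuine molecules; UMI-level substitution errors
inflate counts by at most the per-base error rate times UMI length. Reads
mapping to out-of-tissue spots are retained in the matrix but flagged, and
all downstream statistics use in-tissue spots only.

## The lite caller

The built-in caller exists so the pipeline is testable end-to-end without an
external dependency; it is deliberately minimal, not a re-implementation of
a production aligner. It seeds on shared 12-mers, extends ungapped (match
+1, mismatch −1, best contiguous segment per diagonal), takes the
best-scoring V and J per read (ties broken lexicographically for
determinism), and extracts the CDR3 from the conserved V cysteine codon to
the J FGxG phenylalanine codon inclusive — the convention of common callers,
so clone keys are comparable across sources. Annotations whose CDR3 span is
out of frame, contains a stop, or whose anchors fall outside the read are
dropped and counted. There is no indel handling, no D-segment calling, and
no quality-aware consensus; the bundled toy reference (6 V, 4 J synthetic
segments with valid anchors, no shared 12-mer) is a labelled synthetic
stand-in, not IMGT germline.

## Repertoire statistics

Diversity is the Shannon index \(H = -\sum_i p_i \ln p_i\) (natural
logarithm). Overlap between two count vectors is the Morisita-Horn index

\[ MH = \frac{2 \sum_i x_i y_i}{(d_x + d_y)\, X\, Y}, \qquad
   d_x = \sum_i x_i^2 / X^2, \; X = \sum_i x_i, \]

taken over the union of clones; it is abundance-weighted, lies in [0, 1],
and equals 1 exactly when the two frequency vectors coincide. Clone-rank
cumulative tables sort by descending count with lexicographic tie-breaking
so reruns are reproducible.

Microbe-specific (bystander) clones are identified from IFN-&gamma; capture
after CEFX peptide stimulation: a clone is called specific if it appears at
least twice in the IFN-&gamma;<sup>+</sup> sorted repertoire and its
frequency there is at least 5-fold its frequency among
IFN-&gamma;<sup>−</sup> cells. A clone absent from the negative sort has
zero negative frequency and passes the ratio clause whenever the count
clause holds — any finite frequency is &ge; 5 &times; 0. Known-specificity
lookup against a VDJdb-style table is deliberately stricter than clonotype
identity: all six fields (CDR3&alpha;, CDR3&beta;, TRAV, TRAJ, TRBV, TRBJ)
must match exactly at gene level, and cells lacking either chain match
nothing.

## Phenotype classification and spatial statistics

Single-cell metaclusters A (terminally differentiated), B and C
(progenitor-/memory-like), and D (dividing) drive clone-level calls: a clone
is an A/D clone if its cells in A+D strictly outnumber those in B+C, a B/C
clone on the reverse strict inequality; ties with at least one counted cell
are ambiguous and excluded from two-group contrasts (reported in tables);
naive and unassigned cells never vote.

Spot centers are placed from array coordinates on the hexagonal lattice with
a configurable center-to-center pitch (default 100 µm, the platform's
spacing), so distances are Euclidean in micrometers. The distance of a spot
to the "tumor border" is its distance to the nearest tumor-labeled spot
(tumor spots are at 0); no polygon is fit, which keeps the definition
assumption-free at the cost of a half-pitch granularity. A clone's tumor
fraction is the percentage of its in-tissue UMIs on tumor-parenchyma spots.
Region labels other than tumor (stroma, inflammation, necrosis, brain) all
count as non-tumor for fractions and distances, while region-resolved UMI
tables keep the full labels. A group-level tumor share for the most expanded
clones can be defined either by pooling UMIs across the group's clones or as
the median per-clone fraction; the two differ whenever clone sizes are
skewed, so `run_stats()` reports both summaries.

Group contrasts use the Mann-Whitney U test on per-clone tumor fractions
(\(U = \sum_{i,j} [x_i > y_j] + \frac12 [x_i = y_j]\), two-sided
tie-corrected normal approximation, no continuity correction) and the
two-sample Kolmogorov-Smirnov test on UMI-expanded border distances.
The KS p-value is exact (conditional on the pooled sample, hence valid under
ties) when both expanded sizes are at most 25 and asymptotic with effective
size \(nm/(n+m)\) otherwise; the UMI expansion treats each captured molecule
as one observation, which overstates independence when several UMIs share a
spot — a caveat shared by any UMI-level test. Genes below 10 total counts or
expressed in two or fewer spots are below the detection limit and filtered
(`filter_detected_genes()`, i.e. kept iff total &ge; 10 and spots &ge; 3).

## The synthetic-data generator

The generator is first-class, tested code: it produces a hexagonal grid with
a contiguous central tumor disc (default 30 &times; 30 spots, 700 µm radius,
all in tissue), a Zipf-distributed clone repertoire (exponent 1 by default,
matching the long-tailed clone-size spectra of expanded repertoires) built
on the toy segment reference, phenotype labels drawn per clone, and
phenotype-dependent UMI placement with tumor probabilities 0.8 (A/D) and 0.2
(B/C) by default — a strong but realistic spatial segregation for expanded
clones. Reads are emitted at 3 reads per UMI with configurable per-base
substitution rates on barcode, UMI and insert; read 2 windows start at a
random position among the first 15 V-segment bases, emulating a pool of
staggered forward primers, and default to 150 nt so both CDR3 anchors are
always covered. Whitelist barcodes are rejection-sampled to pairwise
Hamming distance &ge; 3.

What the simulation does *not* emulate: indels and quality-correlated
errors (the lite caller is ungapped by design), transcriptome background
reads, variable per-spot cell density, doublets, segment-specific primer
efficiencies, and real germline sequence similarity between V families.
Passing round-trip tests therefore demonstrates the correctness of the
bookkeeping — demultiplexing, correction, deduplication, linkage and the
statistics — on reads whose generative model matches the caller's
assumptions; it does not certify performance on real libraries, where an
external production caller is the intended route.

## Validation summary

The test suite checks, among others: exact recovery of the planted
clone-by-spot matrix from an error-free 100k-read simulation (50 clones,
30 &times; 30 grid); that with 1%-per-base barcode errors and a
distance-&ge;3 whitelist no read is ever assigned to a wrong spot while
&ge; 95% of reads with at most one barcode error are assigned; agreement of
Shannon, Morisita-Horn, specificity filtering, border distances and U
statistics with independent brute-force oracles on 1000 random instances
each; empirical type-I error of both tests within [3%, 7%] at nominal 5%
over 1000 null simulations (20 observations per group); and &ge; 95% power
at &alpha; = 0.01 over 200 replicates for the planted 0.8 vs 0.2
localization effect with 20 clones per group and 30 UMIs per clone. These
problem sizes keep the full suite inside a few minutes on one CPU while
leaving the binomial and multinomial noise realistic.
`scripts/acceptance.R` recomputes the same quantities from scratch.

## Known limitations

* Clonotype identity ignores the CDR3 nucleotide sequence, so convergent
  rearrangements with identical amino acids merge — intended, as it matches
  the cross-platform linkage rule, but a caveat for clone-size estimates.
* The &alpha;-rescue rule cannot recover cells whose &alpha; partner is
  itself unobserved elsewhere, and refuses all ambiguous evidence.
* The distance statistic inherits the spot pitch as its resolution floor;
  sub-spot localization is out of scope.
* The lite caller is not suitable for real reads with indels or heavy
  error; use an external caller's export for production data.
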