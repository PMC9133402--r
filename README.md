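# spotTCR

Spot-resolved T cell receptor (TCR) clonotype mapping for spatial
transcriptomics, with the repertoire and localization statistics needed to
link clone *phenotype* to clone *position* in the tumor microenvironment.

Standard spatial gene-expression libraries almost never sample the rearranged
TCR locus deeply enough to call clonotypes. After a targeted re-amplification
of the spatial cDNA with pooled TRBV forward primers, read 1 of the resulting
library still carries the capture-spot barcode and UMI while read 2 covers
the V(D)J junction. spotTCR is for immunologists and computational biologists
who have such paired reads (plus the companion single-cell, bulk TCR&beta;
and tissue-annotation tables) and want to know, for example, whether
terminally differentiated T cell clones concentrate in the tumor parenchyma
while memory-like clones remain in the surrounding stroma.

## What it computes

* **Spot demultiplexing and UMI deduplication** — read 1 is split into a
  16-nt spot barcode and 12-nt UMI; barcodes are whitelist-corrected
  (exact, else unique Hamming-distance-1 neighbor, else discarded); the
  clone &times; spot matrix counts *distinct* UMIs per cell, collapsing PCR
  duplicates. Clone labels per read come from an external caller's
  supporting-read export or from the built-in lite V/J caller with CDR3
  extraction (conserved Cys → FGxG Phe).
* **Clonotype identity** — TRBV family + TRBJ family + CDR3&beta; amino
  acids; records with identical families and CDR3 are the same clone.
  Cells with only a TCR&alpha; are rescued when every other cell carrying
  that &alpha; pairs with a single &beta; clone.
* **Repertoire statistics** — Shannon diversity
  `H = -Σ p_i ln p_i`; Morisita-Horn overlap
  `MH = 2 Σ x_i y_i / ((d_x + d_y) X Y)` with `d_x = Σ x_i² / X²`;
  clone-rank cumulative frequency tables.
* **Bystander specificity** — a clone is CEFX-specific (microbe-reactive)
  iff it occurs ≥ 2 times in the IFN-&gamma;⁺ sorted repertoire with
  frequency ≥ 5&times; its IFN-&gamma;⁻ frequency; plus exact paired-chain
  lookup against VDJdb-style tables.
* **Spatial statistics** — per-clone tumor-parenchyma UMI fractions,
  distance-to-tumor-border ECDFs, Mann-Whitney U on per-clone fractions,
  two-sample Kolmogorov-Smirnov on UMI-expanded distances, the ≥ 10-count /
  ≥ 3-spot gene detection filter, and expanded-clone localization tables.
* **Synthetic data** — a generator that plants a tumor disc on a hexagonal
  spot lattice, a Zipf repertoire with phenotype-dependent placement, and
  barcoded FASTQ reads with configurable substitution errors and full
  ground truth, so the entire pipeline is testable without any download.

## Worked example

```r
library(spotTCR)

sim <- simulate_spatial_dataset("demo", seed = 42, n_rows = 20, n_cols = 20,
                                tumor_radius_um = 500, n_clones = 25,
                                total_umis = 1500, reads_per_umi = 3)
mat <- run_extract(sim$paths$r1, sim$paths$whitelist,
                   r2 = sim$paths$r2, refs = toy_segment_reference())
#> spatial clone matrix: 25 clones x 381 spots, 1500 UMIs (4500/4500 reads assigned)

phen <- run_link(mat, sim$cells)       # AD: 9 clones, BC: 16 clones
st   <- run_stats(mat, phen, sim$grid, top_n = 10)
round(st$pooled_tumor_share, 1)
#>   AD   BC
#> 81.7 20.0
head(st$expanded, 3)
#>   rank                    clone_id call total_umis tumor_fraction
#> 1    1    TRBV20_TRBJ1_CPCYCMQDVYF   BC        416       18.02885
#> 2    2 TRBV19_TRBJ2_CFSMYNSGQWDMEF   BC        185       20.00000
#> 3    3 TRBV28_TRBJ1_CFRFIGTKRTFRMF   BC        116       21.55172
st$mann_whitney[c("U", "p_value")]
#> U = 144, p = 4.6e-05
```

The simulation planted tumor probabilities 0.8 for A/D clones and 0.2 for
B/C clones: the recovered pooled tumor shares (81.7% vs 20.0%) and the
Mann-Whitney contrast on per-clone fractions reflect exactly that effect.
The KS test on border distances is null here (D = 0.066, p = 0.93) because
the generator places out-of-tumor UMIs uniformly in the stroma for both
phenotypes — distance gradients are not part of its model.

Repertoire-side operations work the same way on the companion tables:

```r
spec <- cefx_specific_clones(sim$cefx$pos, sim$cefx$neg)
length(spec)                 # 5 of 5 planted specific clones recovered
shannon_index(aggregate_repertoire(sim$clones$clone_id,
                                   pmax(sim$clones$n_umis, 1)))
#> 2.663
```

A thin command-line wrapper with `simulate | extract | link | stats |
repertoire` subcommands ships in `inst/scripts/spottcr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/spottcr.R", package="spotTCR"))')" \
    simulate --out-dir demo --seed 5
```

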