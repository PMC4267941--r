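# dielcycle

Detection and regulatory analysis of diel (day/night) cyclic gene
expression in short, evenly sampled transcriptome time courses.

Under a 12-h light : 12-h dark cycle, a large fraction of a
photosynthetic organism's transcriptome oscillates with a ~24-h period.
`dielcycle` is for researchers who have a gene × timepoint expression
matrix (FPKM-like values; the reference design is 8 Zeitgeber-time points
at 3-h intervals with two replicate days appended, 16 samples) and want
to call cycling genes with a calibrated error rate, describe and group
them, and dissect the functional, evolutionary and cis-regulatory
structure of the cycling transcriptome.

## What it computes

**Cyclic score.** For each gene, day-length segments of the expression
vector are mean-centred and Fourier-transformed,
`y_k = Σ_n x_n e^{-i2πkn/M}`; squared-magnitude spectra over the nonzero
frequencies are min–max normalized to [0, 1]
(`y* = (y − y_min)/(y_max − y_min)`) and averaged across segments
(Welch-style, untapered). The score is the averaged value at the
one-cycle-per-day component: a clean daily cosine scores exactly 1.
Significance comes from a permutation null (shuffled expression vectors);
the cycling threshold is the score attained by the top 2% of null scores
(an empirical *P* of 0.02). Period, amplitude and phase are estimated
from the full-length spectrum, with quadratic log-power interpolation
giving continuous periods.

**Downstream analyses.** Phase clusters (peak ZT) subdivided by
two-round k-means into 10–90-gene expression clusters; Fisher-exact +
Benjamini–Hochberg term enrichment per phase with circular-adjacency
summaries; a three-state difference-equation model of duplicate-pair
divergence (`f_CC' = f_CC(1−d) + αs f_D`, etc.) with closed-form rate
fitting and steady state `f_D* = d/(d+s)`; random-pairing significance
tests for state and phase retention; chi-square co-cycling and
amplitude/phase correlation for ortholog pairs; promoter extraction from
FASTA + GFF3, exact-p-value PWM scanning, UPGMA motif merging, and naive
plus linear max-margin (SVM) phase classifiers with 10-fold
cross-validated AUC-ROC.

A synthetic-data generator reproduces the study design with known ground
truth (cycling fraction, amplitude = half the mean, bimodal dawn/dusk
phase distribution, lognormal noise), so the whole pipeline is testable
without external data.

## Worked example

```r
library(dielcycle)
lay <- sampling_layout()                     # 3-h sampling, 2 x 24 h
sim <- generate_expression(n_cycling = 300, n_flat = 700, seed = 1)
det <- detect_cycling(sim$expression, lay, top_pct = 2,
                      n_permutations = 5000, seed = 2)
```

This prints (via the summaries below) a permutation threshold of 0.978,
calls 311 of 1000 genes cycling — all 300 planted cyclers (sensitivity
1.000) plus 11 false positives (FPR 0.016, near the nominal 0.02) — and
fits a mean period of 23.94 h:

```
  gene_id score      p period amplitude phase phase_cluster
1   g0001     1 0.0144   25.4      2.83  13.1            12
2   g0002     1 0.0144   25.9      6.16  15.5            15
3   g0003     1 0.0144   25.0      2.17  15.1            18
```

Each row is a called gene: its score (confident cyclers saturate at 1),
smoothed empirical p, fitted period (h), amplitude (expression units),
continuous peak phase and ZT phase cluster. The divergence model at the
fitted rates d = 0.42, s = 0.53 gives the long-run state frequencies

```r
steady_state(divergence_model(d = 0.42, s = 0.53))
#>     CC     NN      D
#> 0.2789 0.2789 0.4421
```

i.e. an asymptotic diverged-duplicate fraction of ≈0.44.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that chain the
package into the full study workflow on synthetic data, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R            # data with known truth
Rscript analysis/02_detect_rhythms.R      # scores, threshold, fits
Rscript analysis/03_cluster_and_enrich.R  # subclusters, term enrichment
Rscript analysis/04_duplicate_divergence.R
Rscript analysis/05_ortholog_comparison.R
Rscript analysis/06_motif_phase_prediction.R
```

See `vignettes/diel-methods.Rmd` for the model, parameter and design
rationale.

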