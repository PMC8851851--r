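# contactnorm

Nontransformed cells can suppress the growth and phenotype of adjacent
transformed cells through direct cell–cell junctions, a process called
**contact normalization**. `contactnorm` implements the transcriptome
analysis used to dissect this process in a four-group layered coculture
design, where Src-transformed cells are grown over themselves, over
cadherin-competent nontransformed cells, or over cadherin-knockout cells,
and nontransformed cells over themselves:

| group     | culture                                              |
|-----------|------------------------------------------------------|
| `N_self`  | nontransformed cells over nontransformed cells       |
| `T_self`  | Src-transformed cells over Src-transformed cells     |
| `T_vs_N`  | transformed cells over cadherin-competent cells      |
| `T_vs_KO` | transformed cells over cadherin-knockout cells       |

The package is aimed at analysts working with bulk RNA-seq from such
coculture designs, and at methodologists who want a planted-truth benchmark
for threshold-based classification cascades.

## The classification cascade

Counts are converted to transcripts per million,

TPM(g, s) = 10^6 · (c(g,s)/ℓ(g)) / Σ<sub>g′</sub> (c(g′,s)/ℓ(g′)),

and genes are filtered at mean TPM ≥ 1 in at least one group. Expressed
genes then pass through three nested fold-change/t-test stages, each using
the pooled-variance two-sample Student t-test on replicate TPMs
(df = n₁ + n₂ − 2) and pseudocount-stabilized ratios
FC = (m₁ + 1)/(m₂ + 1):

1. **Src effect** — `T_self` vs `N_self`: FC ≥ 3 (or ≤ 1/3), p < 0.05.
2. **Contact reversal** — `T_vs_N` vs `T_self`: relative change
   (m<sub>T_vs_N</sub> − m<sub>T_self</sub>)/(m<sub>T_self</sub> + 1)
   opposite in sign to the Src effect, |change| ≥ 0.40, p < 0.08.
3. **Cadherin dependence** — `T_vs_KO` vs `T_vs_N`: FC ≥ 2 back toward the
   transformed-self direction, p < 0.05.

Every gene lands in exactly one "onion layer": `not_expressed`,
`expressed_unaffected`, `src_only`, `cn_cadherin_independent`, or
`cn_cadherin_dependent`. A gamma–Poisson simulator (`simulate_study()`)
plants these classes with configurable effect sizes and dispersion and
carries the ground truth, so stage-wise sensitivity and specificity can be
measured with `evaluate_recovery()`. Companion helpers cover
cellular-location summaries and score-thresholded interaction-network
neighborhoods of classified genes, and percent-of-control statistics for
growth and densitometry assays.

## Worked example

```r
library(contactnorm)

sim <- simulate_study(n_genes = 1000, dispersion = 0.01, seed = 42)
res <- run_cascade(sim$counts, sim$design)
res
#> <cn_cascade>
#>   1000 genes detected, 900 expressed (TPM >= 1)
#>   Src-affected: 120 (60 up, 60 down)
#>   contact-reversed: 80 (40 induced, 40 suppressed by contact)
#>   cadherin-dependent: 40 (20 induced, 20 suppressed)
```

One thousand simulated genes were detected, 900 of them expressed above the
TPM ≥ 1 filter (the other 100 are planted silent genes). Src transformation
altered 120 genes at the ≥3-fold, p < 0.05 cut-off; coculture with
cadherin-competent cells inversely changed 80 of them by ≥40% (p < 0.08);
and 40 of those lost their normalization over knockout cells by ≥2-fold
(p < 0.05), i.e. they depend on cadherin-mediated contact. `tidy(res)`
returns the per-gene table, `glance(res)` the layer counts, and
`autoplot(res)` the onion bar chart. Scoring against the planted truth:

```r
tidy(evaluate_recovery(sim$truth, res))
#> # A tibble: 4 × 7
#>   stage         tp    fp    tn    fn sensitivity specificity
#> 1 expression   900     0   100     0           1           1
#> 2 src_effect   120     0   880     0           1           1
#> 3 reversal      80     0   920     0           1           1
#> 4 cadherin      40     0   960     0           1           1
```

At these planted margins (8× Src effect, 60% reversal, 4× cadherin
differential, dispersion 0.01) every stage recovers its planted set
perfectly. Assay statistics follow the same conventions:

```r
percent_of_control(c(12, 9, 11, 10), c(200, 210, 190, 200))
#> # A tibble: 1 × 5
#>   percent_mean percent_sem       p.value n_treated n_control
#> 1         5.25       0.323 0.00000000721         4         4
```

i.e. growth at 5.25% ± 0.32% of control — the >90% suppression typical of
contact-normalized transformed cells.

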