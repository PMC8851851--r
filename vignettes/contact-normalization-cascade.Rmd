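---
title: "Classifying contact-normalized transcriptomes: model, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying contact-normalized transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactnorm)
```

## The biological question and the design

Transformed cells growing in contact with nontransformed neighbors are
often "contact normalized": their growth and much of their transcriptional
program is pulled back toward normal. The layered-culture design separates
this into four groups — nontransformed self-culture (`N_self`),
Src-transformed self-culture (`T_self`), transformed cells cocultured over
cadherin-competent nontransformed cells (`T_vs_N`), and over
cadherin-knockout cells (`T_vs_KO`) — each with three biological
replicates. Comparing along this chain answers three nested questions per
gene: did Src change it, did contact reverse that change, and did the
reversal require cadherin junctions?

## The cascade and its thresholds

All statistics run on TPM. The cascade is deliberately threshold-based
(fold change plus Student's t-test) rather than a shrinkage-based
differential-expression model: the analysis it implements is a printed
decision rule, and the package's job is to apply that rule exactly and
transparently. The thresholds live in `cascade_config()`:

| parameter           | default | unit/meaning                               |
|---------------------|---------|--------------------------------------------|
| `min_tpm`           | 1       | inclusive expression filter, group mean TPM |
| `src_fold`          | 3       | minimum Src fold change (inclusive)         |
| `src_alpha`         | 0.05    | Src-stage p cut-off (strict)                |
| `reversal_fraction` | 0.40    | minimum inverse change vs `T_self`          |
| `reversal_alpha`    | 0.08    | reversal-stage p cut-off                    |
| `cdh_fold`          | 2       | minimum cadherin differential (inclusive)   |
| `cdh_alpha`         | 0.05    | cadherin-stage p cut-off                    |
| `pseudocount`       | 1 TPM   | additive stabilizer in every ratio          |

The reversal stage's 0.08 is not a typo for 0.05: it is the stated cut-off
for that stage and is kept verbatim as the default. All fold and percent
boundaries are inclusive, matching the "at least" phrasing of the rule;
p-value comparisons are strict. The t-test is the classical pooled-variance
(equal-variance) two-sample test — "Student's" is read as naming that
test — computed on raw TPM replicates by default. No multiple-testing
correction is applied by default because the rule is stated in raw
per-gene p-values; `p_adjust = "BH"` enables within-stage
Benjamini–Hochberg adjustment for users who want it.

Several points the rule leaves open are settled here as package decisions,
each behind a switch:

* **Fold-change definition.** The ratio of group means with pseudocount 1
  TPM in numerator and denominator. One TPM matches the expression-filter
  scale, and the pseudocount bounds ratios of near-zero genes (a gene at
  10 vs 0 TPM reports 11, not infinity).
* **"Expressed in any sample group"** is read as *group mean* ≥ 1 TPM in at
  least one group, since the group is the unit of every comparison in the
  cascade; `filter_scope = "any_sample"` selects the single-sample reading.
* **"Inversely affected by at least 40%"** is implemented as a change of at
  least 40% *of the transformed-self level*, opposite in sign to the Src
  effect (`reversal_mode = "inverse_change"`). The plausible alternative —
  recovering at least 40% of the displacement back toward the normal-self
  baseline — is available as `reversal_mode = "restoration"`.
* **Cadherin dependence requires direction consistency**: the knockout
  coculture must move the gene *back toward* its transformed-self level
  (fold ≥ 2 for Src-up genes, ≤ 1/2 for Src-down genes). A two-fold
  differential in the inconsistent direction is not a loss of
  normalization and classifies as independent. This aligns the
  dependent-gene directions with the original Src directions.
* **The dependence test is applied to all reversed genes** (both the
  contact-suppressed and contact-induced sides), the natural reading of
  the nested design.
* **Zero pooled variance** (reachable only on noise-free synthetic data):
  equal means give t = 0, p = 1; unequal means give p = 0 with a warning.
* **Ties at thresholds are inclusive** throughout.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws counts from a gamma–Poisson (negative-binomial)
model: for gene $g$ in sample $s$ of group $G$,
$\lambda \sim \mathrm{Gamma}(1/\phi_g,\; 1/(\phi_g \mu_{gG s}))$ and
$c_{gs} \sim \mathrm{Poisson}(\lambda)$, so the variance is
$\mu + \phi\mu^2$ with a per-gene dispersion $\phi$ shared across groups.
This is the simplest standard RNA-seq noise model with an overdispersion
control; the underlying experiment published no distributional description
of its data, so the NB model is a stand-in chosen for familiarity, not a
fitted model. Per-sample library sizes are jittered ±10% and gene lengths
drawn uniformly from 500–5000 bases (unless supplied) so that TPM's
per-sample and per-length normalizations are genuinely exercised. One root
seed governs everything; per-gene substreams are derived by a deterministic
hash, so extending a specification leaves earlier genes' draws unchanged.

Planted group means follow the class structure: `N_self` at `base_mean`;
`T_self` multiplied (or divided) by `src_fold`; `T_vs_N` moved by
`reversal_fraction` of the transformed-self level in the opposite
direction (for `*_down` classes, an increase of `1 + reversal_fraction`);
`T_vs_KO` equal to `T_vs_N` except for dependent classes, where it moves
back by `cdh_fold`.

**Compositionality.** TPM renormalizes every sample to one million, so
planted means are relative: the generator rescales all of them by one
common factor that makes the `N_self` profile sum to $10^6$. A common
factor preserves every cross-group fold change exactly; what it cannot
remove is the attenuation of realized fold changes by the ratio of group
profile sums (if Src up-regulation adds 30% to the transformed profile
sum, an 8-fold planted effect realizes as ≈ 6-fold). `simulate_study()`
therefore keeps the affected fraction modest (12% of genes) and balanced
between up and down classes, which keeps the attenuation within ~25% even
at 8-fold effects. Real data have the same compositional property; the
cascade's thresholds are defined on the realized TPM scale in both cases.

`simulate_study()` encodes the study conditions: 4 groups × 3 replicates,
a lognormal baseline abundance (meanlog = log 50, sdlog = 1), and a default
depth of 3×10⁷ reads per sample — the depth of a paired-end HiSeq lane
shared by twelve libraries. Depth matters more than it may seem: at
~10⁶ reads the low-abundance tail of Src-*down* genes (divided by 8, and
divided again in dependent knockout cocultures) collapses onto a count
floor of a handful of reads, where n = 3 t-tests are powerless no matter
how small the dispersion. Silent (`not_expressed`) genes are planted at
0.001 TPM rather than just below 1: at realistic depth one read converts
to roughly one TPM for an average-length gene (and several TPM for a short
one), so Poisson shot noise around any larger "silent" level would leak
genes across the inclusive TPM ≥ 1 filter; truly silent genes produce
(next to) no reads at all.

The simulator does **not** emulate batch effects, isoform structure,
length biases beyond the TPM definition, correlated genes, UMI counting,
or spatial structure within the membrane. Passing recovery tests on this
generator therefore demonstrates that the cascade implements its decision
rule correctly under its own statistical assumptions — not that the rule
is optimal, or that real data meet those assumptions.

## Recovery benchmarking

`evaluate_recovery()` compares predicted onion layers with the layers a
perfect classifier would assign to the planted classes. Per stage
(expression filter, Src effect, reversal, cadherin dependence) it reports
sensitivity and specificity with truth-positives defined by the planted
class and prediction-positives by layer membership at or inside the
corresponding layer. The test suite and `scripts/acceptance.R` run a
1000-gene benchmark (100 silent, 780 unaffected, 20 genes in each of the
six affected classes) with effects at twice every threshold — 8× Src, 60%
reversal, 4× cadherin — at dispersion 0.01, where every stage is required
to reach sensitivity and specificity ≥ 0.95, and a near-noiseless variant
(dispersion 10⁻⁴) required to label every gene correctly. These problem
sizes keep a full run in seconds while leaving dozens of genes per class,
enough for stable stage-wise rates.

## Numerical and degenerate-input choices

* TPM requires at least one nonzero count per sample; an all-zero sample
  is rejected rather than silently dropped.
* `fold_change(0, 0, 0)` is undefined and rejected; with the default
  pseudocount it is 1.
* A design missing one of the four groups, or with fewer than two
  replicates in any group, is rejected before any statistics run.
* Degenerate thresholds are legal: `reversal_alpha = 0` yields zero
  reversed genes and the nesting invariants still hold.
* Counts may be non-integer (upstream estimated counts); only
  non-negativity is enforced. One row is one transcript/gene as supplied —
  no isoform collapsing or effective-length correction is attempted, and
  whether rows are genes or transcripts is the caller's contract.

## Annotation and network summaries

Cellular-location categories are assigned from a user-supplied flat table
(no live ontology or interaction-database queries, keeping runs
reproducible and network-free): noncoding genes are `noncoding_rna`
regardless of location; coding genes take the first match in the
precedence extracellular > plasma membrane > cytoplasm > nucleus. The
precedence is a package decision — multi-location genes have no canonical
bin — chosen to favor the compartments most relevant to intercellular
communication. Interaction neighborhoods use the conventional confidence
tiers 0.400 / 0.700 / 0.900 exposed as presets `medium` / `high` /
`highest`.

## Known limitations

* The cascade inherits the statistical fragility of n = 3 t-tests at raw
  thresholds; it classifies, it does not estimate effect sizes with
  uncertainty. For inference beyond the printed rule, a count-based model
  (e.g. a negative-binomial GLM) is the right tool.
* Compositional attenuation means realized and planted fold changes differ
  when a large expression mass shifts between groups; interpret recovered
  folds on the TPM scale.
* The assay helpers implement the downstream arithmetic
  (percent-of-control, SEM as sd/√n, loading-normalized densitometry,
  fold ratios of means) on user-supplied measurement tables; image
  quantification itself is out of scope, as is read alignment and
  quantification upstream of the counts matrix.
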