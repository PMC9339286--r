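---
title: "Predicting TF-perturbation responses: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TF-perturbation responses: models, nulls, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the science implemented by **pertpred**: what is
being predicted, how the features are built, how the models are trained
and calibrated, what the synthetic generator plants (and what it does not
emulate), and where genuinely open design choices were resolved.

## The prediction problem

A TF perturbation experiment perturbs one transcription factor and
profiles expression afterwards; a gene is *responsive* when its change
passes fixed thresholds (adjusted p < 0.05 and |log2 fold-change| > 0.5
for replicated designs; |log2FC| > 0.5 alone when there are no
replicates; any nonzero shrunken fold-change when the input table is
already shrunken toward zero). All thresholds are strict inequalities,
and boundary behavior is pinned by tests. The model predicts, for a
(TF, gene) pair, the probability that the gene responds — using only
features measured *before* the perturbation, so features cannot be
consequences of the response.

Because each prediction must concern a TF the model has never seen,
cross-validation is grouped by TF: with the default 10 folds, each model
trains on instances of 90% of the TFs and is tested on the rest. A
gene-wise assignment variant is not provided; the TF-grouped design is
the one that supports the intended use (predicting responses for an
unperturbed TF).

## Features

**Positional tracks.** The promoter window is tiled with 100-bp bins,
5′→3′ in gene orientation. Relative interval $[a, b)$ maps to genomic
$[\mathrm{tss}+a, \mathrm{tss}+b)$ on the plus strand and
$[\mathrm{tss}-b, \mathrm{tss}-a)$ on the minus strand; windows are
clipped at chromosome ends, and a clipped bin keeps its feature identity
over the reduced span so the matrix stays rectangular. Peaks contribute
their full signal (−log10 q) to the single bin containing their summit
(interval midpoint when no summit is recorded) — anchoring at a point
prevents one peak from multiply counting across bins. Coverage tracks
contribute base-pair-weighted sums, so splitting a record across a bin
boundary conserves total mass. Dinucleotide frequencies are computed per
bin from the promoter sequence (overlapping windows, windows containing
N excluded from numerator and denominator); computing them per bin rather
than per region keeps sequence composition on the same positional footing
as the signal tracks.

**Enhancer features (human scheme).** Gene–enhancer links contribute to
either 32 growing bins per side (widths 1, 2, 3, … kb, measured from the
promoter edge) or two per-side aggregates. Each link is assigned by its
interval midpoint — the one unambiguous anchor when an enhancer straddles
a bin edge. Links whose midpoint lies beyond 500 kb are dropped; the
500-kb reach is enforced as a hard cut even though 32 growing bins would
nominally cover 528 kb, so the outermost bin is truncated. A link whose
midpoint falls inside the promoter window is dropped from the enhancer
features because the promoter bins already cover that territory.

**Expression features.** The level feature is the median log2 expression
across control replicates (log2(x+1) for linear-scale input; the +1
pseudocount is conventional and keeps zero TPM at level zero). The
variation feature is the residual of a LOESS regression (span 0.75,
degree 1 — standard defaults) of the coefficient of variation on the
level. The residualization removes the strong mean–variance dependence:
on simulated data the absolute correlation between level and variation is
below 0.01. Genes with zero mean expression have an undefined CV and are
assigned variation 0 with a warning.

## Models and evaluation

Gradient-boosted trees (binary logistic objective) with conventional
settings for this problem size: 300 rounds, depth 6, learning rate 0.05,
row and column subsampling 0.8, single-threaded for bit-for-bit
reproducibility. A light profile (100 rounds) is used where many
cross-validation sweeps are needed; both profiles are plain
configuration, not tuned values. Class imbalance is left unweighted by
default because evaluation is rank-based.

AUPRC uses the average-precision estimator: instances ranked by
descending score, tied scores entering as one block, no trapezoidal
interpolation (interpolation inflates AUPRC at low prevalence). Two
anchoring properties follow: a perfect ranking scores 1, and an
all-equal-scores ranking scores exactly the prevalence.

## The permutation null and per-TF significance

For each permutation, responsive labels are shuffled within each TF —
preserving that TF's responsive count — and the entire grouped
cross-validation is rerun with unmodified features. The mean permuted
AUPRC per TF sits close to the TF's response fraction, and the log of the
permuted SD is approximately linear in the log response fraction, so a
linear fit (the LSD model) predicts the null SD for any TF; a
conservative variant fits only the highest-SD TF in each quintile of
percent-responsive (right-closed breaks at the 20/40/60/80th
percentiles). The p-value for a TF is the upper tail of a normal null
centered on the analytic expectation (the response fraction) with the
LSD-predicted SD; TFs with fewer than 1% responders use their own
empirical permuted SD instead.

One calibration subtlety is worth knowing. The average-precision
estimator's null mean lies slightly *above* the response fraction — about
+0.003 at 2,000 genes, roughly half a null SD. Centering on the analytic
expectation therefore shifts null p-values by ~0.5σ (anticonservative).
This is immaterial at the 10⁻³ decision threshold used for declaring a TF
significant, but it means null p-values are only approximately uniform
under analytic centering. `tf_pvalue()` accepts an explicit `mu` so the
empirical permuted mean can be used as a diagnostic, exactly calibrated
centering; the test suite verifies uniformity under that centering and
verifies the size of the analytic shift.

## SHAP attributions

Attributions are computed by an exact path-dependent TreeSHAP engine
implemented in C++ in double precision. Per tree, attributions sum to
leaf(x) − E[tree] exactly, so local accuracy — base value plus the sum of
attributions equals the model's margin output — holds to ~10⁻¹⁴ rather
than the ~10⁻⁶ float accumulation error of single-precision contribution
predictors. Split routing casts operands to float32 to replicate the
booster's own comparison semantics. The engine is cross-checked in the
tests against the boosting library's contribution predictor and against a
brute-force exhaustive-Shapley oracle on small trees. Margin (log-odds)
space is the default because additivity is exact there; a probability
option maps the base value through the logistic and rescales each
instance's attributions proportionally.

Aggregations follow the field's conventions: per feature class (TF
binding, each histone mark, accessibility, the 16 dinucleotides pooled,
expression level, expression variation) and per gene group (responsive,
nonresponsive, bound, bound∩responsive, …), the positive and negative
attribution sums, their total (net influence), and the mean |SHAP|
(global importance); per-bin positional profiles over bound genes;
one-sided Wilcoxon rank-sum tests comparing bound-responsive against
bound-nonresponsive genes per bin (exact enumeration when both groups
have ≤ 10 genes, normal approximation with tie correction otherwise); and
upstream vs downstream mean |SHAP| with an across-TF rank-sum comparison.

## What the synthetic generator plants

`simulate_dataset()` emits a complete dataset — TSS table, per-TF
narrowPeak files, per-mark and accessibility bedGraphs, promoter FASTA,
expression TSV, enhancer links, and per-TF DE tables — every file
parseable by the package's own readers. Responsiveness is sampled from

$$\operatorname{logit} P = \beta_0 + \beta_{bind}\,b + \beta_{gex}\,z(\mu)
 + \beta_{var}\,z(\varepsilon) + \beta_{hm}\,z(h),$$

where $b$ is the (signal-scaled) bound indicator, $\mu$ the latent log2
expression level, $\varepsilon$ the level-independent CV noise, and $h$
the latent driving the first histone mark's gene-body coverage.

* `yeastlike`: β_bind dominant (2.2), summits drawn N(−150 bp, 80 bp)
  relative to the TSS so binding information concentrates a few hundred
  bp upstream; β_gex 0.6, β_var 0.45, β_hm 0.25.
* `humanlike`: β_bind = 0 with decoy peaks uniform within ±50 kb, so
  binding is present but carries no information; β_gex 1.1, β_var 0.9,
  β_hm 0.1. The variation weight exceeds its yeast value because the
  feature is observed through a noisy replicate-level CV estimate
  (attenuation), and the histone weight is small so that the expression
  features dominate, which is the condition this preset represents.

β₀ is set so the median per-TF response fraction lands in the 2–7% range
typical of perturbation-response compendia. Histone coverage is written
with a downstream (gene-body) amplitude driven by the informative latent
and an upstream amplitude driven by a weakly related latent (r ≈ 0.3):
a mere downstream *scaling* would be invisible to scale-invariant tree
models, so the asymmetry is planted as an information asymmetry. DE
tables are generated directly from the sampled labels (responsive genes
get |log2FC| > 0.5 with padj < 0.05 and a nonzero shrunken value;
nonresponsive genes fail both), so relabeling from the emitted tables
reproduces the truth exactly — the pipeline consumes labels, not DE
inference, and simulating read counts would test a DE engine rather than
this package. Each TF's own gene is forced responsive with a large
fold-change, providing the perturbation-efficacy covariate.

What the generator does **not** emulate: correlated multi-mark chromatin
states beyond a shared expression correlation, replicate-level batch
structure, peak-calling artifacts, sequence-driven binding (decoys are
positionally random), and realistic enhancer–promoter contact biology
(links are uniform within reach). Passing the planted-recovery tests
therefore shows the pipeline recovers the effects it is pointed at, not
that real chromatin data would behave this way.

## Problem sizes and numerical choices

Simulated studies default to 1,000 genes × 10 TFs × 10 expression
replicates — small enough for a laptop, large enough that per-TF AUPRC
and the permutation null are stable. The null-calibration analysis uses
2,000 genes with 50 permutations on the expression-feature subset with a
light boosting configuration, since null calibration is a property of the
labels and the estimator, not of model capacity. Planted-recovery runs
use the 100-round profile. Degenerate inputs are handled explicitly:
empty peak files map to all-zero features; an all-N or too-short sequence
yields zero dinucleotide features with a warning; a training fold with no
positive instances is an error rather than a silent degenerate model; an
AUPRC without both classes is an error; a zero null SD is an error.

## Known limitations

Only binary response labels are modeled (no effect sizes or directions);
probability-space SHAP uses a proportional rescaling rather than
interventional expectations; the conservative LSD variant needs at least
two populated quintiles; and the CLI wrapper is a thin convenience over
`run_pipeline()` rather than a workflow engine.
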