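---
title: "Methods: CpG-island-centered analysis of enrichment-captured cfDNA methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CpG-island-centered analysis of enrichment-captured cfDNA methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcap)
```

## The problem

Affinity enrichment of methylated DNA (MBD or MeDIP capture) followed by
sequencing measures the *relative abundance* of methylated fragments, not
per-CpG methylation levels. Applied to plasma cell-free DNA (cfDNA), it
concentrates sequencing on CpG-dense regions — above all CpG islands,
which are unmethylated in normal tissue but focally hypermethylated in
carcinoma. `methcap` implements the island-centered analysis of such
data: capture quality control, fragment-to-feature counting,
negative-binomial differential methylation, harmonization with
array-style (450K-like) tissue methylomes, set intersection to isolate
tumor-derived signals, and a repeated consensus-LASSO classifier.

Because patient plasma methylomes are access-restricted, the package
ships a synthetic-data generator that reproduces the *statistical
structure* of each input — NB counts with capture bias and library-size
variation, Beta-distributed array values with planted island effects,
and spike-in qPCR cycle thresholds — together with ground truth, so
every stage can be tested and calibrated end to end.

## Coordinate and annotation model

Intervals are 1-based and inclusive in memory, so the width of
`chrom:s-e` is `e − s + 1`; this is the convention under which the
region strings and printed sizes of published island panels agree
exactly. On-disk BED is 0-based half-open; `read_bed()`/`write_bed()`
are the only places the offset changes.

`derive_feature_classes()` expands non-overlapping islands into the
standard partition: shores are the 2 kb flanks, shelves the next 2 kb
band, everything else inter-CpG. Where two islands sit closer than
8 kb, each base belongs to the *nearer* island edge (ties go to the
upstream island), i.e. the gap is split at its midpoint. The 2 kb/2 kb
geometry is the UCSC/annotatr convention; the midpoint rule is our
tie-break, chosen because it is the unique symmetric rule that keeps
the output a partition, and it is verified base-by-base against an
independent per-base labelling oracle in the tests. Inter-CpG is the
exact complement on the chromosomes supplied — unannotated contigs are
simply absent from the universe.

## Synthetic data: what it emulates, and what it does not

`simulate_counts()` draws
`count_ij ~ NB(mean = libsize_j · mu_i · fc_ij, alpha)` with

* `mu_i` = `baseline_mean` × a class-bias multiplier (island 30,
  shore 8, shelf 3, inter 1). The multipliers model MBD capture bias so
  that the island share of reads vastly exceeds the island share of the
  genome, qualitatively matching enrichment data; no public per-class
  coverage means exist to fit them, so they are stated defaults, not
  estimates.
* library-size factors drawn log-uniformly on `[0.5, 2]`, a realistic
  depth spread for plasma libraries.
* a planted fraction (default 10%) of islands hypermethylated in cases
  at fold change 4, with a small hypomethylated minority (default 0.2%
  of plantings) reflecting the strong hyper/hypo asymmetry of
  CpG-island methylation in carcinoma.
* one global dispersion (default 0.05), enough to exercise dispersion
  estimation without modelling a full mean–dispersion trend.
* default group sizes 12 cases vs 16 controls, a single-cancer plasma
  cohort scale.

`simulate_betas()` mirrors the array side: per-island CpG sites (5 by
default) with Beta-distributed values, group means `base_beta = 0.2`
everywhere except tumor samples at planted islands, which get
`base_beta + delta` with `delta = 0.35` — comfortably above the 0.2
calling threshold. Default group sizes are 21 tumor / 21 normal / 61
PBMC. `simulate_spikein()` produces qPCR Cts with
`ct_enriched = ct_input − log_base(efficiency)`, so one halving of
recovery costs exactly one cycle at base 2.

What the generator does **not** model: fragment-size distributions,
read-level error, GC effects, per-feature mean heterogeneity beyond
class bias, correlated sites within islands, batch effects, or cell
composition drift. Passing tests therefore demonstrate correctness and
calibration of the *statistics* under the assumed model, not
performance on real cohorts.

## Quality control

Recovery is `100 · 2^((ct_input − log2(dilution)) − ct_enriched)`; the
dilution term corrects the unenriched aliquot. Specificity is
`(1 − recovery_unmeth / recovery_meth) · 100`, with a shared dilution
cancelling in the ratio, and the gate passes at ≥ 99% (inclusive).
TPM normalization divides by feature length in kb and rescales each
sample to one million; class coverage fractions and the derived
extended-island share (island + shore + shelf) then partition each
sample's signal. Enrichment noise is the mean coverage of zero-CpG
fragments over the mean coverage of CpG-containing fragments, and the
CpG density at peak is the CpG-count bin (width 1) with maximal total
coverage, ties resolved to the lower density.

## Counting and filtering

Each fragment increments exactly one feature: maximal base overlap,
ties broken by class priority island > shore > shelf > inter, then by
the leftmost feature. Single assignment — rather than letting a
boundary-straddling fragment count toward several classes — keeps
column sums equal to fragment counts, so class percentages behave as a
partition and TPM stays interpretable. Before differential analysis,
inter-CpG rows and all-zero rows are removed (`filter_matrix()`,
idempotent), and the island-only view (`subset_islands()`) is the
substrate for DMCGI calling.

## Negative-binomial Wald differential methylation

The model is the standard count-based one: per feature,
`mu_ij = s_j · 2^(b0 + b1 x_j)` with `x_j = 1` for cases, NB variance
`mu + alpha·mu²`. The pipeline is authored here rather than delegated:

* **Size factors** — median-of-ratios over features nonzero in every
  sample, rescaled to geometric mean 1 (the rescaling fixes the scale;
  it does not affect test statistics).
* **Dispersions** — within-group method-of-moments estimates pooled by
  degrees of freedom, floored at `1e-8`, then shrunk toward a fitted
  `a1/mu + a0` trend by equal-weight log-space averaging. The weight
  0.5 is a stabilizer, not a tuned constant; tests show Wald p-values
  are uniform under the null with it.
* **Fit** — IRLS on the natural-log scale with `log(s_j)` offsets,
  initialized at log group means with pseudocount 0.5, run to an
  absolute deviance change below `1e-8` or 100 iterations. Features
  whose case (or control) counts are all zero drift to a large
  negative (positive) fold change and converge by deviance flatness;
  their Wald statistic is then essentially 0 by an exploding standard
  error, which is the honest answer.
* **Test** — Wald `z = b1/se(b1)` with the expected-information
  standard error, two-sided normal p, BH adjustment (via
  `stats::p.adjust`, with NA-p features excluded from the test count).
* **Calls** — `q < 0.1` and fold change `> 2` (hyper) or `< 1/2`
  (hypo), all strict inequalities. Fold changes are unshrunken MLEs;
  no independent filtering, no outlier replacement — deliberately the
  minimal model the thresholds refer to.

Although the implementation is independent, the test suite cross-checks
it against DESeq2 on simulated data: size factors agree to machine
precision (after fixing the geometric-mean-1 scale), per-feature log2
fold changes agree to ~0.001, and the called island sets are identical
on the fixture tested.

`top_features()` ranks called hypermethylated islands by descending
fold change with ties broken by ascending q then feature id, making the
top-k marker pool deterministic.

## Array harmonization

Sites are tested with the two-group equal-variance F-test (df1 = 1, the
square of the pooled t) on beta values directly — the calling threshold
is on the beta scale, so effect and test live on the same scale; no
M-value transform. Calling is one-sided hypermethylated:
`delta_beta > 0.2` and `q < 0.1`, both strict. Pairing of tumor/normal
samples is ignored (unpaired two-group testing). Called sites collapse
to unique islands; island-level beta matrices take the unweighted mean
of member sites.

## Intersection

Tumor-derived DMCGIs are the exact three-way intersection of plasma,
tumor-vs-normal and tumor-vs-PBMC island sets, keyed by region string —
the sets are harmonized to one annotation beforehand, so no fuzzy
coordinate matching is needed or wanted. Overlap percentages round
half-up to one decimal. `venn3()`/`type_specific()` expose the
seven-region decomposition and the members unique to each cancer type.

## Consensus-LASSO classifier

Each repeat draws a class-balanced 80/20 split
(`round(0.8·n_class)` per class), fits an L1-penalized logistic
regression over a lambda path with stratified 10-fold cross-validation
(glmnet, `alpha = 1`), keeps the CV-deviance-minimizing lambda
(`lambda.min`, not the 1-SE rule — a documented switch exists), and
scores the held-out split. After 100 repeats, the consensus set is the
features with nonzero coefficients in *every* repeat. Predictors are
standardized inside the fit on training data only; the per-repeat model
evaluated on the test split is the full-training-path fit at the chosen
lambda. Repeat seeds derive from a master seed and are logged, so the
whole protocol is reproducible. AUC is the Mann–Whitney form with ties
counting 1/2. `one_vs_rest()` wraps the protocol per class for
multi-cancer classification.

Under the synthetic default (3 informative features at standardized
effect 1.5 among 100 noise features, n = 160), the consensus set
recovers exactly the planted trio in most master seeds, and permuting
labels leaves it empty — the all-repeats rule is what suppresses the
occasional strongly spurious feature a single CV fit would admit.

## Numerical choices and degenerate inputs

* Dispersion floor `1e-8`; trend fitted only when ≥ 10 features are
  above the floor, otherwise raw moments are used.
* Zero pooled variance in the array F-test: p = 1 when group means
  agree, p = 0 flagged degenerate when they differ.
* All-zero sample columns are an error in TPM; matrices whose rows are
  all filterable are an error rather than an empty result.
* Fragments overlapping no feature (possible only off the annotated
  partition) count toward the nearest inter-CpG feature on their
  chromosome; an unannotated chromosome is an error.
* `overlap_percent()` uses explicit half-up rounding because base R's
  `round()` is round-half-even.

## Problem sizes used in the checks

The packaged tests and the acceptance script run: null and power
calibration on 2,000 islands at 12 vs 16 samples (20 null seeds, 3
power seeds); end-to-end recovery on 300 islands with full count/array
overlap; and the classifier protocol at 100 repeats for 10 master seeds
plus 10 permutation runs. These sizes give stable Monte-Carlo estimates
for the properties asserted while keeping a full run in minutes on one
core.

## Known limitations

The NB stage targets the two-group design only (no covariates, no
paired designs); the array stage assumes unpaired groups and equal
variances; consensus selection is performed on resamples of one
dataset, so it guards against split instability, not against dataset-
level spurious association; and synthetic calibration cannot speak to
pre-analytical variation in real plasma collections.
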