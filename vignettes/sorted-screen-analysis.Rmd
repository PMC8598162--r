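---
title: "Analyzing FACS-sorted CRISPR knockout screens with sortscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing FACS-sorted CRISPR knockout screens with sortscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment this package models

A pooled CRISPR knockout screen read out by sorting asks which genes
control a quantitative cell-surface phenotype. Cells carrying a
genome-wide guide library are stimulated (for example, macrophages
stimulated with interferon-gamma to induce surface MHC class II), then
sorted by FACS into the top and bottom tails of the phenotype
distribution. Guides targeting a positive regulator shift their cells
toward the low tail, so those guides become over-represented in the
low-bin sequencing library relative to the high bin. Unsorted "input"
replicates of the same library are sequenced alongside the bins to
measure technical noise without any selection signal.

`sortscreen()` is the single fitting function: it takes a count matrix,
a guide library annotation and (optionally) an expression table for the
screened cell type, and returns a classed fit with `print`, `summary`
and `plot` methods.

```{r, eval = FALSE}
library(sortscreen)
fit <- sortscreen(counts, library, expression, screen_config())
summary(fit)
```

## Stages of the model

### Expression-aware negative controls

The control set is the union of the non-targeting guides and all guides
of genes not transcribed in the screened cells (expression at or below
`expression_threshold`, default 1). Knocking out a silent gene cannot
move the phenotype, so these guides sample the null distribution of the
assay itself, at full library scale. All calibration steps below are
anchored to this set; an empty control set is a hard error.

### Size factors and normalization

`control_size_factors()` computes one factor per sample as
*(control library size)* x *(median-of-ratios skew factor)* / 10^6,
an effective-library-size normalization. The skew factor is the median,
over control guides positive in every sample, of the guide's relative
abundance divided by the geometric mean of its relative abundances
across samples. Two properties follow by construction:

* **Exact depth equivariance.** The reference profile is built from
  relative abundances, so it is invariant to any single sample's depth:
  multiplying one sample's counts by *c* multiplies its factor by
  exactly *c* and leaves every normalized count unchanged.
* **Signal insensitivity.** Only control guides enter the factor, so
  true enrichment in targeting guides (or an arbitrary spike in one of
  them) cannot move the normalization.

A consequence worth knowing: identical samples get *equal* factors, not
factors of 1 — the common factor is the control library size per
million. We chose this convention deliberately; a factor that is exactly
1 for identical samples cannot be exactly depth-equivariant (scaling all
*n* samples by *c* would have to yield factors of both 1 and *c*), and
exact equivariance is the property downstream inference relies on.

### The mean-variance model

Input replicates carry the technical dispersion of the library with no
selection signal. `fit_mean_variance()` learns
`var(mu) = mu + exp(a) * mu^b` from them: guides are grouped into 10-30
equal-size bins by mean normalized count, the average excess variance
`mean(var - mean)` is computed per bin *before* any log transform, and
`a`, `b` come from log-log least squares over positive-excess bins.
Binning first matters — selecting individual guides whose noisy sample
variance exceeds their mean biases the fit toward overdispersion (on
pure Poisson data it invents ~10-30% extra variance; binned moments
recover `var = mean` within a few percent). With fewer than two input
replicates or no overdispersed bins the model falls back to Poisson
with a warning.

### Guide-level test

For each guide, the expected count under no selection is the mean of
`(high + low)/2` across replicates. `guide_test()` compares the summed
low-bin count against a negative binomial with mean `R * mu` and
variance `R * var(mu)` (R replicates), using an interpolated
continuity-corrected tail (the mid-P convention: `P(X > obs) + 0.5 *
P(X = obs)` at integer observations). `p_low` small means the guide is
enriched where knockouts of positive regulators land. A Fisher
per-replicate combination is available via `combine = "fisher"`.

By default the model p-values are then re-calibrated against the
control guides (`calibrate = "control"`): each p is mapped through a
strictly monotone, log-scale-interpolated ECDF of the control-guide
p-values. The NB model is deliberately simple — it estimates the mean
from the same two bins it tests and cannot see the cell-subsampling
noise of the sort itself — so its raw p-values are structurally
miscalibrated even when every distributional assumption about counts
holds. The controls measure the realized null directly; mapping through
their ECDF makes null guide p-values uniform while preserving ranks
exactly (the map is strictly monotone, so gene-level aggregation is
unaffected). Values more extreme than every control are scaled
proportionally below the smallest control p rather than truncated, so
very strong hits keep their resolution. `calibrate = "none"` exposes
the raw model p-values.

### Gene-level aggregation (alpha-RRA)

Guides are ranked by `p_low` into percentiles `u = rank/n` (average
ties; control guides stay in the pool to stabilize ranks). For a gene
with guides at sorted selected percentiles `u(1) <= ... <= u(m)` —
keeping only guides with `p < alpha` — the score is

`rho = min_i P(Beta(i, m - i + 1) <= u(i))`,

the most surprising prefix of its guide ranks under uniformity. A gene
with no guides passing alpha gets `rho = 1`. Significance comes from a
permutation null: for each distinct guide count *k*, random
*k*-subsets of the full percentile pool are scored the same way, and
`p_perm = (1 + #{rho_null <= rho_obs}) / (N + 1)`. Nulls are cached per
*k* and seeded deterministically, so results are reproducible and
independent of gene order. Benjamini-Hochberg `q_bh` values come from
`p.adjust`. Thresholding at alpha (default 0.1) is what makes the
statistic robust to a single jackpot guide: one outlier cannot drag a
gene in when its other guides rank poorly.

### Alpha tuning and quality control

`tune_alpha()` scans an alpha grid and picks the value maximizing the
number of significant genes subject to every designated positive
control staying under `positive_control_q_max`. If no alpha satisfies
the controls it warns INFEASIBLE and returns the alpha minimizing the
worst control q, with the full report attached. Positive controls
should be genes with several efficacious guides; a control whose guides
are mostly inactive cannot constrain alpha. `positive_control_qc()` and
`screen_ppv()` report per-control status and positive predictive value
(against simulation truth, or treating significant non-expressed genes
as false positives in real data).

### Expression filter

By default only expressed genes are tested (`expression_filter =
TRUE`). Silent genes cannot be true regulators, but gene-level count
artifacts (clonal jackpots, mapping pileups) do not respect expression
status; filtering them out of the tested set converts would-be false
positives into nothing. The simulator can plant exactly this failure
mode (`artifact_fraction`, `artifact_effect` on non-expressed genes) to
measure the PPV gain of the filter.

## The synthetic screen

`sim_params()` / `simulate_guide_library()` / `simulate_sorted_screen()`
generate a full study: per-gene expression with a `frac_nonexpressed`
silent fraction, planted hits among expressed genes only, per-guide
efficacies from Beta(5, 1) with a 25% dud fraction, and then an
explicit cell-level simulation per replicate — lognormal guide
abundances (`abundance_sigma = 0.3`), multinomial assignment of cells
to guides (one guide per cell, the low-MOI regime), all-or-none editing
with probability equal to the guide's efficacy, a standard-normal
phenotype shifted by `-effect_size` in edited cells, exact empirical
`q`/`1-q` quantile gates for the two sort bins, and multinomial read
sampling to a fixed depth per sample.

Defaults are the study design: 2,000 genes x 4 guides + 100
non-targeting controls, 40% non-expressed, 5% hits with effect 2 SD,
`q = 0.15`, 2 million cells, 500,000 reads per sample, 2 replicates.
These are *conditions*, not tuning knobs; `abundance_sigma = 0.3` gives
the mild guide-representation spread of a well-maintained library, and
the cell counts give ~37x sorted-cell coverage per guide per bin (a
warning fires below 10x). What the simulator does **not** emulate:
multi-guide infections, partial (in-frame) editing outcomes, PCR
jackpots at the read level, cell-cycle or fitness effects of knockouts,
and gate impurity from sorter spillover. It is a testbed for the
inference, not a sequencer emulator.

## Reproducibility

Everything randomized is seeded: the generator from `sim_params(seed)`,
the permutation null from `screen_config(rng_seed)` (cached draws keyed
by `seed + k`), and `run_screen()` writes a deterministic
`run_log.txt` and `manifest.yaml` with input checksums so a run
directory regenerates byte-identically. The implementation is
single-threaded base R; there is no thread-count dependence. A thin
command-line wrapper ships in `exec/sortscreen` with subcommands
`simulate`, `test`, `tune` and `report`.

## Limitations

* The guide test conditions on `(high + low)` through its mean
  estimate rather than modelling the pair jointly; the control
  calibration absorbs the resulting miscalibration but a joint
  beta-binomial treatment would be more principled.
* Control calibration assumes enough control guides to resolve the
  tail (hundreds to thousands; with few controls the proportional
  extrapolation below the smallest control p carries more weight).
* alpha-RRA with 4 guides per gene cannot distinguish a gene with two
  moderately ranked guides from one strong and one weak; sensitivity
  at `effect_size` below ~1 SD drops quickly at default depth.
* The permutation null treats guides as exchangeable; strong
  gene-level count artifacts violate this, which is exactly why the
  expression filter exists.
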