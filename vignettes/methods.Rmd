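---
title: "Methods: from co-culture screen to enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from co-culture screen to enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtscreen)
```

## The problem

Carcinoma cells that undergo an epithelial-to-mesenchymal transition
(EMT) become invasive and drug-tolerant, and selectively killing them
is a long-standing goal in oncology drug discovery. One practical
route is a two-colour co-culture screen: an epithelial line (GFP,
"green") and an EMT-like derivative (mCherry, "red") are mixed in one
well, treated with a compound library at a single dose, and imaged.
Per-well cell counts in each channel, normalized to untreated wells,
reveal compounds that preferentially kill the EMT-like population.
`emtscreen` implements the full analysis chain for such a screen —
normalization, quality control, hit calling, dose-response potency and
selectivity, growth-rate-corrected potency, panel classification and
gene set enrichment — together with seeded generators that simulate
every input, so the chain is testable end to end without external
data.

## Plate model and normalization

A 96-well plate carries library compounds (single dose, 1 µM in the
emulated design), untreated vehicle wells, and positive-control wells
treated with hygromycin. The positive control exploits an engineered
asymmetry: only the epithelial (green) line carries a
hygromycin-resistance marker, so hygromycin suppresses the red channel
while leaving green intact. Each well is imaged in 13 fields per
channel; per-field counts are summed per well, and

\[
\mathrm{viability}_{\text{well,channel}} =
\frac{\text{well total}}{\text{mean vehicle total on the same plate}}
\]

Normalization is per plate, not screen-wide: this is standard
high-throughput screening practice and cancels plate-to-plate gain
differences (classification is provably invariant to plate-consistent
rescaling of raw counts, and the test suite asserts this).

## Assay quality

With $\mu_n, \sigma_n$ the mean and SD of negative (vehicle) controls
and $\mu_p, \sigma_p$ of positive controls:

\[
Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{\mu_n - \mu_p}, \qquad
S/N = \frac{\mu_n - \mu_p}{\sigma_n}, \qquad
S/B = \frac{\mu_n}{\mu_p}.
\]

SDs use the sample ($n-1$) convention because control wells per plate
are few. QC defaults to the red channel — the positive control acts on
nothing else — and green-channel QC warns accordingly. $Z' \ge 0.5$ is
the conventional screening-grade gate; plates below it are excluded
from hit calling by the pipeline. $Z' = 1$ exactly in the
zero-variance limit, and $Z'$ and $S/B$ are reported as undefined when
their denominators vanish.

## Hit calling

A compound is **EMT-selective** when (a) green viability $\ge 0.55$,
(b) red viability $\le 0.41$, and (c) the ratio $R/G \le 0.65$;
**epithelial-selective** under the mirrored rule (green $\le 0.41$,
red $\ge 0.46$, $R/G \ge 1.80$). Two decisions were open:

* The ratio's orientation is red over green, the only choice
  consistent with the rules' direction (low ratio = red preferentially
  killed).
* The pan-cytotoxic cluster is described only qualitatively in the
  source screen ("bottom left"); we define it symmetrically as both
  channels $\le 0.41$, reusing the published kill threshold. It is
  configurable.

The threshold geometry makes the classes mutually exclusive (green
cannot be both $\ge 0.55$ and $\le 0.41$); anything else is inactive.
A compound with zero green viability has an undefined ratio and can
only reach the pan-cytotoxic or inactive class. Exclusions
(auto-fluorescent or structurally problematic compounds) are an input
annotation, never computed: excluded compounds keep their data-driven
class but leave the reported hit lists.

## Dose-response: 4PL, absolute IC50, selectivity

Viability against dose is modelled with the four-parameter logistic

\[
v(c) = \mathrm{bottom} +
\frac{\mathrm{top} - \mathrm{bottom}}{1 + (c/\mathrm{EC}_{50})^{h}},
\qquad h > 0,
\]

fit by least squares on the $\log_{10}$ dose axis. Numerical choices:

* **Multi-start**: EC50 is initialized at the 25/50/75% dose
  quantiles; lowest residual sum of squares wins, ties broken toward
  the smaller EC50.
* **Optimizer**: box-constrained quasi-Newton (L-BFGS-B) with an
  analytic gradient, run at a coarse then a tight tolerance from each
  start. The line search can abort at machine precision while sitting
  on a stationary point, so convergence is additionally judged by the
  gradient norm at the solution. Noise-free inputs are recovered to
  better than $10^{-6}$ across a grid of parameter combinations (an
  acceptance test).
* **Zero dose**: vehicle points are the normalization denominator, not
  fitted points; they are dropped from the log axis.
* **Inverted data**: monotone-increasing "viability" is fit with
  unordered asymptotes and flagged `non_inhibitory` rather than given
  a negative Hill slope.

The **absolute IC50** — where the fitted curve crosses viability 0.5,
as opposed to the relative EC50 at the curve midpoint — has the closed
form $c_{50} = \mathrm{EC}_{50}\,[(\mathrm{top} - 0.5)/(0.5 -
\mathrm{bottom})]^{1/h}$ and equals the relative EC50 exactly when
$(\mathrm{top}+\mathrm{bottom})/2 = 0.5$. Curves that never cross 0.5
inside the tested range are censored (`">c_max"`, `"<c_min"`), never
extrapolated. Fold-selectivity is the less-sensitive line's IC50 over
the more-sensitive line's, reported rounded half-away-from-zero
(e.g. 194 vs 7 nM gives 27.71, reported 28); censored inputs yield a
bound, not a number.

## Growth-rate correction and population doublings

Fast-dividing lines look artificially sensitive in endpoint assays. The
growth-rate inhibition value

\[
\mathrm{GR}(c) = 2^{\log_2(x(c)/x_0) / \log_2(x_{\mathrm{ctrl}}/x_0)} - 1
\]

rescales the endpoint count $x(c)$ by the control growth
($\mathrm{GR}=1$ no effect, $0$ cytostasis, $<0$ net loss); GR50 is the
0.5-crossing of a 4PL fit to GR values, censored like the IC50. The
formula requires control growth ($x_{\mathrm{ctrl}} > x_0$) and errors
otherwise. Across a panel, IC50 and GR50 are compared by Spearman
correlation of log potencies with censored pairs dropped and counted.

Population doubling level uses
$\mathrm{PDL}_n = 3.32(\log_{10} X_t - \log_{10} X_0) +
\mathrm{PDL}_{n-1}$ with the constant 3.32 verbatim as published;
`exact_log2 = TRUE` substitutes $1/\log_{10} 2 = 3.3219\ldots$ so one
doubling increments the PDL by exactly 1. With either constant the
formula is exactly additive over consecutive passages.

## Panel classification and GSEA

Cell lines are grouped by absolute IC50 with a strict 100 nM cutoff
(sensitive $<$ 100 nM, resistant $>$ 100 nM). An IC50 of exactly
100 nM — unassigned by the strict inequalities — is classed resistant
(documented tie rule, erring against calling sensitivity). Censored
values resolve when their bound decides the comparison and are flagged
ambiguous otherwise.

The enrichment engine is written from scratch:

* **Ranking**: signal-to-noise, $(\bar{x}_S - \bar{x}_R)/(s_S + s_R)$,
  with each class SD floored at $\max(0.2\,|\bar{x}|,\, 0.2)$ (the
  canonical GSEA adjustment), descending, ties broken by gene
  identifier.
* **Score**: weighted running sum — hits add
  $|s|^p / \sum_{\text{set}} |s|^p$ (weight $p = 1$ by default), misses
  subtract $1/(N - N_{\text{set}})$; ES is the signed maximum
  deviation. At $p = 0$ this is the classical Kolmogorov–Smirnov
  statistic, which the tests verify against a brute-force oracle.
* **Null**: phenotype-label permutations at fixed group sizes, with
  genes re-ranked per permutation — appropriate for the emulated
  design of 13 vs 11 samples ($\ge 7$ per class); designs with fewer
  distinct assignments than requested permutations are enumerated
  exactly.
* **NES and inference**: NES divides ES by the mean same-sign
  permutation ES of that set; nominal p is the same-sign permutation
  tail; FDR q follows the standard positive/negative-NES procedure.
  Sets with $q \le 0.25$ are flagged (the conventional cutoff), but the
  full q-value is always reported.
* Gene-set sizes outside [15, 500] (after intersection with measured
  genes) are filtered; both limits are configurable.

Results are made invariant to input gene order and to sample order
within a class by canonicalizing both orderings before analysis.

## What the generators emulate — and what they do not

The synthetic-data module states a world and the tests interrogate the
pipeline inside it:

* **Screen plates**: 80 compounds per plate plus 8 vehicle and 8
  positive-control wells, 13 fields/well, two channels. Counts are
  negative binomial (size 20) around baseline 60 cells/field
  (~780/well), because real imaging counts are overdispersed; Poisson
  is available. The positive control leaves 1/6 of red cells — chosen
  a priori so the simulated assay sits in the published quality regime
  (S/B exactly 6; a delta-method calculation gives $Z' \approx 0.67$
  before any test was run). Truth labels are the hit rules applied to
  the noiseless planted fractions, so "recovery" is well defined.
* **Dose-response**: 4PL plus additive Gaussian noise (SD 0.05 by
  default), truncated at zero, on a serial-dilution series emitted in
  nM end to end.
* **Growth curves**: exponential with multiplicative lognormal noise.
* **Expression panel**: standard-normal background, a planted set
  up-shifted in sensitive samples by 2 within-group SDs (13 vs 11
  samples), decoy sets drawn from background genes only.

Not emulated: image segmentation, plate-position (edge) effects,
compound auto-fluorescence, correlated gene expression, or real
hallmark gene sets. A green test therefore establishes that the
algorithms are correct under the stated statistical model — not that
the model captures every pathology of real screens. The per-well count
dispersion is a free parameter of the generator, not an estimate from
data.

## Known limitations

* The published screen's exact hit counts are not a pure function of
  its rules (some rule-passing compounds were manually excluded), so
  they are not asserted; only rule-recovery on planted truth is.
* GR50 details in the source (endpoint, fitter) are unstated; this
  package fixes them as "same 4PL machinery as IC50, on GR values".
* The enrichment FDR is the empirical GSEA procedure, which can exceed
  a Benjamini–Hochberg FDR in small designs; q-values below ~1/(number
  of permutations) are reported as 0.
* Reported simulated fold-selectivities are integer-rounded ratios of
  two fitted quantities and are therefore noticeably stochastic at
  realistic noise; potency truths near dose-series edges fit with bias
  unless the series brackets both asymptotes.
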