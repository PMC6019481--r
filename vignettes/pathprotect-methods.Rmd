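---
title: "Quantifying pathway protection from two-channel microarray data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pathway protection from two-channel microarray data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathprotect)
```

## The problem

An insult (for instance prolonged seizure activity) reshapes a tissue's
transcriptome; a protective treatment (for instance estradiol replacement in
ovariectomized animals) may blunt that reshaping. `pathprotect` quantifies
such protection at the pathway level from two-channel microarray data laid
out in a *multiple-yellow* design: each array co-hybridizes two differently
labeled biological replicates of the **same** condition, and four conditions
are compared — baseline (CON), treatment alone (CEN), insult alone (COS),
and insult under treatment (CES). Protection is the contrast between the
*unprotected* comparison COS vs CON and the *protected* comparison CES vs
CEN.

## Normalization

A non-control spot is **valid** when its foreground fluorescence is at least
twice its background; only valid spots are used. Each valid spot's
background-subtracted foreground is divided by the median
background-subtracted foreground of all valid spots with the same label on
the same array, anchoring every (array, label) group's median at 1. All
spots probing the same gene in a sample are then averaged, removing array
redundancy, and an iterative algorithm renormalizes the resulting matrix
across labels and conditions: each pass rescales every sample by the median
ratio of its per-gene values to a per-gene reference, and the algorithm
stops when the average absolute relative change of all per-gene
cross-condition expression ratios between successive passes falls below 5%
(the `tol` parameter, dimensionless, default 0.05).

Two choices here were genuinely open and are our own:

* **Reference for the iterative stage.** We use the per-gene geometric mean
  across all samples with valid values. Expression levels are ratios on a
  multiplicative scale, so the geometric mean is the natural anchor;
  arithmetic means would let bright samples dominate.
* **Convergence metric.** The mean over genes and condition pairs of
  |ratio_new/ratio_old − 1|, a literal reading of "average change of
  expression ratios". Iteration is capped (default `max_iter = 100`) and
  non-convergence is an explicit error naming the last delta, never a
  silent truncation.

Genes valid in fewer than n − 1 of a condition's n replicates are treated
as unquantified in that condition: means and variability estimates on one
or two replicates are too unstable to compare.

## Regulation calls with a per-gene fold-change cut-off

For a comparison B vs A the signed expression ratio is
$x = \mu_B/\mu_A$ when $\mu_B \ge \mu_A$ and $x = -\mu_A/\mu_B$ otherwise,
so $|x| \ge 1$ and negative values denote down-regulation. Instead of a
uniform threshold such as 1.5×, each gene carries its own cut-off combining
the technical noise and biological variability of the two conditions:

$$\mathrm{CUT} = 1 + \sqrt{\mathrm{CV}_A^2 + \mathrm{CV}_B^2},$$

where each CV pools the spread of the replicate means with the
per-replicate standard error of the gene's redundant spots. A gene is
called regulated when $|x| \ge \mathrm{CUT}$ **and** the p-value of a
heteroscedastic (Welch) t-test is below α = 0.05. The test runs per
distinct spot group probing the gene, on log-transformed levels by default,
and the gene-level p-value applies a Bonferroni-type correction for the k
redundant spot groups: $p = \min(1, k \cdot \min_j p_j)$ (a Šidák variant
sits behind a flag). Equality with the cut-off counts as regulated — the
inclusive reading of "exceeds" — and this is asserted in tests.

This flexible cut-off admits very stably expressed genes with |x| below
1.5 (false negatives of the uniform rule) and rejects variably expressed
genes with |x| above 1.5 but below their own CUT (false positives). The
package's defaults reproduce the canonical worked cases: x = 1.477 against
CUT = 1.298 is regulated; x = 2.226 against CUT = 2.297 is not.

The exact CUT estimator used on the original arrays is published only by
citation, not by formula; the root-sum-of-squares form above is this
package's declared default. It satisfies the verbal definition (combined
contributions of the two noise sources), is monotone in each CV, equals 1
in the noiseless limit, and under the default simulation conditions its
average lands near 1.45–1.6, the scale reported for real 4×44k arrays. An
optional chi-square mid-interval correction (`cut_estimator = "chisq"`)
inflates small-n CVs.

ON/OFF calls use the validity mask alone: a gene quantifiable (valid in
≥ n − 1 replicates) in one condition and absent (valid in ≤ 1 replicate)
in the other is *turned on* or *turned off*. The two thresholds are
declared defaults, configurable, chosen to keep the quantifiable and
absent states mutually exclusive for n ≥ 3.

## Pathway-level protection quantifiers

For a gene set (pathway) and a comparison:

* **Percent regulated** — the percentages of up- and down-regulated genes
  among the *quantified* members; unquantified members are excluded from
  the denominator and reported separately, never imputed.
* **WPR (Weighted Pathway Regulation)** — a cut-off-free score: each
  quantified member contributes $c_i = (|x_i| - 1)(1 - p_i)$ and the score
  is the mean contribution. The contribution function is this package's
  default (the original is published only by citation); it is continuous,
  zero exactly when $|x| = 1$ or $p = 1$, and satisfies the one printed
  constraint: a (2×, p = 0.01) gene contributes more than twice a
  (1.5×, p = 0.05) gene (0.99 vs 0.475). The mean (rather than sum)
  aggregation keeps pathways of different sizes comparable; `aggregate =
  "sum"` is available.
* **PPR (Pathway Protection)** — the percent reduction of WPR:
  $100\,(\mathrm{WPR}_u - \mathrm{WPR}_p)/\mathrm{WPR}_u$ for the
  unprotected and protected comparisons. Negative values mean the
  treatment worsened the pathway's regulation; the value is undefined
  (reported missing) when the unprotected WPR is 0.
* **TPR (Transcriptomic Protection)** — the percent reduction of the
  regulated fraction. The default is the plain reduction; a
  side-effect-adjusted mode additionally debits the percentage regulated
  by the treatment alone. The adjustment is described only verbally in the
  methods it descends from, so the plain mode is the default and the mode
  used is recorded in the output.

## Expression coordination and switches

Within one condition, the coordination of a gene pair is the Pearson
correlation of their (log) expression levels across the biological
replicates. With n = 4 replicates, significance uses the exact t transform
$t = r\sqrt{(n-2)/(1-r^2)}$ rather than Fisher-z asymptotics; the critical
value at α = 0.05 and n = 4 is |r| = 0.950. Pairs are classified
**S**ynergistic (significantly positive), **A**ntagonistic (significantly
negative), **I**ndependent, or **U**ndetermined. No rigorous test can
declare *significant independence* at n = 4, so I is a declared threshold
class, $|r| \le r_{\mathrm{ind}}$ with default 0.25, and U absorbs the
rest — too little evidence either way.

A pair whose class changes between conditions is a **switch**;
synergistic-to-antagonistic (S→A) and antagonistic-to-synergistic (A→S)
switches are labelled explicitly, and `switch_census()` aggregates them
per gene to expose hubs. Two-pathway networks are built through the genes
common to both pathways: edges run from the first pathway to the common
genes and from the common genes to the second pathway, with common genes
counted once, in their own layer.

Whether coordination should use raw or log levels is unstated in the
tradition this implements; we default to log, where the simulated
lognormal model makes the planted correlation exact, with
`scale = "linear"` available.

Pair enumeration is exact: G genes yield G(G−1)/2 unordered pairs per
condition (12,710 quantified genes would give 80,765,695). Desk-scale use
is intended for ≤ 2,000 genes; the correlation matrix is computed in one
`cor()` call per condition, and memory grows with the square of the gene
count.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, and
nothing more:

* lognormal expression with per-gene baseline log-means uniform in [6, 10]
  (natural log fluorescence units) and per-gene biological CVs uniform in
  [0.10, 0.50] — chosen so the average CUT under defaults lands near the
  1.45–1.6 scale reported for real arrays;
* spot foreground = true level × label bias × lognormal technical noise
  (CV 0.10) + lognormal background (mean 50); label bias Cy5/Cy3 = 1.25
  exercises the per-label normalization;
* 1–4 redundant spots per gene with a fixed layout across arrays, 5%
  control spots, and 1% of spots forced below the validity threshold
  (fg < 2 bg) to exercise the filter deterministically;
* the multiple-yellow design: 4 conditions × 4 replicates = 16 samples on
  8 arrays, each array carrying two replicates of the same condition;
* planted regulation applied multiplicatively to the condition means of
  COS (vs CON) and CES (vs CEN); the default plan regulates 44% of genes
  in the unprotected and 11% in the protected comparison — the headline
  fractions of the motivating study — with |FC| uniform in [1.5, 3] and
  60% down-regulation;
* planted coordination through shared latent factors: genes in a block
  with loadings a, b and residual variance σ² have expected correlation
  $ab/\sqrt{(a^2+\sigma^2)(b^2+\sigma^2)}$, verified against Monte-Carlo
  in the tests. Negating the loadings of a *subset* of a block's genes in
  chosen conditions plants S→A switches on the cross-subset pairs
  (negating a whole block changes no pairwise correlation, since only
  loading products matter).

One global seed drives a single generator stream, so identical
configurations reproduce byte-identical outputs.

What the generator does **not** emulate: probe sequences, hybridization
chemistry, spatial artifacts, saturation, dye-swap-specific biases beyond a
constant label factor, and heavy-tailed outlier spots. Passing
parameter-recovery tests therefore shows the pipeline is correct under its
own model assumptions, not that real arrays satisfy those assumptions.

## Test problem sizes and numerical choices

The parameter-recovery suites run the full pipeline over 20 seeds each on
universes of 120–150 genes — large enough that per-sample normalization
factors are essentially independent of any planted block (with very small
universes the median factor tracks a large block's latent factor and
attenuates the planted correlation; we verified recovery matches the
bivariate-normal closed form at 150+ genes), and small enough to keep the
whole suite under a minute per property. Recovery conditions follow the
package's stated guarantees: sensitivity ≥ 90% with false calls ≤ 10% at
planted |FC| = 3 and biological CV ≤ 0.2; coordination sign recovery ≥ 80%
at planted |ρ| = 0.98 and n = 4, where the theoretical detection
probability at the exact-t critical value is ≈ 0.85 — power at four
replicates is intrinsically low, and the thresholds reflect that.

Other numerical conventions: medians of even-sized groups are midpoints of
the two central values; Welch tests on zero-variance data fall back to the
exact limits (p = 1 for equal means, p → 0 otherwise); ties at x = ±CUT are
regulated; uncomputable correlations (zero variance) are carried as missing
and excluded from percentages and switch detection, with counts logged.

## Limitations

* The CUT and WPR formulas are declared defaults reproducing published
  *behavior*, not reconstructions of the original (cited-only) formulas.
* The heteroscedastic test assumes approximate log-normality; no
  moderated-variance (empirical Bayes) shrinkage is applied, and no
  across-gene FDR control — the design of the method is per-gene corrected
  p-values at a fixed α.
* Coordination is pairwise Pearson only: no partial correlations, so an
  S edge may reflect a shared upstream factor rather than direct
  interaction.
* At n = 4 the I class is a threshold statement, not a significance
  statement.
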