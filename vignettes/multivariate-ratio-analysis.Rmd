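---
title: "Multivariate ratio analysis and barcoding distances: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate ratio analysis and barcoding distances: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mratax)
```

## The problem

Closely related insect species — the motivating case is a group of European
paper wasps — often differ only in subtle, size-entangled proportions of
the body, while DNA barcodes separate them cleanly. An integrative
delimitation therefore needs two machines: one that turns a table of
linear measurements into size-free *shape* evidence expressed as character
ratios (the currency of taxonomic keys), and one that turns aligned
barcode sequences into within- versus between-group distance evidence.
`mratax` implements both, plus seeded generators so the whole pipeline is
testable with no external data.

## The morphometric model

All morphometric machinery operates on natural logarithms of strictly
positive measurements (micrometres). For a specimen with measurement
vector $x \in \mathbb{R}^p_{>0}$:

* **Isosize** is the geometric mean $\left(\prod_j x_j\right)^{1/p}$,
  i.e. $\bar{\ell} = \tfrac1p \sum_j \log x_j$ on the log scale: the
  coordinate along the isometric direction $u = (1,\dots,1)/\sqrt{p}$.
* **Log shape** is $\log x_j - \bar\ell$: the vector of log ratios of each
  character to the specimen's geometric mean. Every log-shape row sums to
  zero, and $\log x = \text{isosize} + \text{log shape}$ exactly.
* **Shape PCA** is a covariance-based PCA of the log-shape matrix,
  equivalently an eigenanalysis of the log-data covariance projected onto
  the orthogonal complement of $u$ ($P = I - \mathbf{1}\mathbf{1}^\top/p$).
  At most $p-1$ components carry variance. It is unsupervised: group
  labels never enter, which avoids circularity when the groups themselves
  are the hypothesis being tested.
* The **PCA ratio spectrum** displays the loading coefficients of one
  shape PC on a single axis; only the ratio of the two characters at
  opposite extremes is informative for that PC. The **allometry ratio
  spectrum** displays per-character OLS slopes of $\log x_j$ on isosize;
  under isometry all slopes are 1. Both carry 68% bootstrap percentile
  intervals (default 1000 replicates), resampling specimens with
  replacement; PCA-loading replicates are sign-aligned to the point
  estimate by dot product before taking percentiles.

### Two-group discrimination in ratio space

Given two groups with log-data means $\mu_1, \mu_2$ and pooled within-group
covariance $W$, the **standard distance** along a direction $r$ is

$$D(r) = \frac{|r^\top(\mu_1 - \mu_2)|}{\sqrt{r^\top W r}},$$

the group separation in pooled within-group standard deviations; it is
invariant to rescaling of $r$ and to global unit changes. The **LDA ratio
extractor** evaluates $D(e_j - e_k)$ — the standard distance of the log
ratio $x_j/x_k$ — for all $p(p-1)/2$ character pairs and returns the
maximiser (120 pairs at $p = 16$; exhaustive search, verified in the tests
against an independent two-sample computation). The report carries the raw
ratio range of each group, because disjoint ranges are what makes a ratio
usable in an identification key.

The statistic $\delta$ asks whether that separation is driven by size or
by shape:

$$\delta = \frac{D(u)}{D(d_{\text{shape}})}, \qquad
  d_{\text{shape}} = W_{\text{shape}}^{+}\,(\mu_1-\mu_2)_{\text{shape}},$$

where the subscript denotes projection onto shape space and $^{+}$ a
pseudo-inverse ($W_\text{shape}$ has rank at most $p-1$ by construction).
$\delta = 0$ exactly when the groups have equal mean isosize, and grows
without bound as the separation becomes purely isometric. The exact
closed form of $\delta$ in the originating method's supplementary scripts
was not available to us; this definition reproduces its documented
behaviour (near zero for shape-dominated separations, label-swap
invariant) and is the package's own commitment.

### Design choices worth recording

* **Covariance, not correlation PCA**: all variables share units (µm) and
  the log scale; correlation-based PCA would discard meaningful variance
  differences between characters.
* **Sign convention**: the loading coefficient of largest magnitude is
  made positive (first index on ties), so output is deterministic across
  platforms and bootstrap replicates can be aligned unambiguously.
* **Bootstrap intervals** are percentile (not BCa) 68% bounds, pooled with
  the point estimate so the interval always contains it; replicates with
  fewer than 3 distinct specimens are redrawn.
* **Ratio orientation**: the numerator is chosen so the pooled
  geometric-mean ratio is at least 1, matching how taxonomic tables print
  ratios; ties in spectrum extremes break by character name.
* **Per-sex analysis**: the motivating data are strongly sexually
  dimorphic, so every MRA entry point refuses mixed-sex tables unless
  explicitly overridden.
* **Missing data**: specimens with any missing or nonpositive measurement
  are dropped with a warning; MRA needs complete positive rows and
  imputation would silently manufacture shape.
* **No allometric correction of best ratios**: deliberately out of scope;
  the spectra expose allometry so the analyst can see it, but reported
  diagnostic ratios are the observed ones.

## The molecular model

Pairwise distances use the **closed-form GTR estimator**: with $\hat F$
the symmetrised matrix of site-pattern proportions of a sequence pair
(pairwise deletion of any column where either sequence has a gap or
ambiguity code) and $\Pi$ the diagonal of the pair's averaged base
frequencies,

$$\hat d = -\operatorname{tr}\!\left[\Pi \log\!\left(\Pi^{-1}\hat F\right)\right],$$

computed stably through the symmetric similarity transform
$\Pi^{-1/2}\hat F\,\Pi^{-1/2}$. In the equal-frequency uniform-pattern
limit this reduces exactly to Jukes–Cantor $-\tfrac34\log(1-\tfrac43 p)$
(asserted to $10^{-9}$ in the tests). Saturated pairs (non-positive
eigenvalues) are flagged unavailable rather than truncated. The
closed-form estimator was chosen over iterative ML because at the
divergences that matter here (below ~5%) the two agree far beyond the
one-decimal percent precision at which such distances are reported; the
tests bound its relative bias at 10 kb below 2% for $d \in \{0.01, 0.05,
0.2\}$.

The **barcoding-gap summary** reports, per OTU, the maximum within-OTU
distance (undefined and flagged for singletons), the nearest neighbour
OTU, the minimum between-OTU distance, and a gap flag set when
within-max < between-min.

**Simple indel coding** turns each distinct internal (start, end) gap run
into one binary character regardless of length. Terminal overhangs are
missing data, not indels; a taxon whose longer gap strictly subsumes a
character's span is scored missing for it, as is a taxon with no data
across the span. Characters are classified parsimony-informative (both
states in ≥ 2 taxa), autapomorphic (minority state in exactly 1 taxon) or
constant. Since the study's own nuclear alignment is not deposited, its
printed indel-character counts are treated as a reconciliation exercise,
not a test target; the coder is instead verified on enumerated toys.

## What the synthetic generators emulate — and what they don't

The morphometric generator draws, per group, a latent log-size
$s \sim N(\mu_s, \sigma_s)$ and sets
$\log x_j = s\,b_j + m_j + \varepsilon_j$ with zero-sum shape offsets
$m$, allometric slopes $b$ (1 = isometry) and independent residuals. This
is the minimal model consistent with the size/shape decomposition: a
single shared size factor, group-specific shape means, optional allometry.
The calibrated spec reproduces the published per-group means exactly in
expectation (log-normal moment matching: $v_j = \log(1+\mathrm{CV}_j^2)$,
$l_j = \log(\text{mean}_j) - v_j/2$), with 60% of the shared log-variance
assigned to the size factor — size is the dominant shared factor in these
wasps, whose largest species also drives a strong size–shape correlation.
What the generator does *not* emulate: correlated residuals between
characters (real covariance structure is richer than one factor),
measurement rounding to eyepiece units, and unbalanced missingness. A
green planted-recovery test therefore establishes correctness of the
estimators under the stated model, not robustness to arbitrary real-world
covariance.

One subtlety the tests encode: because isosize *contains* every character,
planting slope $b$ on one of $p$ characters yields an observable
slope-on-isosize of $b/\bar b$, not $b$; slope *differences between
characters*, which is all the ratio spectrum uses, are unaffected.

The sequence generator is a star-of-stars, not a coalescent: a root
sequence drawn from the base frequencies, OTU ancestors at distance
$(\text{between}-\text{within})/2$ from the root, taxa at
$\text{within}/2$ from their ancestor, evolved by $e^{Qt}$ under a
normalised GTR generator. Distances are additive in expectation, so
expected pairwise distances hit the targets; there is no rate
heterogeneity across sites, no recombination and no realistic genealogy.
Indels are carved post hoc as shared gap runs and never affect distances
(pairwise deletion).

## Numerical and degenerate-input policy

* Loading vectors are explicitly re-projected onto shape space and
  renormalised, so the zero-sum invariant holds to $10^{-10}$ rather than
  merely to eigen-solver precision.
* A table whose specimens are scalar multiples of one vector (pure
  isometry) yields zero shape variance: reported via a `degenerate` flag
  with `NA` variance fractions, not an error.
* $D(r)$ with zero within-group variance along $r$ but distinct means is
  reported as `Inf` with a warning (infinite separation); pairs with zero
  within-group ratio variance are skipped in the search, with a warning.
* $\delta$ with a zero shape-space separation (pure size) is `NA`,
  flagged.
* All stochastic steps take a mandatory seed in the pipeline; every
  tabular output serialises floats at fixed precision, making reruns
  byte-identical.
* Config files are JSON rather than TOML (no TOML parser in the supported
  dependency set); keys are documented in `?read_pipeline_config`.

## Combined verdicts

The pipeline joins, per OTU pair, the morphometric non-overlap flag with
the per-marker gap flags through a fixed truth table
(`?species_verdict`, tested exhaustively): *distinct* requires
morphometric non-overlap or a gap on at least two markers;
*cryptic-species candidate* marks molecular gaps without morphometric
separation; otherwise *not separable* / *not evaluated*. The table is
deliberately conservative: a single-marker gap alone never yields
*distinct*, mirroring the motivating study's insistence on concordant,
independent evidence.

## Known limitations

* Single-ratio extraction only: the sequential multi-ratio extension of
  the LDA ratio extractor is out of scope.
* No canonical-variates analysis across more than two groups; "rest"
  comparisons concatenate specimens without reweighting.
* The closed-form GTR estimator shares the usual log-det-type failure
  mode at saturation; it flags rather than extrapolates.
* The generators' realism limits above apply to every green test based on
  them.
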