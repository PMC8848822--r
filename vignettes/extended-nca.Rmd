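---
title: "Extended necessary condition analysis: necessity, sufficiency, and their difference"
author: "ncax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended necessary condition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncax)
```

## The model

Necessary condition analysis (NCA) asks a different question than
correlation or regression: not whether high x *tends to go with* high y, but
whether a low value of x *precludes* a high value of y. Operationally, plot
y against x and look at the upper-left corner of the scatter. If x were
necessary for y, cases with low x and high y could not exist, and that
corner would be empty.

The analysis quantifies this with three ingredients:

* **Scope.** The empirical bounding rectangle
  $[x_{\min}, x_{\max}] \times [y_{\min}, y_{\max}]$ spanned by the observed
  minima and maxima of both variables, with area
  $S = (x_{\max}-x_{\min})(y_{\max}-y_{\min})$. The scope is always
  empirical, never the theoretical range of a measurement scale: the
  effect size should describe the data at hand, and theoretical bounds that
  no observation attains would dilute it arbitrarily.
* **Ceiling.** An upper envelope $c(x)$ of the occupied region. The default
  CE-FDH (ceiling envelopment, free disposal hull) ceiling is the running
  maximum $c(x) = \max\{y_i : x_i \le x\}$ — the lowest non-decreasing,
  right-continuous step function with no observation strictly above it. The
  observations generating its jumps (the non-dominated upper-left points)
  are the *peers*. The alternative CR-FDH ceiling is the ordinary
  least-squares line through those peers, clamped to the scope rectangle
  when it leaves it.
* **Effect size.** $d = C / S$, where $C$ is the area of the empty ceiling
  zone $\{(x,y) \in \text{scope} : y > c(x)\}$. By construction
  $0 \le d \le 1$: 0 means no empty corner at all, 1 would mean a fully
  empty scope.

The **necessity effect of x on y** uses the upper-left corner. The
**sufficiency effect of x on y** is the empty lower-right corner below the
floor line, and is *identical* to the necessity effect of y on x; the
package computes it exactly that way, by swapping the axes. This identity is
also a logical one: if x were necessary but not sufficient for y, there
would be no (low x, high y) cases but some (high x, low y) cases, so y could
not be necessary for x but would have to be sufficient for x.

A significant necessity effect alone therefore does not establish that x is
"necessary but not sufficient" — it only indicates some non-random
association. The extension implemented here computes *both* directions and
their difference, which supports more specific conclusions.

## Inference

**Permutation test per effect.** The y values are shuffled against the
fixed x values (equivalently, the pairing is broken) `n_permutations` times
(default 10,000), d recomputed each time, and the p-value is the
add-one-smoothed upper tail,

$$p = \frac{\#\{d^{\pi} \ge d_{\text{obs}}\} + 1}{K + 1}.$$

The smoothing keeps p strictly positive with finite permutations, which a
raw proportion does not; ties ($d^{\pi} = d_{\text{obs}}$, common with
discrete data) count toward the tail, the conservative choice. The scope is
invariant under permutation because the marginal value multisets are
unchanged, so only the ceiling is recomputed. Permuted statistics are
compared with a $10^{-12}$ tolerance so that floating-point rounding cannot
turn an exact tie into a strict inequality.

**Bootstrap difference test.** The rows are resampled with replacement
`n_bootstrap` times (default 10,000) and the difference
$d_{\text{nec}} - d_{\text{suf}}$ computed in each resample. The reported
difference is the *mean* of the bootstrap differences, its standard error
their sample standard deviation, $Z = \text{mean}/\text{SE}$, and the
p-value the two-sided standard-normal tail. The plug-in difference on the
observed sample is reported alongside; the bootstrap mean is the headline
number because it, not the plug-in value, is what the Z statistic tests.
Two-sided is the natural choice because the difference has no privileged
sign. Resamples with a degenerate scope (zero range in either variable,
possible at small n) are skipped and counted rather than raised: a failed
resample is an event of the resampling distribution, not a user error. If
the difference is constant across resamples the SE is zero, Z is undefined,
and p is reported as 1 with a flag.

**Interpretation layer.** With significance level `alpha` (default 0.05):

* neither effect permutation-significant → `no_nonrandomness`; nothing can
  be claimed;
* difference not significant → `equal_degrees`;
* difference significant → `necessity_dominant` or `sufficiency_dominant`
  by the sign of the bootstrap mean.

The `guard_ok` flag records whether the *stronger* of the two effects is
itself permutation-significant; a difference verdict should not be trusted
without it. When the sufficiency effect of x on y (equivalently the
necessity effect of y on x) is significant, the report carries a note that
this is logically incompatible with reading x as "necessary but not
sufficient" for y.

**Reproducibility.** `run_extended_nca()` derives sub-seeds for the
permutation tests and the bootstrap deterministically from one master seed;
the same seed gives a bit-identical report. The two permutation tests share
one sub-seed deliberately: with that convention, swapping the input axes
exactly swaps the necessity and sufficiency blocks of the report and
negates Z, a symmetry the test suite asserts bit-for-bit.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `technique` | `"ce_fdh"` | ceiling estimator; `"cr_fdh"` fits a line through the CE-FDH peers. The step ceiling is the more literal reading of "no point above the ceiling" and is the default; the regression line smooths single influential peers at the cost of allowing observations above the line. |
| `n_permutations` | 10,000 | permutation-null resolution; the smallest attainable p is $1/(K+1)$. |
| `n_bootstrap` | 10,000 | bootstrap resolution for the difference distribution. |
| `alpha` | 0.05 | significance level used by the guard and the interpretation. |
| `seed` | 1 | master seed; all randomness derives from it. |

With fewer than two distinct peers no CR-FDH line exists; the CE-FDH step
is used instead with a warning (silently inside resampling loops, where the
event is routine).

## Numerical choices

All areas are closed-form rectangle or trapezoid sums — never numerical
quadrature — so effect sizes are deterministic to machine precision and the
exactness claims in the tests are meaningful. Ties in x are absorbed by the
running maximum (the within-tie maximum defines the step); the data are
never jittered, since jitter would perturb areas. Affine rescaling of
either axis (positive slope) cancels in $C/S$ and leaves d unchanged.
Degenerate scope (zero range in x or y) is a named error: the effect size
is undefined there, not zero.

## The synthetic generators

The generators exist so every inference path can be exercised with known
ground truth, without any external data. All live on the unit square with a
target empty-corner fraction `ceiling_fraction` (written f below):

* `necessity_only`: points uniform below the straight ceiling line
  $y = (1-2f) + 2fx$, whose excluded upper-left triangle has area f
  (feasible for f ≤ 0.5). The points (0, 0) and (1, 1−2f) are pinned so the
  x-range and the y-minimum of the empirical scope do not fluctuate; the
  empirical y-maximum stays random.
* `sufficiency_only`: the axis swap of `necessity_only` at the same seed.
* `both`: points uniform on the band $|y - x| \le 1 - \sqrt{2f}$, leaving
  empty triangles of area f in both corners (f < 0.5); (0,0) and (1,1)
  pinned.
* `independent`: uniform on the square with all four corners pinned. The
  pinned corners make both empty-corner areas exactly zero — useful as a
  hard null for the geometry. For calibrating test size, plain iid uniform
  pairs (no pinning) are the right null and are what the calibration tests
  use, since pinned corners force the observed statistic to its floor.
* `swap_symmetric`: the union of a uniform random set and its axis-swap
  image, so necessity and sufficiency effects are equal by construction and
  the difference statistic is symmetric about zero.

Corner pinning is a fixture choice, not a claim about real data: without
pinned extremes the empirical scope fluctuates and the target fraction is
ill-defined at finite n. Uniform base distributions keep the excluded
areas analytic.

**What recovery looks like.** For `necessity_only` the CE-FDH estimate
converges to f as n grows, with $O(n^{-1/2})$ error (roughly halving per
fourfold n). The finite-n bias is slightly *positive*: the step ceiling
lies below the true line, so the measured empty zone exceeds the excluded
triangle by the mean step-to-line gap, which outweighs the opposing
shrinkage of the empirical y-maximum. At f = 0.5, n = 5000 the estimate
sits a little above 0.50 across seeds.

**What the generators do not emulate:** discrete Likert-type marginals,
heteroscedastic noise, outliers, or the marginal distributions of any real
instrument. Passing recovery tests shows the estimator recovers known
uniform-support geometry, not that real psychological scales satisfy those
assumptions.

## Problem sizes used by the test suite

The suite checks geometry exactly (hand-computed worked examples), checks
areas against a 2000×2000 grid-counting oracle on random small samples,
compares sampled permutation p-values with exhaustive enumeration at n ≤ 6,
calibrates the permutation test's type-I error with 400 independent
replicates (n = 100, 200 permutations each), and exercises recovery at
n = 5000. These sizes keep the whole suite at desk scale while leaving
Monte-Carlo error well inside the asserted bands.

## Limitations

* Only the bivariate, single-determinant analysis is implemented: no
  bottleneck tables, multiple simultaneous determinants, CE-VRS or
  quantile-regression ceilings.
* No confidence intervals for d, and no multiple-testing correction across
  rows when several determinants are analyzed separately.
* The bootstrap Z-test assumes approximate normality of the bootstrap mean;
  at very small n (where many resamples are degenerate and skipped) the
  normal tail is a rough guide.
* d compares empty-area magnitudes; it says nothing about the mechanism
  behind the emptiness. The interpretation layer deliberately reports
  `no_nonrandomness` rather than "no effect" when neither test rejects.
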