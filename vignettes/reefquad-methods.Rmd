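---
title: "Methods: from photoquadrat pixels to benthic cover trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from photoquadrat pixels to benthic cover trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefquad)
```

reefquad implements a complete photoquadrat monitoring workflow for coral
reef benthos: image preparation (frame rectification, color balancing),
confidence-gated point annotation, percent-cover estimation, beta-GAM trend
modeling, and community ordination. Every stage can be exercised end-to-end
on synthetic imagery and simulated cover series with known ground truth.
This vignette explains the models and procedures, the parameters that
matter, the numerical choices, and what the synthetic tests do and do not
demonstrate about field data.

## The synthetic scene generator

`render_quadrat()` emulates the properties of field photoquadrats that the
downstream stages depend on, and nothing more:

* **Spatially coherent class regions.** Benthic classes are laid out as
  random Voronoi patches rather than per-pixel noise, because point
  sampling must encounter contiguous organism patches as it does on a real
  reef. Pixel counts per class are apportioned exactly (largest-remainder
  rounding) over the frame interior, so ground-truth fractions are known to
  one pixel.
* **A near-white PVC frame** (channel values at least 240 before the color
  cast) as a band of configurable thickness at a rotation up to ±20°. The
  brightness separation from scene colors (capped at 235) is what makes
  threshold-based detection possible, mirroring how a white PVC frame
  stands out against benthos.
* **A green/blue color cast** applied additively after scene composition,
  and an optional overexposure gain, emulating underwater attenuation of
  red light and poor exposure.

The generator does **not** model optical attenuation physics, lens or
perspective distortion, blur, biological texture, or class boundaries that
follow organism morphology. Tests passing on these scenes demonstrate the
algorithms' correctness against controlled truth; they do not certify
performance on field imagery, where frame occlusion, fouling on the PVC,
and non-uniform lighting degrade detection in ways the generator does not
produce.

`simulate_cover_series()` draws proportional cover from a beta
distribution whose mean follows an inverse-logit trend:

$$\mu_{s,l,t} = \mathrm{logit}^{-1}\!\left(\mathrm{logit}(b_l) + \beta_l
(t - t_0) + u_{s,l}\right), \qquad y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$$

with per-label baselines $b_l$ (default 0.10), logit-scale slopes per year
$\beta_l$ (optionally reef-type-specific), site intercepts
$u_{s,l} \sim N(0, 0.3^2)$, and precision $\phi = 30$ (beta SD about 0.05
at 10% mean cover — the between-image spread typical of 25-point counts).
These defaults are the simulation conditions used throughout the test
suite; they were fixed once as field-plausible values.

## Frame rectification

The frame detector thresholds near-white pixels (all three channels at or
above `brightness_threshold`, default 200), keeps the largest connected
component (connected-component labeling via EBImage), and estimates the
rotation as the angle in [−20°, 20°] minimizing the area of the
component's bounding box — the minimum-area bounding rectangle of a
rectangular band is aligned with it. The search runs coarse (0.5°) to fine
(0.02°) on the component's convex hull, so it costs microseconds. The
interior crop is found by scanning outward from the band's center in the
derotated mask, then shrunk by a 2 px safety margin so interpolation blur
at the band's inner edge cannot leak into the crop. Detection confidence
is the fraction of a mid-band perimeter rectangle covered by bright
pixels; below `min_band_fraction` (default 0.6) a catchable
"frame not found" condition is raised, which the batch driver uses to pass
frameless (post-2014-style) imagery through untouched.

Rotation uses vectorized bilinear interpolation with edge-reflection
padding; a zero-angle rotation short-circuits, making the pure-crop path
bit-exact. Bilinear interpolation is a convex combination, so rectification
can never extend the channel value range.

On the synthetic sweep (9 angles × 20 seeds), angle recovery is exact to
the 0.02° search grid and frame contamination of the crop is zero; the
test thresholds (mean absolute error ≤ 0.5°, contamination ≤ 0.5%) leave
headroom for the interpolation and mask quantization effects that appear
at other image sizes.

## Color balancing

The operator is deliberately simple and literal: raise every pixel's red
value by a constant per-image offset proportional to the mean green/blue
level, then scale all channels by $1 - \beta$:

$$R' = R + \alpha\,\frac{\bar G + \bar B}{2}, \qquad
(R'', G'', B'') = (1-\beta)\,(R', G, B)$$

with rounding half-up and clipping to [0, 255] after each step, operating
on raw 8-bit sRGB values without gamma linearization. The additive
(rather than multiplicative) red shift is the most direct reading of
"raise red in proportion to the average green and blue"; $\alpha$ (default
0.3) and $\beta$ (default 0.1) are explicit, echoed into output metadata,
because a correction that cannot be reproduced is useless for monitoring
time series. `suggest_alpha()` gives the closed-form gain
$\alpha^* = (\bar G + \bar B - 2\bar R)/(\bar G + \bar B)$ that equalizes
the red mean to the green/blue level, and `cast_reduction_score()`
quantifies the cast gap change so overshoot is detected rather than
rewarded. This is an annotation aid, not physics-based attenuation
correction.

## Point annotation and confidence gating

Points are sampled uniformly **without replacement** at pixel granularity
(duplicates add no information). The label schema carries eight broad
benthic functional groups plus three quality labels (shadow, transect
tape, unidentifiable) that flag unscorable points.

The machine/human split is a threshold on classifier confidence. A point
at *exactly* the threshold is auto-scored — with both "over 50%" and
"under 50%" in common protocol descriptions, the exact-50% case is
genuinely ambiguous, and ties-to-the-machine makes the auto set the
superlevel set of a closed threshold; the threshold is configurable for
anyone who wants the opposite convention. Project-level confidence counts
manually scored points at 1.0 (a human call is treated as certain), which
is the only convention under which adding manual effort to a
low-confidence project raises the reported figure, as it should.

The simulated classifier is a test stand-in, not a model of any real CNN:
correct with probability `accuracy`, otherwise a uniformly wrong benthic
label, with confidence drawn from Beta(8, 2) when right and Beta(2, 3)
when wrong. Passing gates and cover tests under this stub says nothing
about real classifier accuracy — that is exactly why accuracy and the
confidence distributions are explicit parameters.

## Cover estimation

Per-image cover is the point-count fraction after removing quality-label
points and renormalizing the denominator. The renormalization is a
documented assumption: standard point-count practice, and the only rule
under which per-image benthic covers sum to 1 (asserted on every synthetic
run).

For a site-year with far more images than the standard replication, the
resampling procedure draws `n_sub = 20` images without replacement per
iteration and returns per-label medians across `n_iter = 1000` iteration
means. Label-wise medians need not sum to 1; they are reported as-is with
a flag rather than silently renormalized, because the procedure is defined
label-wise. Images are put in canonical (sorted) order before subsampling,
so the result is invariant to input row order under a fixed seed.

The image-area bias check regresses per-image cover of each label with
mean cover above 1% on log10 area by OLS. It is a screening device: a null
outcome across labels justifies analyzing raw cover when image footprints
vary.

## Trend models

Cover trends are modeled at the image level with a beta-distribution GAM
(logit link), fitted by REML via mgcv:

```
cover* ~ reef_type + s(year, by = reef_type, k = 5) + s(locality, bs = "re")
```

* **Boundary squeeze.** The beta likelihood excludes exact 0/1, so the
  response is first transformed with $p^* = (p(n-1) + 0.5)/n$, where $n$
  is the number of rows entering the model (recorded in the fit). The
  transform is strictly interior, monotone, and fixes 0.5.
* **Why image-level rows.** Fitting site-year means would leave 30
  observations against ~10 coefficients; measured null simulations at that
  size reject smooth terms at 12–14% instead of 5%. At image-level
  replication the tests are approximately calibrated.
* **Why no redundant global smooth.** A model containing both a global
  `s(year)` *and* a separate smooth per reef type is exactly concurve: the
  shared trend can sit in either place, and in null simulations the
  term-wise tests become pathological (effective degrees of freedom near
  zero with enormous test statistics, rejection rates of 16–31%). The
  default model therefore carries one smooth per reef type — "a separate
  smoothed function for forereef and patch reefs through time" — which is
  identifiable and calibrated. `global_smooth = TRUE` reproduces the
  redundant structure for comparison with legacy outputs, with this caveat
  documented.
* **Basis dimension.** `k = 5`, capped at the number of distinct years
  (five survey years cannot support more).
* **Random effect.** Locality enters as a penalized random-intercept term
  (`bs = "re"`); with a single locality it is dropped with a warning.
* **Calibration in practice.** mgcv's smooth p-values are approximate.
  Across 1000-replicate null simulations at this design the per-term
  rejection rate at $\alpha = 0.05$ is about 5–7% depending on replication
  level — adequate for trend screening, but worth remembering when a
  p-value sits near the boundary. Power for a forereef-only logit trend of
  +0.25/yr at the 6-site × 5-year × 20-image design exceeds 90%, with the
  patch-reef smooth staying null.

Non-convergence raises an explicit error carrying the deviance;
back-transformed fitted curves are produced per reef type with 95%
intervals on the link scale, excluding the locality effect.

`fixed_transect_sensitivity()` refits on fixed-transect sites only,
dropping the reef-type terms (under the default manifest both fixed sites
are forereefs, so a single type remains).

## Community ordination

The community matrix is site-year × functional group with entries
$\sqrt{\text{mean cover}}$. NMDS uses Bray–Curtis dissimilarity by default
(the community-ecology convention for cover data; Euclidean is available)
through vegan's `metaMDS` with 20 seeded random restarts; stress is
reported with the conventional interpretation band (0.1–0.2 read as good
to excellent).

The RDA and its permutation ANOVA are implemented natively. Terms
(reef type, locality, year — year as a numeric covariate) are added
sequentially; each term's constrained variance is the squared norm of the
response projected onto the orthonormal increment of its design columns
(QR decomposition), so constrained plus residual variance equals the total
exactly, and a term adding no rank raises an error naming it. Significance
uses unrestricted row permutation of the response with pseudo-F statistics:
$p = (1 + \#\{F^{perm} \ge F^{obs}\})/(1 + n_{perm})$, giving a p-value
floor of $1/(n_{perm}+1)$ — 1/1000 at the default 999 permutations. Rows
are canonically sorted by site and year before analysis so p-values are
exactly invariant to input row order. The variance partition and
F statistics are verified against vegan's `rda`/`anova.cca` to 1e-10 in
the test suite; the permutation machinery itself is this package's own.

Permutation is unrestricted (no blocking): with locality in the model this
tests the omnibus exchangeability null term-by-term, which is the
appropriate reading when no permutation structure is specified. Both the
dissimilarity and the permutation scheme are configurable assumptions, not
claims about any particular historical analysis.

## Problem sizes used in the test suite

Simulation-based checks use sizes chosen to balance Monte-Carlo precision
against desk-scale runtimes: the rectification sweep runs 9 angles × 20
seeds at 320 px; GAM null calibration uses 500 replicates at 5 images per
site-year and power 200 replicates at the full 20; RDA calibration uses
500 datasets at 199 permutations (p-value validity is exact for any
permutation count), with the 1/1000 floor asserted at 999; cover
unbiasedness uses 10⁴ points. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch under
a caller-supplied seed.

## Known limitations

* Frame detection assumes a rectangular band brighter than everything else
  in the image; heavy overexposure (gain pushing scene pixels past the
  threshold) or a fouled, dim frame will defeat it. No perspective or
  lens-distortion correction is attempted.
* The color balancer is a fixed two-step operator on raw pixel values; it
  is not a colorimetric correction.
* The beta GAM treats image-level covers as conditionally independent
  given site and year; within-transect spatial autocorrelation is not
  modeled.
* Smooth-term p-values are approximate (mildly liberal, ~5–7% at nominal
  5% in this design); they should be read as screening statistics.
* The simulated classifier's confidence model is a stub for testing the
  gating logic, not a calibration model for any real classifier.
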