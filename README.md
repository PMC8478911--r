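# reefquad

Reef monitoring programs photograph the seafloor along transects
("photoquadrats") and estimate benthic cover — the fraction of substrate
occupied by corals, algae, sponges and other functional groups — by
classifying the organisms under randomly placed points in each image.
Before scoring, field imagery usually needs preparation: early surveys
framed each shot with a white PVC quadrat that must be detected, the image
rotated square and cropped to the frame's inside edge, and the green/blue
underwater color cast corrected. After scoring, ecologists need defensible
statistics for questions like *is stony coral cover increasing on the
forereefs?* and *has the whole community shifted?*

reefquad implements that entire workflow as an R package, for reef
ecologists and monitoring-program analysts:

* **Synthetic data with known truth** — renderable quadrat scenes (Voronoi
  class patches, rotated PVC frame, color cast) and beta-distributed cover
  time series, so every stage is testable without downloading imagery.
* **Frame rectification** — near-white thresholding, largest connected
  component, rotation by minimum-area bounding box search, inside-edge crop.
* **Color balance** — `R' = R + α(Ḡ+B̄)/2`, then all channels scaled by
  `1 − β`; rounded half-up, clipped to [0, 255].
* **Confidence-gated annotation** — uniform random points, a simulated
  classifier stand-in, auto-scoring at confidence ≥ threshold (default
  0.5) with the rest queued for manual labels; CoralNet-style CSV
  interchange.
* **Cover statistics** — per-image point-count cover with quality-label
  exclusion, site-year means ± SE, the n = 20 × 1000-iteration resampling
  median, and an image-area bias regression against log10 area.
* **Trend models** — image-level beta GAM (logit link) per functional
  group: `cover* ~ reef_type + s(year, by = reef_type, k = 5) +
  s(locality, bs = "re")`, with the boundary squeeze
  `p* = (p(n−1)+0.5)/n`, plus a fixed-transect-only sensitivity refit.
* **Community ordination** — square-root cover matrix, Bray–Curtis NMDS
  with stress, and a native RDA with sequential pseudo-F statistics and
  permutation ANOVA (999 permutations, p-floor 1/1000).

See `vignettes/reefquad-methods.Rmd` for the models, assumptions, and
numerical choices.

## Worked example

```r
library(reefquad)

## render a quadrat with an 8°-rotated frame, rectify, and balance it
spec <- scene_spec(width_px = 320, height_px = 320,
                   class_fractions = c(SC = 0.25, MA = 0.15, SA = 0.35, CS = 0.25),
                   frame_rotation_deg = 8, seed = 42)
sc  <- render_quadrat(spec)
det <- detect_frame(sc$image)
det
#> <frame_detection> rotation -8.00 deg, confidence 1.00
#>   inner bbox (top,left,bottom,right): 52 52 268 268
quad <- rectify_and_crop(sc$image, det)
bal  <- balance(quad, alpha = suggest_alpha(quad), beta = 0.1)
cast_reduction_score(quad, bal)
#> [1] -0.95
```

The detector recovered the −8° correction exactly and the crop contains no
frame pixels; the negative cast score says the red/green-blue gap shrank.

```r
## score 25 points with a simulated 90%-accurate classifier, gate at 0.5
pts   <- generate_points(bal, 25, seed = 7, image_id = "demo")
annot <- simulated_classifier(pts, sc$truth, accuracy = 0.9, seed = 8)
fin   <- score_points(annot, sc$truth, threshold = 0.5)
table(fin$status)
#>   auto manual
#>     24      1
round(overall_confidence(fin), 3)
#> [1] 0.782
subset(image_cover(fin), cover > 0)
#>   image_id label      cover n_points_included
#> 1     demo    MA 0.33333333                24
#> 3     demo    SC 0.16666667                24
#> 5     demo    SP 0.04166667                24
#> 6     demo    SA 0.33333333                24
#> 8     demo    CS 0.12500000                24
```

24 of 25 points cleared the 0.5 confidence gate; one was manually scored
(counted at confidence 1.0 in the overall figure). With only 25 points the
cover estimate is noisy around the true fractions (SC 0.25, MA 0.15,
SA 0.35, CS 0.25) — per-image counts are meant to be averaged over a
transect.

```r
## fit the cover trend model to a simulated survey:
## forereef-only logit trend of +0.25/yr, 6 sites x 5 years x 20 images
man <- default_site_manifest()
d <- simulate_cover_series(6, c(2014, 2016:2019),
                           trend = list(SC = c(patch = 0, forereef = 0.25)),
                           reef_types = setNames(man$reef_type, man$site),
                           seed = 1, n_images = 20)
fit <- fit_trend_gam(d, label = "SC")
summary(fit)
#> Term tests (n = 600, deviance explained = 64.0%)
#>                       term       type statistic   p_value      edf
#>                (Intercept) parametric   -7.3813 1.568e-13       NA
#>             reef_typepatch parametric   -3.4896 4.837e-04       NA
#>  s(year):reef_typeforereef     smooth  210.4300 0.000e+00 1.444003
#>     s(year):reef_typepatch     smooth    4.0231 4.496e-02 1.000843
#>                s(locality)     smooth  193.5600 0.000e+00 3.902553
round(subset(fit$curves, reef_type == "forereef"), 3)
#>    year  mean  lo95  hi95
#>  1 2014 0.118 0.084 0.164
#>  2 2016 0.175 0.128 0.235
#>  3 2017 0.210 0.155 0.277
#>  4 2018 0.247 0.185 0.321
#>  5 2019 0.286 0.216 0.367
```

The forereef smooth carries the injected trend (χ² = 210, p < 1e-16) and
the back-transformed forereef curve climbs from 12% to 29% cover; the
patch smooth is only marginal at this seed, and the parametric reef-type
contrast and locality random effect absorb level differences among reefs.

```r
## community-level shift: sqrt-cover matrix, NMDS, RDA + permutation ANOVA
d1 <- simulate_cover_series(6, c(2014, 2016:2019),
                            trend = c(SC = 0.3, MA = -0.2, OCT = 0, SP = 0,
                                      CS = -0.15, LTA = 0),
                            reef_types = setNames(man$reef_type, man$site),
                            seed = 4)
agg <- data.frame(site = d1$site, year = d1$year, reef_type = d1$reef_type,
                  label = d1$label, cover = d1$cover)
m <- build_matrix(agg)
run_nmds(m, seed = 2)
#> NMDS (bray distance): 30 points, stress = 0.204 (usable with caution)
rda_perm_anova(m, n_perm = 999, seed = 3)
#> RDA permutation ANOVA (n_perm = 999)
#>       term df   variance proportion       F p_value
#>  reef_type  1 0.00078288    0.01162 0.46349   0.809
#>   locality  4 0.01234000    0.18320 1.82640   0.024
#>       year  1 0.01539200    0.22850 9.11230   0.001
#> Residual variance 0.038849 on 23 df (total 0.067364)
```

The injected year shift dominates the community matrix: the year term
explains 23% of community variance at the permutation floor p = 0.001,
while reef type explains ~1% here because the simulated shift was applied
to both reef types equally.

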