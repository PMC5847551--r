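---
title: "Methods: quantifying artificial light at night within species ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying artificial light at night within species ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightrange)
```

# Scope and data model

`nightrange` analyses a time-ordered stack of single-band nighttime-light
composites (digital numbers, DN 0–63, 63 = sensor saturation) against a set
of species range polygons carrying IUCN category and a used-by-people flag.
All layers must share one equal-area grid (`grid_spec`): equal-area pixels
make counts proportional to area, so lit-pixel fractions are area fractions.
The pipeline never resamples; inputs on different grids are an error, and
reprojection is treated as an I/O-boundary concern outside the computational
contract.

Rasters are exchanged as plain-text ESRI ASCII grids and vectors as GeoJSON.
This keeps the package free of compiled geospatial dependencies; the ASCII
format restricts I/O to square pixels, though the in-memory `grid_spec`
carries width and height separately.

Row/column indices are 0-based with pixel (0, 0) at the top-left; map
intervals are half-open, so a point on a shared pixel edge belongs to the
pixel with the larger index. A pixel belongs to a rasterized range when its
*center* lies inside the polygon (even-odd rule); a range too small to
capture any center receives the single pixel containing its centroid. The
centroid fallback is why the smallest possible range mask is exactly one
pixel, matching range-size tables whose minimum is 1. The rasterizer is
validated against an exhaustive, independently coded winding-number oracle
over every pixel center.

# Intercalibration

Stable-lights composites from different satellite-years are not
radiometrically comparable. Each year is mapped onto a configurable
reference year (default: the middle of the stack, minimizing extrapolation
at both ends) through a second-order polynomial

$$ \mathrm{DN}_{ref} = c_0 + c_1\,\mathrm{DN} + c_2\,\mathrm{DN}^2 $$

fitted by *quantile regression through the median*: the coefficients
minimize the sum of absolute residuals. The L1 objective is what buys
robustness — pixels that genuinely changed between the two years act as
outliers, and a median fit ignores them where an ordinary least-squares
quadratic would be dragged along (the test suite demonstrates this failure
of OLS on contaminated data).

Delimiting truly change-free "stable areas" by hand is unreliable, so the
default stable-pixel set is simply every pixel lit in both years, relying on
the robust fit; optional trimming iteratively drops pixels whose absolute
residual exceeds `k` (default 3) median absolute deviations and refits, at
most 5 rounds. Fewer than 30 usable pixels is an error (`calibrate_stack()`
can instead pass such years through uncalibrated with a warning when
`fallback_identity = TRUE`, which the pipeline enables so fully dark or
fully saturated worlds still flow end to end).

## Numerical choices

The L1 fit is solved by iteratively reweighted least squares with weights
$1/\max(|r_i|, 10^{-6})$, stopping when the objective improves by less than
a relative $10^{-8}$ (inside the contracted $10^{-6}$), at most 200
iterations, keeping the best iterate. The solver is deterministic for fixed
input. On data admitting an exact fit (e.g. identity) the solution is exact
to machine precision.

Applied calibration clamps to $[0, 63]$, keeps fractional values (no
re-rounding), and maps DN = 0 to 0 regardless of the intercept: a truly dark
pixel must never acquire light from a calibration constant. A fitted map
that is non-monotone on $[0, 63]$ (possible when $c_2 < -c_1/126$) triggers
a warning.

A genuinely quadratic sensor distortion has a non-quadratic inverse, so
exact coefficient recovery from noiseless data holds only for affine
distortions; for mild quadratics the fitted map inverts the distortion to
within ~0.1 DN RMS over the full DN span. The tests check affine recovery at
$10^{-3}$ and quadratic recovery by composition. Calibrating an
already-calibrated stack is idempotent up to errors-in-variables
attenuation, which is zero in the noiseless case and well under 1.5 DN at
1 DN observation noise.

# Exposure statistics

*Lit* means DN ≥ 5.5; darkness is strictly below. The 5.5 DN default is
twice the detection limit for on-the-ground-attributable DN change, a
conservative bound; it is a parameter (`threshold`) throughout.

Period summaries average the calibrated stack per pixel over the first five
and last five years and threshold the *mean image* — the threshold is
applied after averaging, following the order of operations of the analysis
this package re-implements (average, then extract). An annual
mean-of-fractions alternative can be assembled from the per-year table; with
growing light the period-mean convention is slightly more inclusive at the
fringe. Per species we report pixel counts, lit counts and fractions, mean
and summed DN per year and per period, and the all-years average DN as the
mean over years of the per-year range-mean DN (smoother than any single
year).

The evenness statistic sorts a range's DN descending and reports the
smallest $k/n$ whose cumulative sum reaches 95% of ΣDN. It equals
$\lceil 0.95 n \rceil / n$ for a uniformly lit range and decreases strictly
as light concentrates. For a fully dark range (ΣDN = 0) it is reported
*undefined* rather than 0 or 1 — the statistic has no meaning without light.
Ties need no special rule: the result depends only on the multiset of
values.

# Trend tests

`mann_kendall()` is implemented from first principles:
$S = \sum_{i<j}\mathrm{sign}(x_j - x_i)$, tie-corrected variance
$[n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18$ over tie groups of size $t$,
tau as tie-adjusted tau-b (count series are tie-heavy, and tau-b is the
convention of the standard Kendall implementations), and a
continuity-corrected normal deviate. A constant series is a valid input
(tau = 0, p = 1), not an error. For tie-free series with $n \le 10$ an
exact p-value is available from the null distribution of $S$, enumerated
via the inversion-count generating function
$\prod_{k=1}^{n}(1 + x + \dots + x^{k-1})$ — the same distribution a full
permutation would produce, without materializing $n!$ permutations; with
ties it falls back to the normal approximation with a warning.

No multiple-testing correction is applied across per-species tests (the
analysis this re-implements applies none); `trend_table(bh = TRUE)` emits
Benjamini-Hochberg q-values for users who want them. Autocorrelation- and
seasonality-adjusted variants are out of scope.

# Richness and correlation

Richness grids count overlapping range masks per pixel, for all species and
for the threatened subset (categories CR, EN, VU). The construction is an
exact overlay: the grid total equals the sum of per-species pixel counts,
and the threatened grid is pixelwise ≤ the all-species grid — both asserted
exactly in the tests.

The headline correlation unit is one point per *occupied richness level*
(mean DN among pixels with exactly $k$ overlapping species), following the
subdivide-richness-into-masks procedure; a per-pixel variant (richness vs DN
across all occupied pixels, much larger $n$) is available behind
`per_pixel = TRUE`. The published analysis names Pearson's correlation but
prints CIs narrower than $n = 82$ levels would give under Fisher z, so the
correlation unit there is ambiguous; both units are provided, neither
asserted as "the" original. Inference is Pearson's $r$ with a Fisher-z 95%
CI ($\tanh(\mathrm{atanh}\,r \pm 1.96/\sqrt{n-3})$) and a $t$-based p-value;
constant input yields a flagged undefined result. Richness classes for
mapping are equal-width integer intervals from 1 of width
$\lceil \max/5 \rceil$ (max 82 → 1–17, 18–34, ...), zero-richness pixels
unclassed.

# Use comparison

Lit proportions are arcsine-square-root transformed
($\arcsin\sqrt{p} \in [0, \pi/2]$, the classical variance-stabilizing
transform) and compared between used and not-used species by a one-factor
linear model — a two-group ANOVA equivalent to the pooled two-sample
t-test, $F = t^2$, df $(1, n-2)$. The dependent variable for the combined
comparison averages the two period-mean lit proportions per species;
per-period results are also emitted. The CI of the group difference is on
the transformed scale; raw-scale group means are reported alongside. (Note
the published df 1,432 is one less than $n - 2 = 1{,}433$ for 1,435 species;
this package reports $n - 2$.)

# The synthetic world

The generator's job is ground truth, not realism. It emulates the features
the pipeline's correctness depends on, with defaults stated once:

* **Grid and span**: 256 × 256 equal-area pixels, 21 annual composites
  (1992–2012 labels).
* **Light**: 25 urban sources with saturated 2-pixel cores (DN 63) and
  brightness decaying at 2.5 DN/pixel down to a dim fringe at 8 DN. The
  bright interior is *constant over time* — the stable areas that real
  intercalibration presupposes — while the fringe radius grows so the lit
  area expands by 5%/year. Every pixel's DN is thus non-decreasing, lit
  area and ΣDN grow monotonically, and the growth is purely peripheral,
  which is what makes the evenness statistic rise for exposed species (new
  dim pixels join the 95% cumulative set). An early version grew light by
  scaling the whole radial profile; that left no stable pixels at all and
  the median fit absorbed genuine change — the fixed-interior design is the
  deliberate correction.
* **Sensor distortion**: per-year quadratic coefficients drawn near
  identity ($c_0 \sim U(-2,2)$, $c_1 \sim U(0.85,1.15)$,
  $c_2 \sim U(-0.003, 0.001)$), the middle year forced to identity, plus
  1 DN observation noise on lit pixels; truly dark pixels are never
  distorted to positive values (stable-lights semantics: no false lights).
* **Species**: 1,435 ranges as axis-aligned ellipses rasterized analytically
  by the pixel-center rule — ground-truth pixel membership is exact by
  construction, with a matching 96-gon polygon attached so the vector I/O
  and rasterization path is exercised too. Range sizes are log-uniform on
  [1, 10⁴] pixels; used and threatened flags are Bernoulli at 838/1,435 and
  417/1,435. Centres cluster (sd 8% of the grid) around 3 hotspots whose
  x-positions are evenly spaced across the western band x ∈ [0.1, 0.6] —
  deterministic spacing, because a fully random placement occasionally put
  every cluster out of reach of the light and left the directional
  statistics undefined.
* **Geography of light vs richness**: urban sources live in x ∈ [0.75, 1],
  far enough east that even the final-year lit footprint stays off the
  high-richness cluster cores while the eastern tails of the clusters and
  the larger ranges still overlap it. Light therefore falls preferentially
  on low-richness cells for *any* seed — the stated precondition of the
  negative richness–brightness result. (With a narrower margin the
  expanding fringe eventually lit the richest cells and the correlation's
  sign became seed-dependent.)

What a green end-to-end test establishes: the pipeline's direction-level
results (more species lit later; positive global trend; spreading light;
negative richness–brightness correlation) on a world built to have them.
What it does not establish: real-world magnitudes. The published percentages
(80.7% → 89.7% of species lit) come from the actual DMSP-OLS and IUCN range
data, where light is vastly more widespread relative to ranges than in this
synthetic geography; here only a few percent of species are exposed, by
construction of the light/richness segregation. The generator also omits
gas flares, inter-annual satellite pairs, cloud artifacts, geolocation
error, and realistic urban-growth morphology. The `used` flag is assigned
independently of geography, so the use comparison is null on synthetic
data — the machinery is validated by its $F = t^2$ identity and null
calibration instead.

All randomness flows through explicit integer seeds (the caller's RNG state
is saved and restored); identical seeds give bit-identical bundles, and a
bundle's JSON config block regenerates it exactly.

# Reproducibility and outputs

`nightrange_run()` orchestrates acquire → calibrate → exposure → table-1
summary → trends → evenness → richness → use comparison, aborting with the
stage named on failure, and (with `out_dir`) writes tidy CSVs, the
calibration model as JSON, and a manifest recording seed, threshold,
periods, and headline statistics. Re-running an identical config reproduces
every table byte-for-byte. The `nightrange` CLI
(`inst/cli/nightrange`) exposes `simulate`, `calibrate`, `exposure`,
`trend`, `richness`, `compare-use` and `run --config cfg.json`.

# Known limitations

* No skyglow propagation: stable-lights composites record sources, not
  scattered brightening, so exposure is conservative near lit areas.
* Sub-pixel light attribution is not modelled; a "lit pixel" may be an
  isolated light rather than pixel-wide illumination.
* No spatial-autocorrelation adjustment in the richness correlation and no
  phylogenetic correction in the use comparison (matching the analysis this
  package re-implements).
* The ASCII-grid I/O path requires square pixels.
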