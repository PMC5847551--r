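# nightrange

Quantifying artificial light at night (ALAN) within species geographic
ranges from multi-year nighttime-light composite stacks.

## The problem

Satellite stable-lights composites (DMSP-OLS style) record nighttime
brightness as digital numbers (DN) on a 0–63 scale, one annual composite per
year, with bright urban cores saturating at 63. Conservation questions about
how much of a species' geographic range is exposed to ALAN — and how fast
that exposure is growing — require three things the raw data do not provide:

1. **Intercalibration.** Different satellite-years are not radiometrically
   comparable. Each year's composite must be mapped onto a reference year's
   DN scale before any multi-temporal analysis.
2. **Zonal exposure statistics.** Range polygons must be rasterized onto the
   composites' common equal-area grid and summarized per species.
3. **Trend and pattern inference.** Monotonic-trend tests on lit-pixel
   series, richness–brightness correlations, and group comparisons.

`nightrange` implements this pipeline end to end, together with a synthetic
nightscape-and-ranges generator with exact ground truth, so that every stage
is testable without any external download.

## Methods at a glance

* **Intercalibration** fits, for each year, a second-order polynomial
  `DN_ref = c0 + c1·DN + c2·DN²` by *quantile regression through the median*
  (minimizing the sum of absolute residuals), which is insensitive to the
  outlying values that distort ordinary least squares. Stable pixels default
  to all pixels lit in both years; optional MAD trimming refines them.
  Calibrated DN are clamped to `[0, 63]`, kept fractional, and truly dark
  pixels (DN = 0) are never mapped to positive values.
* **Lit classification** uses a darkness threshold of DN < 5.5 (twice the
  detection limit for DN change): a pixel at 5.5 is lit. Per species we
  report the lit-pixel count and proportion, mean and summed DN, per year
  and for two period-mean images (first and last five years).
* **Evenness** is the smallest fraction of a range's pixels whose descending
  cumulative DN reaches 95% of the range's ΣDN; small values mean light
  concentrated in few pixels. Undefined for fully dark ranges.
* **Trends** use the Mann-Kendall test built from first principles:
  `S = Σ_{i<j} sign(x_j − x_i)`, tie-corrected
  `var(S) = [n(n−1)(2n+5) − Σ_t t(t−1)(2t+5)]/18`, tie-adjusted tau-b, and a
  continuity-corrected normal deviate (exact small-n option for tie-free
  series).
* **Richness** grids count overlapping ranges per pixel (all species and the
  CR/EN/VU threatened subset); occupied richness levels are correlated with
  mean DN by Pearson's r with a Fisher-z 95% CI.
* **Use comparison** is a one-factor linear model (two-group ANOVA,
  `F = t²`) on arcsine-square-root transformed lit proportions of species
  used vs not used by people.

## Worked example

```r
library(nightrange)

# the default synthetic world: 256 x 256 equal-area grid, 21 annual
# composites (1992-2012), 25 growing urban light sources, 1,435 species
# ranges clustered around western richness hotspots, per-year quadratic
# sensor distortion with 1 DN observation noise
res <- nightrange_run(run_config(seed = 1L))
print(res)
```

prints (abridged; the run takes ~15 s):

```
<nightrange_results>
  years 1992-2012, 1435 species
  1992: 2.0% with lit pixels, 0.1% fully lit, 98.0% dark
  ...
  2012: 5.3% with lit pixels, 0.4% fully lit, 94.7% dark
  global trend: tau = 1.00, p = 2.77e-10; per-species +69/-0/none 1366
  spread increased for 93.9% of species
  richness-brightness all|2008-2012: r = -0.555 (-0.675, -0.408)
  use comparison (last period): F(1,1433) = 0.28, p = 0.595
```

Reading the output: the share of species with any lit pixel in their range
grows year on year (2.0% → 5.3%); the across-species mean lit-pixel series
rises monotonically (Mann-Kendall tau = 1, p < 0.001); for 93.9% of exposed
species the 95%-cumulative-DN pixel fraction is higher in 2008–2012 than in
1992–1996 (light spreading through ranges rather than intensifying in
place); and brightness falls with species richness (r = −0.56) because the
generator places urban light away from the richness hotspots. The use
comparison is null here — the generator assigns the `used` flag
independently of geography.

Individual stages are exported (`calibrate_stack()`, `range_exposure()`,
`evenness_95()`, `mann_kendall()`, `build_richness()`, `compare_use()`, ...)
and a CLI wraps them:

```sh
inst/cli/nightrange simulate --out bundle/ --seed 1 --rows 64 --cols 64 --years 10 --species 50
inst/cli/nightrange calibrate --input bundle/ --out calibrated/
inst/cli/nightrange exposure --input bundle/ --ranges bundle/ranges.geojson \
    --out tables/ --periods 1992-1996,1997-2001 --per-year
inst/cli/nightrange run --config cfg.json
```

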