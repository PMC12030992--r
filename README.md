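# fvcdyn

Spatiotemporal analysis of fractional vegetation cover (FVC) dynamics from
annual vegetation-index rasters, written for ecologists and remote-sensing
analysts studying long-term greening/degradation in arid regions. The
package implements the full statistical chain such studies run on a
multi-year NDVI archive:

* **FVC inversion** — dimidiate pixel model,
  FVC = (NDVI − NDVI_soil)/(NDVI_veg − NDVI_soil), endmembers from the
  5th/95th NDVI percentiles, five-level cover grading;
* **trend analysis** — per-pixel Theil–Sen slope
  β = median[(x_j − x_i)/(t_j − t_i)] with the Mann–Kendall test
  (var(S) = n(n−1)(2n+5)/18, continuity-corrected Z, 99% level), graded
  into five trend classes;
* **persistence** — rescaled-range (R/S) Hurst exponent from
  R/S = c·m^H, combined with the trend class into a five-way future-trend
  map;
* **stability** — coefficient of variation (sd/mean) per period with a
  five-level grading, overall and per ecological zone;
* **climate response** — pixelwise first-order partial correlation
  r_xy·z = (r_xy − r_xz·r_yz)/√((1−r_xz²)(1−r_yz²)) of FVC with
  temperature and precipitation, each controlling the other;
* **scale selection** — aggregation to square analysis units, global
  Moran's I (row-standardized contiguity weights, randomization variance)
  and unit CV scanned across candidate scales;
* **driving factors** — the geographical detector family:
  q = 1 − SSW/SST factor detector with optimal discretization (equal
  interval / quantile / geometric / standard deviation × k = 4..8),
  interaction detector with five-way typing, Welch-t risk detector,
  F-ratio ecological detector, overall and per zone;
* **product validation** — MAE/RMSE similarities, R², SSIM, PSNR between
  co-registered products;
* **synthetic data** — seeded generators (exact fractional Gaussian noise
  by circulant embedding, planted trend fields, stratified factor tables
  with analytic q, climate stacks with closed-form partial correlations)
  so every statistic is validated against known ground truth.

Rasters are plain-text ESRI ASCII grids (`read_asc()`/`write_asc()`);
tables are data frames/CSV.

## Worked example

The `analysis/` directory is a numbered workflow over a fully synthetic
scene with known truth. `analysis/01_simulate.R` builds a 60×60 km,
25-year NDVI archive with a planted greening block (+0.004 FVC/yr), a
degrading block (−0.003 FVC/yr), climate stacks with a planted
FVC–temperature partial correlation of 0.5, and a factor table whose
land-use q\* is 0.66. The later scripts recover all of it:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_trends.R
```

prints (abridged):

```
scene: 60x60 pixels, 25 years; planted q (land use) = 0.660; planted FVC~temp partial = 0.50
trend class shares (%):
  Significant decrease  4.1
  Slight decrease       7.6
  Basically unchanged  39.5
  Slight increase      33.4
  Significant increase 15.4
slope recovery: MAE 0.00080 FVC/yr (planted slopes 0, -0.003, +0.004)
greening block detected as increase: 100% of its pixels
mean Hurst exponent 0.67 (noise planted at H = 0.5)
```

The significant-increase share (15.4%) is dominated by the planted greening
block (11% of the scene); the slight classes absorb sampling noise around
zero slope, and the Hurst mean sits above 0.5 by the documented small-sample
R/S bias. `analysis/05_scale_geodetector.R` then ranks the drivers:

```
factor detector q ranking:
   land_use   elevation night_light
      0.649       0.107       0.006
planted land-use q*: 0.660
risk detector: land-use stratum means 0.105, 0.3, 0.595; optimal stratum 3
```

and `analysis/04_stability_climate.R` recovers the climate coupling:

```
mean FVC~temperature partial r: 0.492 (planted 0.50); significant at 5%: 73% of pixels
mean FVC~precipitation partial r: 0.000 (planted 0)
```

From R directly:

```r
library(fvcdyn)
sim <- gen_fvc_stack(shape = c(20, 20), slope_field = 0.004, noise_sd = 0.02)
tr <- trend_stack(sim$stack)
area_fractions(tr$trend_class)
```

See `vignettes/fvc-dynamics-methods.Rmd` for the models, parameter
defaults, and the design decisions behind them.

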