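---
title: "Methods: detecting island building and turbidity plumes from multi-band reflectance time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting island building and turbidity plumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conversion of submerged coral reefs into artificial islands can be monitored
with moderate-resolution satellite reflectance imagery: a newly built island
replaces a dark water target with a bright land target, and the dredging that
builds it throws up sediment plumes that alter the water's spectral
signature. `reefwatch` implements an analysis chain for this problem on time
series of Rayleigh-corrected reflectance (R_rc, dimensionless) in four bands
(469, 555, 645 and 859 nm) mapped at 250-m nominal resolution on an
equidistant cylindrical grid, together with a synthetic scene generator that
makes every stage testable by parameter recovery.

## Radiometric model

**Rayleigh-corrected reflectance.** For each band,

R_rc = pi * Lt\* / (F0 * cos(theta0)) - Rr,

where Lt\* is at-sensor total radiance already adjusted for ozone and gaseous
absorption, F0 the extraterrestrial solar irradiance (Earth-sun distance
correction folded into F0 by the caller), theta0 the solar zenith angle and
Rr the Rayleigh reflectance. The operation is linear in Lt\* and errors when
theta0 >= 90 degrees. Adjusting Lt for gaseous absorption is upstream
processing and out of scope.

**Sunglint correction.** Glint adds a spectrally shaped copy of a
non-negative magnitude field to every band, with the 859-nm multiplier
defined as 1. For pixels with R_rc(859) > 0.01, the 469 and 645 nm bands are
rescaled by subtracting the NIR signal scaled by per-band coefficients
C(469) = 0.67 and C(645) = 0.94. The exact functional form was a genuinely
open choice (whether the subtraction uses C * R_rc(859) or
C * (R_rc(859) - trigger)); we adopt plain C * R_rc(859) subtraction, the
standard NIR-based deglint construction. Pixels at or below the trigger are
left untouched, so a small residual glint error (at most
|C(469) - C(645)| * trigger = 0.0027 in TI units) survives on weakly
glinted pixels; this mirrors operational behaviour. A `deglinted` flag on
the returned object makes the correction idempotent.

**Turbidity Index.** TI = R_rc(469) - R_rc(645). It is invariant under any
offset applied equally to both bands, which is what makes it robust to the
broadband part of glint, and after deglinting it is exactly independent of
the injected glint magnitude over zero-NIR water (the correction
coefficients equal the glint spectral shape there). TI is elevated over
sediment plumes, near zero over clear water, slightly negative over
submerged reef and strongly negative over land, including artificial
islands.

**True-colour composites.** Channels are scaled 0-0.15 (MODIS-like) or
0-0.5 (OLI-like), clipped and quantised to 0-255 with
round-half-away-from-zero (so 0.075 at the MODIS scaling maps to 128).
Half-resolution green/blue inputs are ratio-sharpened by the full-resolution
red band: the multiplier is red divided by its own 2x2 block-mean
reconstruction, which exactly restores any band proportional to red.

## Cloud masking

Cloud products enter as boolean grids or probabilities (thresholded at 0.5).
The raw mask is dilated by 500 m with a Euclidean disk — at 250-m pixels a
radius-2 disk of 13 offsets. A disk rather than a square was chosen because
"dilated by 500 m" is distance language and the disk is the isotropic
structuring element; this was an open choice. Manual overrides (polygons
with `force_clear` or `force_cloud` modes and optional date windows) patch
the two known failure modes: bright new islands misflagged as cloud, and
missed thin cloud. force_clear applies first, force_cloud second, so
force_cloud wins on contradictory overlaps (warned).

## Change detection

**Shallow water.** A pixel is shallow when its red-band reflectance exceeds
0.005 in at least 20 cloud-free passes of the reference year. Two documented
proxies: the criterion was calibrated on a remote-sensing-reflectance
product, while the synthetic series carries R_rc in the red channel; and we
count cloud-free passes only, a stated package decision (the alternative —
all passes — is expressible by passing an all-clear cloud array).

**Island detection.** For each pixel, ordinary least squares (with
intercept) of R_rc(859) against time in fractional years from the first
observation, over cloud-free observations only. Pixels with fewer than
`min_valid_obs` (default 10) usable observations carry NA; the guard exists
because cloud-gap artifacts otherwise contaminate the trend. A pixel is
flagged as new island when its slope exceeds 0.013 per year. The printed
threshold carries mixed units (per-steradian per year) that conflict with
R_rc being dimensionless; we keep the numerical value 0.013 on dimensionless
R_rc, in 1/year. Detected pixels are individuated into islands by
8-connected component labelling, with area = pixel count / 16 km^2.
A step change of height h at fraction p through the record produces an OLS
slope of roughly 2 h p (1 - p) / T for a record of length T years, so
conversions in the first or final few percent of the record fall below
threshold — the reason islands built before the record starts, or pixels
converted in the record's closing weeks, are missed at the pixel level while
the island is still detected through its earlier-converted pixels. Islands
below one native pixel (~0.06 km^2) are below the method's resolution.

## Plume quantification

Delineations (manual polygons, or the automated surrogate) are rasterized by
pixel-centre containment, cloud-masked pixels are removed, and area is
exactly pixel count / 16 km^2 — the fixed 250-m pixel-area rule is applied
everywhere, ignoring the sub-percent latitude dependence of true pixel area
over the region of interest. Per-reef "affected area" is the union of
footprints (per-date areas double-count overlaps). Frequency maps divide
per-pixel coverage counts by an explicit `n_total_images`, so normalising by
all examined images or only plume-bearing images are both expressible. The
single-hit fraction is pixels covered exactly once over pixels covered at
least once.

The automated surrogate `auto_delineate` thresholds TI at the clear-water
median plus k MADs (k = 5 by default; at the default noise level this sits
about 5 sigma above clear water and well below the default plume signal),
keeps non-cloud pixels only, and retains the 8-connected components touching
a 4-pixel buffer around the reef — plumes emanate from the construction
site, so detached bright specks (cloud-edge artifacts) are rejected. It is
labelled `source = "auto"` and never merged silently with manual
delineations.

## The synthetic world

The generator composites each scene in the order baseline -> island growth
-> plume -> glint, adds Gaussian noise (sd 0.002), then overwrites cloudy
pixels with a bright cloud spectrum; the truth records every layer before
cloud occlusion. Defaults, chosen once:

* Spectra (469/555/645/859 nm): deep water (0.030, 0.020, 0.008, 0.002);
  reef adds (0, 0.025, 0.030, 0.001) — benthic signal in green/red, so reef
  TI is slightly negative and red exceeds the shallow-water threshold; land
  (0.10, 0.12, 0.15, 0.25) — high NIR, strongly negative TI; cloud 0.60 in
  all bands.
* Plume perturbation per unit amplitude: (+1, +0.6, +0.3, +0.05) across the
  bands, i.e. a net TI gain of 0.7 per unit amplitude and a slight red/NIR
  brightening, as sediment scatters across the visible. No reflectance
  magnitudes for plume water are published, so the default amplitude (0.05)
  is a free parameter of the stated world.
* Glint spectral shape (0.67, 0.80, 0.94, 1.0) equals the deglint
  coefficients, making glint-invariance of TI exactly testable over
  zero-NIR water.
* Islands grow by ranking footprint pixels by distance from the growth
  origin and adding `round(f * n)` of them, f the (default linear) growth
  fraction — hence truth island masks are non-decreasing in time.
* Clouds are smoothed-noise blobs thresholded to an exact coverage fraction
  (default 30% in the benchmark); plumes are circular blobs with a
  deterministic per-date drift offset (no advection physics); glint fields
  are a smooth west-east gradient.

Identical config and seed give bit-identical output; the generator saves and
restores the caller's RNG state.

What the generator does *not* emulate: mixed pixels and sensor point-spread
(islands have crisp edges), view-angle-dependent pixel growth, tides,
aerosol variability, cloud shadows, and background TI drift between scenes.
A green parameter-recovery test therefore establishes the correctness of the
pipeline's logic on the stated world, not the field performance of the
thresholds on real imagery.

### The benchmark and its calibration claims

`benchmark_config()` fixes a 53 x 80 pixel scene observed daily for
2013-2015 with 30% cloud, a sunglint episode every 9th day, three reefs, a
Mischief-like 6.39 km^2 island built January-December 2015 with plumes every
5 days during construction, a 0.125 km^2 (two-pixel) island built
February-August 2014 with weekly plumes, and an untouched control reef. The
spatial window is deliberately small (the method is per-pixel, so spatial
extent adds cost, not information); time and event structure are not scaled
down. On this world the 0.013 1/y threshold flags zero deep-water pixels
and recovers both islands, reproducing the no-false-positive calibration
claim.

One benchmark subtlety: plume-area recovery by the surrogate is assessed on
a plume placed mostly over deep water. Plume portions overlying submerged
reef start from a negative TI baseline and a 0.05-amplitude plume does not
lift them above the clear-water threshold; the surrogate (like red-band
algorithms over shallow water) under-delineates there. This is a documented
limitation, not a tuning target.

## Numerical choices

* Rasterization: even-odd ray casting on pixel centres; boundary pixels
  follow the half-open crossing convention, so test geometry avoids placing
  centres exactly on edges. Zero-area polygons warn and give empty masks.
* Quantisation: round-half-away-from-zero, fixed.
* OLS slopes: accumulated sufficient statistics (n, sum t, sum t^2, sum y,
  sum ty) per pixel; exact on noiseless linear input to ~1e-12, NA where
  the design is degenerate or observations are too few.
* Areas: pixel count / 16, exactly, everywhere.
* "<0.01" project-table entries are censored intervals (0, 0.01), excluded
  from exact sums; per-country totals over censored columns are reported as
  lower bounds with a censored count. The printed per-country totals ship
  as their own verbatim fixture because the censored column sum cannot
  reproduce them.
* `Pre-OLI` and `Ongoing` are first-class date sentinels, not missing
  values. Records outside a configured grid are flagged, never dropped.

## File formats

The deployment environment carries no binary-raster stack, so all I/O is
plain text: CSV grids with JSON sidecars for rasters and series, GeoJSON
for polygons and overrides, JSON for configs, CSV for tables. The
`reefwatch` CLI (see `exec/reefwatch`) drives simulate / detect-islands /
shallow-mask / country-totals on these formats.
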