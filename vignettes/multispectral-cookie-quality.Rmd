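---
title: "Methods: multispectral quality assessment of butter cookies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral quality assessment of butter cookies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific problem

Industrial cookie baking is controlled by two knobs — baking time and oven
temperature — and judged by two quality attributes: surface browning
(a sensory attribute, traditionally scored by a trained panel) and residual
water content (traditionally measured by destructive oven-drying
gravimetry). Visible/near-infrared (VIS/NIR) multispectral imaging can
replace both measurements with one non-destructive camera exposure:
Maillard/caramelization pigments absorb in the violet–green bands, and
water absorbs around 970 nm. `bakevision` implements that replacement as
three linked statistical models, plus a calibrated synthetic image
generator used to develop and validate them end to end.

The package works on `spectral_image` objects: an `rows x cols x bands`
reflectance cube in `[0, 1]`, a strictly increasing wavelength grid in
nanometres, and an optional logical surface mask.

## The three models

### 1. Browning score (Fisher discriminant analysis)

Cookies from a fixed-temperature time series ("Set 1": 180 °C, times
4–20 min, triplicates) are assigned one of three sensory classes —
`underbaked`, `adequately_baked`, `overbaked` — by majority vote of a
simulated panel. All surface pixels of all cookies are pooled, each pixel
inheriting its cookie's class, and Fisher's discriminant is fitted by hand
(`fit_fda()`): with within-class scatter $S_W$ and between-class scatter
$S_B$, the loadings are the leading eigenvectors of
$(S_W + \lambda I)^{-1} S_B$. We solve the symmetrised system
$S_W^{-1/2} S_B S_W^{-1/2}$ for numerical stability, keep at most two
components (three classes bound $\mathrm{rank}(S_B) \le 2$), and normalise
each loading to unit length. The default ridge
$\lambda = 10^{-6}\,\mathrm{tr}(S_W)/p$ guards against collinear bands and
is exactly zero-effect in the well-conditioned case.

The browning **score** is the projection on the first loading, oriented and
shifted so that the mean pixel of the lightest class scores exactly 0 and
the score *decreases* as browning deepens. Class limits for pixel-wise and
cookie-wise classification are midpoints of the mean scores of the
4/6-minute and 10/12-minute time groups (`compute_class_limits()`); score
maps are smoothed with a masked Gaussian before thresholding so isolated
noisy pixels do not form spurious zones, and ties go to the more-baked
class.

### 2. Water content (NIPALS PLS1 regression)

Gravimetric water percentage is $100\,(m_\mathrm{initial} -
m_\mathrm{dried})/m_\mathrm{initial}$. The predictor is the surface-mean
spectrum (one 19-value vector per cookie), the training design is the full
time x temperature grid ("Set 2": 150–200 °C x 4–16 min, triplicates,
105 cookies). The PLS1 regression is authored directly as NIPALS
(`fit_plsr()`): for each component, weight $w = X^\top y / \lVert X^\top y
\rVert$, score $t = Xw$, loadings $p = X^\top t / t^\top t$ and $q =
y^\top t / t^\top t$, then deflation of both blocks; the final coefficient
vector is $B = W (P^\top W)^{-1} q$ on mean-centred data (no variance
scaling — all bands share reflectance units). Zero-variance bands are
dropped with a warning and get a zero coefficient. The number of
components is chosen by seeded k-fold cross-validation
(`cv_select_components()`), taking the smallest count whose CV-RMSEP is
within 1 % of the minimum (parsimony rule). Accuracy is reported as
held-out RMSEP on a 1/3 test split never touched during selection.
Pixel-wise application of the coefficient vector gives water maps
(`water_map()`).

### 3. Browning response surface (quadratic in time and temperature)

Mean browning scores over the Set 2 grid are fitted by ordinary least
squares (`stats::lm`) to the 6-term quadratic
$S = b_0 + b_1 t + b_2 T + b_{11} t^2 + b_{22} T^2 + b_{12} tT$
(`fit_surface()`). Points at or beyond 20 min are excluded: they are
outside the usable baking range and would drag the quadratic. The
time-to-temperature **sensitivity ratio**
$(\partial S/\partial t)/(\partial S/\partial T)$ (`sensitivity_ratio()`)
expresses how many °C of oven temperature trade against one minute of
baking time; `zone_map()` renders the under/adequate/over regions of the
time x temperature plane from the fitted surface and the class limits.

## The synthetic generator

No public image data accompanies this problem, so the package ships a
generator (`sim_config()`, `render_image()`, `generate_set()`) calibrated
to reproduce the *structure* of the two-set baking experiment: realistic
spectra, a rim-leads-centre browning gradient, exposure-driven drying, and
panel/gravimetry observations. It emulates physics only as far as the
models under test can see it.

* **Exposure.** One scalar drives everything:
  $E = t + (T - 180)/10$ min-equivalents, encoding an exact
  "1 minute ≈ 10 °C" equivalence (`temp_per_min_equiv = 10`,
  `exposure_ref_temp_c = 180`). Recovering the built-in ratio of 10 from
  the fitted response surface is one of the package's validation targets.
* **Drying.** Water mass fraction decays as
  $x(E) = x_\mathrm{floor} + (x_0 - x_\mathrm{floor}) e^{-E/\tau}$ with
  $x_0 = 0.115$, $x_\mathrm{floor} = 0.010$ and $\tau = 4.46$. The time
  constant was calibrated analytically so the design-extreme water contents
  span roughly 1.1–9.4 % — the realistic range for this product — rather
  than fitted to any model output. A per-cookie log-normal jitter on
  $\tau$ (`water_jitter_sd = 0.08`) decouples water from browning: without
  it, water is a deterministic function of the same exposure scalar as
  pigment, and a regression could read water from high-contrast visible
  bands instead of the 970 nm water band.
* **Reflectance.** Beer–Lambert-style attenuation of an unbaked dough base
  spectrum $R_0(\lambda) = 0.48 + 0.17\,\mathrm{logistic}((\lambda -
  540)/70)$:
  $R = R_0\,e^{-c\,A_\mathrm{brown}(\lambda)}\,e^{-(x - x_0)
  A_\mathrm{water}(\lambda)} + \varepsilon$, clipped to $[0,1]$, with
  pigment concentration $c = 0.2\,\max(0, E)$ and i.i.d. Gaussian noise
  (`noise_sd = 0.01`). The water term uses the *deficit* $x - x_0$, so an
  unbaked cookie equals the dough spectrum exactly. The brown template
  peaks sharply at 395 nm with a secondary 525 nm shoulder and a flat NIR
  floor (so browning always darkens every band); the water template is a
  Gaussian centred at 970 nm. Template shapes were chosen so each model's
  physically meaningful band is identifiable, which is exactly what the
  recovery checks verify.
* **Radial gradient.** The rim bakes ahead of the centre: local exposure is
  $E \cdot (0.85 + 0.15\rho)$ at normalised radius $\rho$
  (`edge_lead = 0.85`). The value 0.85 keeps 6-minute cookies free of
  underbaked pixels while preserving a visible browning ring.
* **Observations.** Gravimetry adds weighing noise to simulated initial and
  dried masses; the panel thresholds each judge's noisy perceived exposure
  at 5 and 11 min-equivalents and takes a majority, with ties resolved to
  `adequately_baked`.

## Input/output and reproducibility

Image cubes are stored as multi-page 32-bit IEEE-float TIFFs with the
wavelength grid in a JSON sidecar. The float pages are written by a small
deterministic TIFF writer inside the package because the available TIFF
writer only stores normalized integer samples, which quantizes the data
and breaks bit-exact round trips; files are *read* with `tiff::readTIFF()`,
so an independent libtiff implementation validates every file the package
writes. Models serialize to plain JSON at full precision; tables to CSV
with `%.15g` formatting. All randomness flows through `withr::with_seed()`
with documented seed derivations, making datasets, models and pipeline
reports byte-identical across runs with the same seed.

The `run_pipeline()` driver (and the `inst/scripts/bakevision.R` command
line wrapper) chains the eight stages — simulate, segment, train-browning,
score, fit-surface, train-water, predict-water, report — with explicit
artifact hand-offs: a missing upstream artifact produces an error naming
the stage that creates it.

## Problem sizes

Defaults target the realistic camera geometry (256 x 256 pixels, 19
bands). Tests and the shipped acceptance script run the same designs at
48–64 pixels: every quantity validated (loading peaks, coefficient peaks,
RMSEP, sensitivity ratio) is a statistical property of the 30- and
105-cookie designs, not of pixel count, and the small images keep the full
suite under a minute. These sizes are the package's own choice.

## Limitations

* The generator is phenomenological: one exposure scalar, first-order
  drying, Beer–Lambert attenuation with fixed templates. It contains no
  heat-transfer physics, no surface texture, cracking or gloss, and its
  radial gradient is perfectly circular.
* The quadratic response surface is a local approximation; fitted to a
  saturating browning response it can flatten (and its gradient can change
  sign) at the most-baked corner of the design box, which is why
  `sensitivity_ratio()` refuses to extrapolate outside the box.
* The FDA browning score assumes pooled-pixel class-conditional
  distributions differ mainly in mean; strongly heteroscedastic classes
  would call for quadratic discriminants.
* Class limits depend on the presence of the 4, 6, 10 and 12 minute groups
  in the training series; other designs need limits supplied explicitly
  via `set_class_limits()`.
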