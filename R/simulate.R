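#' Simulation configuration for the synthetic bakery
#'
#' Collects every constant of the synthetic multispectral cookie generator.
#' The generator is statistical, not mechanistic: it encodes the empirical
#' structure the downstream models rely on — reflectance falling with baking
#' mainly in the 400–700 nm visible range, browning propagating from the
#' cookie edge toward the center, a water absorption signal peaking at
#' 970 nm, and a built-in time–temperature equivalence of 1 min per 10 °C.
#'
#' Defaults are calibrated once so that the full time-by-temperature design
#' ("set2", 150–200 °C x 4–16 min) spans average water contents of roughly
#' 1.2–9.4 % and so that, at 180 °C, 4 min cookies read as underbaked, 6–10
#' min as adequately baked and 12+ min as overbaked.
#'
#' @param wavelengths_nm Ordered 19-band grid (nm). The default covers
#'   385–970 nm and contains the diagnostically important 385, 395, 470,
#'   525, 630 and 970 nm bands.
#' @param image_size Image side length in pixels (square images). 256 by
#'   default; 1280x960-class sizes are supported but slow in plain R.
#' @param cookie_radius_px Cookie disk radius in pixels.
#' @param exposure_ref_temp_c Reference oven temperature (°C) at which
#'   exposure equals baking time.
#' @param temp_per_min_equiv Temperature increase (°C) equivalent to one
#'   extra minute of baking.
#' @param water_initial_frac Dough water mass fraction before baking.
#' @param water_floor_frac Asymptotic water mass fraction after exhaustive
#'   baking.
#' @param water_decay_tau Exponential drying time constant (minute
#'   equivalents). The default 4.46 places the set2 design extremes at
#'   ~9.4 % and ~1.2 % water.
#' @param pigment_lag Exposure (min-equivalents) before brown pigment starts
#'   accumulating.
#' @param pigment_rate Pigment accumulation per minute-equivalent beyond the
#'   lag (absorbance units).
#' @param brown_absorb_template Per-band absorbance weights of the brown
#'   (Maillard) pigment; the default peaks at 395 and 525 nm with a small
#'   flat near-infrared tail.
#' @param water_absorb_template Per-band absorbance weights of water; the
#'   default is a Gaussian peak at 970 nm.
#' @param edge_lead Dimensionless in (0, 1]: ratio of center to edge local
#'   exposure. 1 means uniform baking; smaller values brown the rim first.
#' @param water_jitter_sd SD of the per-cookie log-normal jitter on the
#'   drying time constant. Real replicate cookies dry slightly differently
#'   (dough moisture, sheet position) independently of how brown they look;
#'   this is the variation that forces the water model to read the
#'   near-infrared water band instead of inferring water from browning.
#' @param noise_sd Per-pixel, per-band Gaussian reflectance noise SD.
#' @param background_reflectance Flat background spectrum level.
#' @param seed Default integer seed for dataset generation.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(wavelengths_nm = c(385, 395, 430, 450, 470, 505, 525,
                                          565, 590, 630, 645, 660, 700, 850,
                                          890, 910, 940, 950, 970),
                       image_size = 256L,
                       cookie_radius_px = round(0.375 * image_size),
                       exposure_ref_temp_c = 180,
                       temp_per_min_equiv = 10,
                       water_initial_frac = 0.115,
                       water_floor_frac = 0.010,
                       water_decay_tau = 4.46,
                       pigment_lag = 0,
                       pigment_rate = 0.2,
                       brown_absorb_template = default_brown_template(wavelengths_nm),
                       water_absorb_template = default_water_template(wavelengths_nm),
                       edge_lead = 0.85,
                       water_jitter_sd = 0.08,
                       noise_sd = 0.01,
                       background_reflectance = 0.08,
                       seed = 1L) {
  stopifnot(
    all(diff(wavelengths_nm) > 0),
    length(brown_absorb_template) == length(wavelengths_nm),
    length(water_absorb_template) == length(wavelengths_nm),
    all(brown_absorb_template >= 0), all(water_absorb_template >= 0),
    noise_sd >= 0, edge_lead > 0, edge_lead <= 1, water_jitter_sd >= 0,
    water_floor_frac < water_initial_frac, water_decay_tau > 0
  )
  structure(list(
    wavelengths_nm = as.numeric(wavelengths_nm),
    image_size = as.integer(image_size),
    cookie_radius_px = as.integer(cookie_radius_px),
    exposure_ref_temp_c = exposure_ref_temp_c,
    temp_per_min_equiv = temp_per_min_equiv,
    water_initial_frac = water_initial_frac,
    water_floor_frac = water_floor_frac,
    water_decay_tau = water_decay_tau,
    pigment_lag = pigment_lag,
    pigment_rate = pigment_rate,
    brown_absorb_template = brown_absorb_template,
    water_absorb_template = water_absorb_template,
    edge_lead = edge_lead,
    water_jitter_sd = water_jitter_sd,
    noise_sd = noise_sd,
    background_reflectance = background_reflectance,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default absorbance templates
#'
#' The brown-pigment template has Gaussian peaks at 395 nm (weight 1) and
#' 525 nm (weight 0.55) plus a flat 0.25 near-infrared tail: melanoidins
#' absorb mostly in the near-UV/blue but darken the whole spectrum. The
#' water template is a Gaussian peak of height 1.5 centred on the 970 nm
#' water overtone.
#'
#' @param wavelengths_nm Wavelength grid (nm).
#' @return Numeric vector of non-negative weights, one per band.
#' @export
default_brown_template <- function(wavelengths_nm) {
  1.0 * exp(-((wavelengths_nm - 395) / 12)^2) +
    0.55 * exp(-((wavelengths_nm - 525) / 40)^2) +
    0.25
}

#' @rdname default_brown_template
#' @export
default_water_template <- function(wavelengths_nm) {
  1.5 * exp(-((wavelengths_nm - 970) / 30)^2)
}

# Unbaked dough reflectance: pale yellow, low in the blue, plateauing in the
# red/NIR.
base_reflectance <- function(wavelengths_nm) {
  0.48 + 0.17 * stats::plogis((wavelengths_nm - 540) / 70)
}

#' A single baking condition
#'
#' @param time_min Baking time in minutes (> 0).
#' @param temp_c Oven temperature in °C.
#' @param replicate Integer replicate index.
#' @return A list of class `baking_condition`.
#' @export
baking_condition <- function(time_min, temp_c, replicate = 1L) {
  if (!is.numeric(time_min) || time_min <= 0) stop("`time_min` must be > 0")
  structure(list(time_min = time_min, temp_c = temp_c,
                 replicate = as.integer(replicate)),
            class = "baking_condition")
}

#' Thermal exposure in minute-equivalents
#'
#' Maps a (time, temperature) pair to a single exposure scale
#' `E = t + (T - T_ref) / k`, with `k = temp_per_min_equiv`. The linear
#' additive form makes the 1 min ≈ 10 °C equivalence exact by construction,
#' which keeps response-surface recovery a well-posed check rather than an
#' approximation of Arrhenius kinetics.
#'
#' @param condition A [baking_condition()].
#' @param config A [sim_config()].
#' @return Exposure in minute-equivalents (may be negative for cool, short
#'   bakes below the reference temperature).
#' @examples
#' exposure(baking_condition(9, 190), sim_config())  # 10
#' @export
exposure <- function(condition, config = sim_config()) {
  if (condition$time_min <= 0) stop("baking time must be positive")
  condition$time_min +
    (condition$temp_c - config$exposure_ref_temp_c) / config$temp_per_min_equiv
}

#' Average water mass fraction after a given exposure
#'
#' First-order drying toward a floor:
#' `X(E) = floor + (initial - floor) * exp(-E / tau)`. Negative exposures
#' (cooler than the reference at time zero) are clamped to zero, so
#' `X(0) = water_initial_frac`.
#'
#' @param E Exposure in minute-equivalents (vectorised).
#' @param config A [sim_config()].
#' @param tau_scale Multiplier on the drying time constant (used internally
#'   for the per-cookie drying jitter; 1 gives the nominal curve).
#' @return Water mass fraction(s) in `[water_floor_frac, water_initial_frac]`.
#' @export
water_curve <- function(E, config = sim_config(), tau_scale = 1) {
  E <- pmax(E, 0)
  config$water_floor_frac +
    (config$water_initial_frac - config$water_floor_frac) *
      exp(-E / (config$water_decay_tau * tau_scale))
}

# Brown pigment concentration after a given exposure (absorbance units).
pigment_curve <- function(E, config) {
  config$pigment_rate * pmax(pmax(E, 0) - config$pigment_lag, 0)
}

#' Render one synthetic multispectral cookie image
#'
#' A centred disk of radius `cookie_radius_px` on a flat dark background.
#' Baking acts through a radially graded local exposure
#' `E_local(rho) = E * (edge_lead + (1 - edge_lead) * rho)` (`rho` =
#' normalised radius), so the rim always leads the center — browning and
#' drying propagate inward. Per-pixel reflectance follows a Beer–Lambert
#' style attenuation of the unbaked dough spectrum (which already contains
#' the dough's initial water):
#' `R(lambda) = R_base(lambda) * exp(-c * A_brown(lambda)) *
#' exp(-(w - w0) * A_water(lambda)) + noise`, clipped to `[0, 1]`, with
#' pigment `c` and surface water `w` driven by the local exposure and `w0`
#' the initial dough water fraction — so an unbaked cookie reproduces
#' `R_base` exactly and drying raises near-infrared reflectance.
#'
#' @param condition A [baking_condition()].
#' @param config A [sim_config()].
#' @param seed Integer seed for the pixel noise (deterministic rendering).
#' @return A list with `image` (a [spectral_image()] carrying the true disk
#'   mask) and `truth` (list: `exposure_minequiv`, `water_frac_true` — the
#'   bulk water fraction at the nominal exposure, used for gravimetry —,
#'   `pigment_mean`, `true_class`).
#' @export
render_image <- function(condition, config = sim_config(), seed = config$seed) {
  n <- config$image_size
  r <- config$cookie_radius_px
  if (r >= n / 2) stop("cookie_radius_px must be smaller than half the image side")
  E <- exposure(condition, config)
  wl <- config$wavelengths_nm
  nb <- length(wl)

  ctr <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  rho <- sqrt((xs - ctr)^2 + (t(xs) - ctr)^2) / r
  mask <- rho <= 1

  draws <- withr::with_seed(seed, list(
    tau_scale = exp(stats::rnorm(1, 0, config$water_jitter_sd)),
    noise = if (config$noise_sd > 0) {
      stats::rnorm(n * n * nb, 0, config$noise_sd)
    }
  ))

  e_local <- pmax(E, 0) * (config$edge_lead + (1 - config$edge_lead) * pmin(rho, 1))
  w_local <- water_curve(e_local, config, tau_scale = draws$tau_scale)
  c_local <- pigment_curve(e_local, config)

  rb <- base_reflectance(wl)
  cube <- array(config$background_reflectance, c(n, n, nb))
  idx <- which(mask)
  for (b in seq_len(nb)) {
    plane <- cube[, , b]
    plane[idx] <- rb[b] *
      exp(-c_local[idx] * config$brown_absorb_template[b]) *
      exp(-(w_local[idx] - config$water_initial_frac) *
            config$water_absorb_template[b])
    cube[, , b] <- plane
  }
  if (!is.null(draws$noise)) {
    cube <- cube + array(draws$noise, c(n, n, nb))
  }
  cube <- pmin(pmax(cube, 0), 1)

  truth <- list(
    exposure_minequiv = E,
    water_frac_true = water_curve(E, config, tau_scale = draws$tau_scale),
    pigment_mean = mean(c_local[idx]),
    true_class = class_from_exposure(E)
  )
  list(image = spectral_image(cube, wl, mask = mask), truth = truth)
}

#' Browning classes and default sensory thresholds
#'
#' The default exposure thresholds (5 and 11 minute-equivalents) place the
#' 180 °C series exactly as the sensory panel did: 4 min underbaked, 6–10
#' min adequately baked, 12 min and longer overbaked.
#'
#' @return `browning_classes()`: the ordered class labels.
#' @export
browning_classes <- function() c("underbaked", "adequately_baked", "overbaked")

#' @rdname browning_classes
#' @export
default_panel_thresholds <- function() c(5, 11)

class_from_exposure <- function(E, thresholds = default_panel_thresholds()) {
  browning_classes()[findInterval(E, thresholds) + 1L]
}

#' Simulate gravimetric water determination
#'
#' Emulates weighing a cookie before and after drying to constant mass at
#' 105 °C. Balance noise is added independently to both weighings; at zero
#' noise the pair reproduces the true water fraction exactly via
#' `X = (initial - dried) / initial`.
#'
#' @param truth Truth list from [render_image()] (uses `water_frac_true`),
#'   or a bare water fraction.
#' @param nominal_mass_g Nominal post-bake cookie mass (g).
#' @param noise_sd_g Balance noise SD (g).
#' @param seed Integer seed.
#' @return Named numeric vector `c(initial_mass_g, dried_mass_g)`.
#' @export
simulate_gravimetry <- function(truth, nominal_mass_g = 10, noise_sd_g = 0.005,
                                seed = 1L) {
  stopifnot(nominal_mass_g > 0)
  x <- if (is.list(truth)) truth$water_frac_true else truth
  eps <- if (noise_sd_g > 0) {
    withr::with_seed(seed, stats::rnorm(2, 0, noise_sd_g))
  } else c(0, 0)
  initial <- nominal_mass_g + eps[1]
  dried <- min(initial, initial * (1 - x) + eps[2])
  c(initial_mass_g = initial, dried_mass_g = dried)
}

#' Simulate a sensory panel vote
#'
#' Each panelist perceives the cookie's exposure with independent Gaussian
#' error and assigns exactly one of the three browning classes by
#' thresholding the perceived exposure.
#'
#' @param E Exposure in minute-equivalents.
#' @param n_panelists Number of panelists (>= 1).
#' @param thresholds Increasing length-2 vector of exposure thresholds
#'   (underbaked/adequate, adequate/overbaked).
#' @param vote_noise SD of the perceptual error (minute-equivalents).
#' @param seed Integer seed.
#' @return Named integer vector of votes per class, summing to `n_panelists`.
#' @export
simulate_panel <- function(E, n_panelists = 6L,
                           thresholds = default_panel_thresholds(),
                           vote_noise = 0.4, seed = 1L) {
  stopifnot(n_panelists >= 1)
  if (length(thresholds) != 2L || diff(thresholds) <= 0) {
    stop("`thresholds` must be two increasing values")
  }
  perceived <- if (vote_noise > 0) {
    withr::with_seed(seed, E + stats::rnorm(n_panelists, 0, vote_noise))
  } else rep(E, n_panelists)
  cls <- findInterval(perceived, thresholds) + 1L
  votes <- tabulate(cls, nbins = 3L)
  names(votes) <- browning_classes()
  votes
}

#' Consensus sensory class from panel votes
#'
#' Majority vote; ties are broken toward `adequately_baked` (in practice the
#' simulated panel, like a real one, essentially never splits a cookie
#' between the underbaked and overbaked extremes).
#'
#' @param votes Named integer vector as returned by [simulate_panel()], or a
#'   matrix/data frame of such rows.
#' @return Character class label(s).
#' @export
consensus_class <- function(votes) {
  one <- function(v) {
    v <- as.numeric(v)
    top <- which(v == max(v))
    if (length(top) > 1L) "adequately_baked" else browning_classes()[top]
  }
  if (is.matrix(votes) || is.data.frame(votes)) {
    apply(votes, 1L, one)
  } else one(votes)
}

#' Generate a full synthetic baking experiment
#'
#' Two presets mirror the study layout:
#' * `"set1"` — browning-score construction: 180 °C, baking times 4, 6, 7,
#'   8, 9, 10, 12, 14, 16 and 20 min, triplicate (30 cookies), with
#'   simulated six-person panel votes.
#' * `"set2"` — response surface and water modelling: 150, 160, 170, 180
#'   and 200 °C crossed with 4, 6, 8, 10, 12, 14 and 16 min, triplicate
#'   (105 cookies), with simulated gravimetric masses.
#'
#' Every cookie gets its own sub-seed derived from `seed`, so the dataset is
#' byte-identical for a fixed seed regardless of evaluation order.
#'
#' @param design `"set1"` or `"set2"`.
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param n_panelists Panel size for the vote simulation.
#' @param vote_noise Panelist perceptual noise (min-equivalents).
#' @param nominal_mass_g,balance_noise_sd_g Gravimetry settings.
#' @return A list with `images` (list of [spectral_image()]), `records`
#'   (data frame: set, id, time_min, temp_c, replicate, initial_mass_g,
#'   dried_mass_g, votes_under, votes_adequate, votes_over) and `truth`
#'   (data frame: id, exposure_minequiv, water_frac_true, pigment_mean,
#'   true_class).
#' @examples
#' ds <- generate_set("set1", sim_config(image_size = 32L), seed = 7)
#' nrow(ds$records)  # 30
#' @export
generate_set <- function(design = c("set1", "set2"), config = sim_config(),
                         seed = config$seed, n_panelists = 6L,
                         vote_noise = 0.4, nominal_mass_g = 10,
                         balance_noise_sd_g = 0.005) {
  design <- match.arg(design)
  grid <- if (design == "set1") {
    expand.grid(replicate = 1:3,
                time_min = c(4, 6, 7, 8, 9, 10, 12, 14, 16, 20),
                temp_c = 180)
  } else {
    expand.grid(replicate = 1:3,
                time_min = c(4, 6, 8, 10, 12, 14, 16),
                temp_c = c(150, 160, 170, 180, 200))
  }
  grid <- grid[order(grid$temp_c, grid$time_min, grid$replicate), , drop = FALSE]

  images <- vector("list", nrow(grid))
  recs <- vector("list", nrow(grid))
  tru <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cond <- baking_condition(grid$time_min[i], grid$temp_c[i], grid$replicate[i])
    sub <- cookie_seed(seed, i)
    ri <- render_image(cond, config, seed = sub)
    masses <- simulate_gravimetry(ri$truth, nominal_mass_g,
                                  balance_noise_sd_g, seed = sub + 1L)
    votes <- simulate_panel(ri$truth$exposure_minequiv, n_panelists,
                            vote_noise = vote_noise, seed = sub + 2L)
    id <- sprintf("%s_%02d_%03d_%d", design, grid$time_min[i],
                  grid$temp_c[i], grid$replicate[i])
    images[[i]] <- ri$image
    recs[[i]] <- data.frame(
      set = design, id = id, time_min = grid$time_min[i],
      temp_c = grid$temp_c[i], replicate = grid$replicate[i],
      initial_mass_g = masses[["initial_mass_g"]],
      dried_mass_g = masses[["dried_mass_g"]],
      votes_under = votes[["underbaked"]],
      votes_adequate = votes[["adequately_baked"]],
      votes_over = votes[["overbaked"]],
      stringsAsFactors = FALSE
    )
    tru[[i]] <- data.frame(
      id = id, exposure_minequiv = ri$truth$exposure_minequiv,
      water_frac_true = ri$truth$water_frac_true,
      pigment_mean = ri$truth$pigment_mean,
      true_class = ri$truth$true_class, stringsAsFactors = FALSE
    )
  }
  list(images = images,
       records = do.call(rbind, recs),
       truth = do.call(rbind, tru))
}

# Per-cookie seed fan-out: 3 seeds per cookie (noise, balance, panel), kept
# well below 2^31.
cookie_seed <- function(seed, i) {
  (as.integer(seed) %% 2000000L) * 1000L + 3L * as.integer(i)
}
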