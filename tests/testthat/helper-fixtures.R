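# Small-image simulator configs and memoised datasets shared across test
# files. Images are kept small (32-48 px) so the whole suite stays fast;
# the statistical structure does not depend on image size.

tiny_cfg <- function(noise_sd = 0.01, image_size = 48L, ...) {
  sim_config(image_size = as.integer(image_size), noise_sd = noise_sd, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# Set 1 (sensory time series) with default noise, plus its consensus labels
# and a fitted browning model with class limits.
fixture_set1 <- function() {
  cached("set1", generate_set("set1", tiny_cfg(), seed = 101))
}

fixture_browning_model <- function() {
  cached("browning_model", {
    s1 <- fixture_set1()
    labels <- consensus_class(
      s1$records[, c("votes_under", "votes_adequate", "votes_over")]
    )
    pool <- build_pixel_dataset(s1$images, class_labels = labels)
    m <- fit_fda(pool$pixels, pool$groups,
                 wavelengths_nm = s1$images[[1]]$wavelengths_nm)
    ms <- vapply(seq_along(s1$images), function(i) {
      mean_browning_score(score_pixels(s1$images[[i]], model = m))
    }, numeric(1))
    gm <- tapply(ms, s1$records$time_min, mean)
    set_class_limits(m, compute_class_limits(gm))
  })
}

fixture_set2 <- function() {
  cached("set2", generate_set("set2", tiny_cfg(), seed = 202))
}

fixture_set2_spectra <- function() {
  cached("set2_spectra", {
    s2 <- fixture_set2()
    list(
      spectra = t(vapply(s2$images, mean_spectrum,
                         numeric(length(s2$images[[1]]$wavelengths_nm)))),
      water_pct = water_fraction(s2$records$initial_mass_g,
                                 s2$records$dried_mass_g)
    )
  })
}

# Per-seed replication of the full water-model and response-surface
# analysis, shared by the accuracy and sensitivity-recovery checks.
fixture_multiseed <- function(n_seeds = 10) {
  cached(paste0("multiseed", n_seeds), {
    cfg <- tiny_cfg()
    model <- fixture_browning_model()
    res <- lapply(seq_len(n_seeds), function(seed) {
      s2 <- generate_set("set2", cfg, seed = 500 + seed)
      spectra <- t(vapply(s2$images, mean_spectrum,
                          numeric(length(cfg$wavelengths_nm))))
      y <- water_fraction(s2$records$initial_mass_g, s2$records$dried_mass_g)
      spec <- split_spec(seed = seed)
      sp <- split_train_test(seq_len(nrow(spectra)), spec)
      sel <- cv_select_components(spectra[sp$train, ], y[sp$train], spec)
      pm <- fit_plsr(spectra[sp$train, ], y[sp$train], sel$n_components)
      held_out <- rmsep(predict(pm, spectra[sp$test, ]), y[sp$test])

      ms <- vapply(seq_along(s2$images), function(i) {
        mean_browning_score(score_pixels(s2$images[[i]], model = model))
      }, numeric(1))
      surf <- fit_surface(ms, s2$records$time_min, s2$records$temp_c)
      list(rmsep = held_out, ratio = sensitivity_ratio(surf, 10, 175),
           r_squared = surf$r_squared)
    })
    list(rmsep = vapply(res, `[[`, numeric(1), "rmsep"),
         ratio = vapply(res, `[[`, numeric(1), "ratio"),
         r_squared = vapply(res, `[[`, numeric(1), "r_squared"))
  })
}
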