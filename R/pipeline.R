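#' Default pipeline configuration
#'
#' Returns the configuration list the pipeline runs from; any subset of
#' fields can be overridden via a YAML file or the `override` argument.
#' Simulator keys mirror [sim_config()] fields; `split` mirrors
#' [split_spec()].
#'
#' @param override Named list of overrides (nested lists merge shallowly).
#' @return Configuration list.
#' @export
default_pipeline_config <- function(override = NULL) {
  cfg <- list(
    seed = 1L,
    outdir = "bakevision_out",
    designs = c("set1", "set2"),
    simulator = list(image_size = 256L, noise_sd = 0.01),
    panel = list(n_panelists = 6L, vote_noise = 0.4),
    gravimetry = list(nominal_mass_g = 10, balance_noise_sd_g = 0.005),
    segmentation = list(offset = 0.02),
    browning = list(ridge = NULL, gaussian_sigma = 2),
    split = list(train_fraction = 2 / 3, n_folds = 5L),
    water = list(max_components = 10L, gaussian_sigma = 2)
  )
  if (!is.null(override)) {
    for (nm in names(override)) {
      if (is.list(override[[nm]]) && is.list(cfg[[nm]])) {
        for (sub in names(override[[nm]])) cfg[[nm]][[sub]] <- override[[nm]][[sub]]
      } else cfg[[nm]] <- override[[nm]]
    }
  }
  cfg
}

pipeline_stages <- c(simulate = 1L, segment = 2L, `train-browning` = 3L,
                     score = 4L, `fit-surface` = 5L, `train-water` = 6L,
                     `predict-water` = 7L, report = 8L)

# One master seed fans out to per-stage seeds so stages can be rerun in
# isolation and still reproduce the full-run artifacts.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 20000000L) * 100L + pipeline_stages[[stage]]
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s'; run the '%s' command first",
                 path, produced_by), call. = FALSE)
  }
  path
}

pipeline_log <- function(outdir, command, cfg, config_path = NULL) {
  hash <- if (!is.null(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else {
    tmp <- tempfile(); on.exit(unlink(tmp))
    writeLines(yaml::as.yaml(cfg), tmp)
    unname(tools::md5sum(tmp))
  }
  line <- sprintf("command=%s seed=%d config_md5=%s bakevision=%s R=%s",
                  command, cfg$seed, hash,
                  as.character(utils::packageVersion("bakevision")),
                  paste(R.version$major, R.version$minor, sep = "."))
  cat(line, "\n", file = file.path(outdir, "pipeline_log.txt"),
      sep = "", append = TRUE)
}

#' Run one stage of (or the whole) analysis pipeline
#'
#' Orchestrates the full study reproducibly: simulate the two baking sets,
#' segment the cookie surfaces, train the sensory-anchored browning score,
#' score all cookies, fit the time x temperature response surface, train
#' the water-content PLSR on a 2/3 split with fivefold CV, predict the
#' held-out third, and emit a report (predictions table, score summary,
#' zone map, pixel-wise water maps for the coolest-oven series).
#'
#' Every stage logs the configuration hash and the seed it ran under;
#' rerunning any stage with the same config reproduces its artifacts
#' byte-identically.
#'
#' @param command One of `simulate`, `segment`, `train-browning`, `score`,
#'   `fit-surface`, `train-water`, `predict-water`, `report`, or `all`.
#' @param config Path to a YAML config file, or a config list
#'   ([default_pipeline_config()] fills the gaps).
#' @param seed Optional seed override.
#' @param outdir Optional output-directory override.
#' @param design Optional design subset for `simulate`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(command, config = NULL, seed = NULL, outdir = NULL,
                         design = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  cfg <- default_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(design)) cfg$designs <- design

  if (identical(command, "all")) {
    for (cmd in names(pipeline_stages)) {
      run_pipeline(cmd, cfg, outdir = cfg$outdir)
    }
    return(invisible(cfg$outdir))
  }
  command <- match.arg(command, names(pipeline_stages))
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sseed <- stage_seed(cfg$seed, command)

  switch(command,
    "simulate" = stage_simulate(cfg, out, sseed),
    "segment" = stage_segment(cfg, out),
    "train-browning" = stage_train_browning(cfg, out),
    "score" = stage_score(cfg, out),
    "fit-surface" = stage_fit_surface(cfg, out),
    "train-water" = stage_train_water(cfg, out, sseed),
    "predict-water" = stage_predict_water(cfg, out),
    "report" = stage_report(cfg, out)
  )
  pipeline_log(out, command, cfg, config_path)
  invisible(out)
}

sim_config_from <- function(cfg) {
  do.call(sim_config, cfg$simulator)
}

stage_simulate <- function(cfg, out, sseed) {
  sc <- sim_config_from(cfg)
  for (i in seq_along(cfg$designs)) {
    ds <- generate_set(cfg$designs[i], sc, seed = sseed + 10L * i,
                       n_panelists = cfg$panel$n_panelists,
                       vote_noise = cfg$panel$vote_noise,
                       nominal_mass_g = cfg$gravimetry$nominal_mass_g,
                       balance_noise_sd_g = cfg$gravimetry$balance_noise_sd_g)
    write_dataset(ds, file.path(out, "data", cfg$designs[i]))
  }
}

load_design <- function(cfg, out, design, with_masks = FALSE) {
  dir <- file.path(out, "data", design)
  require_artifact(file.path(dir, "samples.csv"), "simulate")
  masks_dir <- NULL
  if (with_masks) {
    masks_dir <- file.path(out, "masks")
    require_artifact(masks_dir, "segment")
  }
  read_dataset(dir, masks_dir = masks_dir)
}

stage_segment <- function(cfg, out) {
  dir.create(file.path(out, "masks"), showWarnings = FALSE)
  for (design in cfg$designs) {
    ds <- load_design(cfg, out, design)
    for (i in seq_len(nrow(ds$records))) {
      m <- segment(ds$images[[i]], offset = cfg$segmentation$offset)
      write_mask(m, file.path(out, "masks",
                              paste0(ds$records$id[i], "_mask.tif")))
    }
  }
}

stage_train_browning <- function(cfg, out) {
  ds <- load_design(cfg, out, "set1", with_masks = TRUE)
  labels <- consensus_class(ds$records[, c("votes_under", "votes_adequate",
                                           "votes_over")])
  pool <- build_pixel_dataset(ds$images, class_labels = labels)
  model <- fit_fda(pool$pixels, pool$groups, ridge = cfg$browning$ridge,
                   wavelengths_nm = ds$images[[1]]$wavelengths_nm)
  ms <- vapply(seq_along(ds$images), function(i) {
    mean_browning_score(score_pixels(ds$images[[i]], model = model))
  }, numeric(1))
  group_means <- tapply(ms, ds$records$time_min, mean)
  model <- set_class_limits(model, compute_class_limits(group_means))
  dir.create(file.path(out, "models"), showWarnings = FALSE)
  write_model(model, file.path(out, "models", "browning_model.json"))
}

stage_score <- function(cfg, out) {
  model <- read_model(require_artifact(
    file.path(out, "models", "browning_model.json"), "train-browning"))
  dir.create(file.path(out, "scores"), showWarnings = FALSE)
  rows <- list()
  for (design in cfg$designs) {
    ds <- load_design(cfg, out, design, with_masks = TRUE)
    for (i in seq_len(nrow(ds$records))) {
      sm <- score_pixels(ds$images[[i]], model = model)
      ms <- mean_browning_score(sm)
      write_map(sm, file.path(out, "scores",
                              paste0(ds$records$id[i], "_score.tif")))
      rows[[length(rows) + 1L]] <- data.frame(
        set = design, id = ds$records$id[i],
        time_min = ds$records$time_min[i], temp_c = ds$records$temp_c[i],
        mean_score = ms, class = classify_cookie(ms, model),
        stringsAsFactors = FALSE
      )
    }
  }
  write_table(do.call(rbind, rows), file.path(out, "scores", "scores.csv"))
}

stage_fit_surface <- function(cfg, out) {
  scores <- utils::read.csv(require_artifact(
    file.path(out, "scores", "scores.csv"), "score"), stringsAsFactors = FALSE)
  s2 <- scores[scores$set == "set2", ]
  if (nrow(s2) == 0) stop("no set2 scores available; run 'score' on set2")
  surf <- fit_surface(s2$mean_score, s2$time_min, s2$temp_c)
  model <- read_model(file.path(out, "models", "browning_model.json"))
  zm <- zone_map(surf, model)
  write_model(surf, file.path(out, "models", "surface.json"))
  zdf <- data.frame(time_min = rep(zm$time_grid, times = length(zm$temp_grid)),
                    temp_c = rep(zm$temp_grid, each = length(zm$time_grid)),
                    score = as.vector(zm$scores),
                    zone = as.vector(zm$zones), stringsAsFactors = FALSE)
  write_table(zdf, file.path(out, "models", "zone_map.csv"))
}

water_inputs <- function(cfg, out) {
  ds <- load_design(cfg, out, "set2", with_masks = TRUE)
  spectra <- t(vapply(ds$images, mean_spectrum,
                      numeric(length(ds$images[[1]]$wavelengths_nm))))
  measured <- water_fraction(ds$records$initial_mass_g, ds$records$dried_mass_g)
  list(ds = ds, spectra = spectra, measured = measured)
}

stage_train_water <- function(cfg, out, sseed) {
  wi <- water_inputs(cfg, out)
  spec <- split_spec(cfg$split$train_fraction, cfg$split$n_folds, seed = sseed)
  sp <- split_train_test(seq_len(nrow(wi$spectra)), spec)
  sel <- cv_select_components(wi$spectra[sp$train, ], wi$measured[sp$train],
                              spec, cfg$water$max_components)
  model <- fit_plsr(wi$spectra[sp$train, ], wi$measured[sp$train],
                    sel$n_components,
                    wavelengths_nm = wi$ds$images[[1]]$wavelengths_nm)
  dir.create(file.path(out, "models"), showWarnings = FALSE)
  write_model(model, file.path(out, "models", "water_model.json"))
  jsonlite::write_json(
    list(seed = spec$seed, n_folds = spec$n_folds,
         train_ids = wi$ds$records$id[sp$train],
         test_ids = wi$ds$records$id[sp$test],
         cv_rmsep = sel$cv_rmsep),
    file.path(out, "models", "water_split.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
}

stage_predict_water <- function(cfg, out) {
  model <- read_model(require_artifact(
    file.path(out, "models", "water_model.json"), "train-water"))
  split <- jsonlite::read_json(file.path(out, "models", "water_split.json"),
                               simplifyVector = TRUE)
  wi <- water_inputs(cfg, out)
  idx <- match(split$test_ids, wi$ds$records$id)
  pred <- predict(model, wi$spectra[idx, , drop = FALSE])
  out_df <- data.frame(
    id = wi$ds$records$id[idx],
    time_min = wi$ds$records$time_min[idx],
    temp_c = wi$ds$records$temp_c[idx],
    measured_pct = wi$measured[idx],
    predicted_pct = pred,
    deviation = pred - wi$measured[idx],
    stringsAsFactors = FALSE
  )
  dir.create(file.path(out, "report"), showWarnings = FALSE)
  write_table(out_df, file.path(out, "report", "predictions.csv"))
}

stage_report <- function(cfg, out) {
  require_artifact(file.path(out, "report", "predictions.csv"), "predict-water")
  scores <- utils::read.csv(require_artifact(
    file.path(out, "scores", "scores.csv"), "score"), stringsAsFactors = FALSE)
  require_artifact(file.path(out, "models", "surface.json"), "fit-surface")
  dir.create(file.path(out, "report", "water_maps"),
             recursive = TRUE, showWarnings = FALSE)

  agg <- stats::aggregate(mean_score ~ set + time_min + temp_c, scores, mean)
  agg <- agg[order(agg$set, agg$temp_c, agg$time_min), ]
  write_table(agg, file.path(out, "report", "score_summary.csv"))
  file.copy(file.path(out, "models", "zone_map.csv"),
            file.path(out, "report", "zone_map.csv"), overwrite = TRUE)

  model <- read_model(file.path(out, "models", "water_model.json"))
  ds <- load_design(cfg, out, "set2", with_masks = TRUE)
  cool <- which(ds$records$temp_c == min(ds$records$temp_c) &
                  ds$records$replicate == 1)
  for (i in cool) {
    wm <- water_map(ds$images[[i]], model = model,
                    gaussian_sigma = cfg$water$gaussian_sigma)
    write_map(wm, file.path(out, "report", "water_maps",
                            paste0(ds$records$id[i], "_water.tif")))
  }
}
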