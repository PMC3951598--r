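#' Pool surface pixels across cookies into a labelled matrix
#'
#' Stacks the spectra of every masked (surface) pixel of every cookie into
#' one matrix; each pixel inherits its cookie's consensus sensory class.
#' This pooled matrix is what the browning discriminant is estimated from.
#'
#' @param images List of [spectral_image()]s.
#' @param masks List of logical masks (defaults to each image's own mask).
#' @param class_labels Character vector, one sensory class per cookie.
#' @return List with `pixels` (matrix, one row per surface pixel, one column
#'   per band) and `groups` (factor of class labels, levels in baking order).
#' @export
build_pixel_dataset <- function(images, masks = NULL, class_labels) {
  stopifnot(length(images) == length(class_labels))
  if (is.null(masks)) masks <- lapply(images, function(im) im$mask)
  stopifnot(length(masks) == length(images))
  present <- intersect(browning_classes(), unique(class_labels))
  if (length(setdiff(unique(class_labels), browning_classes())) > 0) {
    stop("unknown class label")
  }
  blocks <- vector("list", length(images))
  for (i in seq_along(images)) {
    m <- masks[[i]]
    if (is.null(m)) stop("cookie ", i, " has no mask")
    if (!any(m)) {
      warning("cookie ", i, " has an empty mask; contributes no pixels")
      next
    }
    cube <- images[[i]]$cube
    nb <- dim(cube)[3]
    blocks[[i]] <- cbind(
      matrix(cube[rep(m, nb)], ncol = nb),
      i
    )
  }
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  stacked <- do.call(rbind, blocks)
  groups <- factor(class_labels[stacked[, ncol(stacked)]], levels = present)
  # classes whose only cookies had empty masks contribute nothing; drop them
  groups <- droplevels(groups)
  list(pixels = stacked[, -ncol(stacked), drop = FALSE], groups = groups)
}

#' Fit the Fisher-discriminant browning model
#'
#' Estimates the within-group scatter matrix `S_W` and between-group scatter
#' matrix `S_B` from pooled surface-pixel spectra and solves the generalised
#' eigenproblem `(S_W + ridge I)^{-1} S_B` for up to two unit-norm
#' projection vectors (three browning classes give `S_B` rank at most 2).
#' The solve is done on the symmetrised system
#' `W^{-1/2} S_B W^{-1/2}` for numerical stability.
#'
#' The browning score is the projection onto the first loading, oriented so
#' the underbaked (lightest) class has the highest mean score — the score
#' *decreases* with browning — and offset so the mean pixel score of the
#' lightest class is 0 (the "no browning" anchor).
#'
#' @param pixels Numeric matrix, one row per pixel, one column per band.
#' @param groups Factor of sensory classes, one per pixel.
#' @param ridge Ridge added to `S_W`'s diagonal; default
#'   `1e-6 * trace(S_W) / n_bands`. Pass 0 to forbid regularisation.
#' @param wavelengths_nm Optional wavelength grid stored with the model.
#' @return An object of class `fda_model`: loadings (rows = discriminants),
#'   scatter matrices, eigenvalues, per-class mean scores, orientation sign,
#'   score offset and (until [compute_class_limits()] fills them) `NA` class
#'   limits.
#' @export
fit_fda <- function(pixels, groups, ridge = NULL, wavelengths_nm = NULL) {
  pixels <- as.matrix(pixels)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  p <- ncol(pixels)
  if (k < 2) stop("need at least two groups")
  if (nrow(pixels) < p + 1) stop("need more pixels than bands")

  gmeans <- rowsum(pixels, groups) / as.vector(table(groups))
  grand <- colMeans(pixels)
  centered <- pixels - gmeans[as.integer(groups), , drop = FALSE]
  s_w <- crossprod(centered)
  dm <- sweep(gmeans, 2, grand)
  s_b <- crossprod(dm * sqrt(as.vector(table(groups))))

  if (sum(s_b^2) < 1e-24 * max(1, sum(s_w^2))) {
    stop("no separation: group means are identical (S_B = 0)")
  }
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(s_w)) / p
  s_wr <- s_w + diag(ridge, p)
  ew <- eigen(s_wr, symmetric = TRUE)
  if (min(ew$values) <= 0) {
    stop("within-group scatter is singular; increase `ridge`")
  }
  w_half_inv <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  sym <- w_half_inv %*% s_b %*% w_half_inv
  es <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  n_keep <- min(2L, k - 1L)
  loadings <- w_half_inv %*% es$vectors[, seq_len(n_keep), drop = FALSE]
  loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), "/")

  raw_scores <- as.vector(gmeans %*% loadings[, 1])
  lightest <- levels(groups)[1]
  orientation <- if (raw_scores[which(levels(groups) == lightest)] ==
                     max(raw_scores)) 1 else -1
  # flip if the lightest class is not already the top scorer
  if (orientation == -1) raw_scores <- -raw_scores
  offset <- -raw_scores[which(levels(groups) == lightest)]

  structure(list(
    loadings = t(loadings),
    within_scatter = s_w,
    between_scatter = s_b,
    eigenvalues = es$values[seq_len(n_keep)],
    class_mean_scores = stats::setNames(raw_scores + offset, levels(groups)),
    orientation_sign = orientation,
    score_offset = offset,
    ridge = ridge,
    wavelengths_nm = wavelengths_nm,
    limit_under_adequate = NA_real_,
    limit_adequate_over = NA_real_
  ), class = "fda_model")
}

#' @export
print.fda_model <- function(x, ...) {
  cat(sprintf(
    "<fda_model> %d loading(s) over %d bands; class mean scores: %s\n",
    nrow(x$loadings), ncol(x$loadings),
    paste(sprintf("%s=%.3f", names(x$class_mean_scores),
                  x$class_mean_scores), collapse = ", ")
  ))
  if (!is.na(x$limit_under_adequate)) {
    cat(sprintf("  class limits: under/adequate %.3f, adequate/over %.3f\n",
                x$limit_under_adequate, x$limit_adequate_over))
  }
  invisible(x)
}

#' Pixel-wise browning score map
#'
#' Projects every surface pixel onto the first discriminant loading:
#' `score = sign * (loading . spectrum) + offset`. Scores are 0 for
#' unbrowned reference dough and decrease as the surface browns. Background
#' pixels are `NA`.
#'
#' @param img A [spectral_image()].
#' @param mask Logical surface mask (defaults to `img$mask`).
#' @param model A fitted [fit_fda()] model.
#' @return Numeric matrix of scores (`NA` outside the mask).
#' @export
score_pixels <- function(img, mask = img$mask, model) {
  check_grid(model$wavelengths_nm, img$wavelengths_nm)
  nb <- dim(img$cube)[3]
  if (ncol(model$loadings) != nb) {
    stop(sprintf("model has %d bands but image has %d",
                 ncol(model$loadings), nb))
  }
  if (is.null(mask)) stop("no surface mask available")
  px <- matrix(img$cube[rep(mask, nb)], ncol = nb)
  s <- model$orientation_sign * as.vector(px %*% model$loadings[1, ]) +
    model$score_offset
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  out[mask] <- s
  out
}

check_grid <- function(model_wl, img_wl) {
  if (!is.null(model_wl) && !isTRUE(all.equal(as.numeric(model_wl),
                                              as.numeric(img_wl)))) {
    stop("wavelength grid of image does not match the model's")
  }
  invisible(TRUE)
}

#' Average browning score of a cookie
#'
#' @param score_map Score matrix from [score_pixels()].
#' @param mask Logical surface mask.
#' @return Arithmetic mean score over the surface.
#' @export
mean_browning_score <- function(score_map, mask = !is.na(score_map)) {
  if (!any(mask)) stop("empty mask")
  mean(score_map[mask])
}

#' Class limits on the browning-score axis
#'
#' The boundary between underbaked and adequately baked is the midpoint of
#' the mean scores of the 4 and 6 min groups; the boundary between
#' adequately baked and overbaked is the midpoint of the 10 and 12 min
#' groups — the sensory panel's transition times at the reference
#' temperature.
#'
#' @param group_scores Named numeric vector of mean browning scores keyed by
#'   baking time in minutes (names coercible to numeric; must include 4, 6,
#'   10 and 12).
#' @return Named numeric vector `c(limit_under_adequate, limit_adequate_over)`
#'   with `limit_under_adequate > limit_adequate_over` for scores that
#'   decrease with browning.
#' @export
compute_class_limits <- function(group_scores) {
  need <- c("4", "6", "10", "12")
  have <- as.character(as.numeric(names(group_scores)))
  if (!all(need %in% have)) {
    stop("need group mean scores for 4, 6, 10 and 12 min baking")
  }
  g <- stats::setNames(as.numeric(group_scores), have)
  c(limit_under_adequate = mean(g[c("4", "6")]),
    limit_adequate_over = mean(g[c("10", "12")]))
}

#' Attach class limits to a fitted browning model
#'
#' @param model An `fda_model`.
#' @param limits Vector from [compute_class_limits()].
#' @return The model with `limit_under_adequate` / `limit_adequate_over` set.
#' @export
set_class_limits <- function(model, limits) {
  model$limit_under_adequate <- unname(limits[["limit_under_adequate"]])
  model$limit_adequate_over <- unname(limits[["limit_adequate_over"]])
  model
}

#' Pixel-wise browning classification map
#'
#' Smooths the score map with a masked Gaussian filter (background excluded
#' from every local average, so no background values bleed into the rim)
#' and thresholds it into the three browning classes. A pixel exactly on a
#' limit goes to the more-baked class.
#'
#' @param score_map Score matrix from [score_pixels()].
#' @param mask Logical surface mask.
#' @param limits Vector from [compute_class_limits()], or a model with
#'   limits attached.
#' @param gaussian_sigma Smoothing SD in pixels; 0 disables smoothing.
#' @return Character matrix of class labels (`NA` outside the mask).
#' @export
classify_pixels <- function(score_map, mask = !is.na(score_map), limits,
                            gaussian_sigma = 2) {
  if (inherits(limits, "fda_model")) {
    limits <- c(limit_under_adequate = limits$limit_under_adequate,
                limit_adequate_over = limits$limit_adequate_over)
  }
  if (gaussian_sigma < 0) stop("`gaussian_sigma` must be >= 0")
  sm <- if (gaussian_sigma > 0) {
    masked_gaussian(score_map, mask, gaussian_sigma)
  } else score_map
  out <- matrix(NA_character_, nrow(score_map), ncol(score_map))
  cls <- browning_classes()
  v <- sm[mask]
  lab <- ifelse(v > limits[["limit_under_adequate"]], cls[1],
                ifelse(v > limits[["limit_adequate_over"]], cls[2], cls[3]))
  out[mask] <- lab
  out
}

# Normalised (masked) Gaussian convolution: convolve value*mask and mask
# with the same kernel and take the ratio, so background never contributes.
masked_gaussian <- function(map, mask, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  k1 <- exp(-x^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  vals <- map
  vals[!mask | is.na(vals)] <- 0
  num <- EBImage::filter2(vals, kern, boundary = "replicate")
  den <- EBImage::filter2(matrix(as.numeric(mask), nrow(mask)), kern,
                          boundary = "replicate")
  out <- matrix(NA_real_, nrow(map), ncol(map))
  out[mask] <- num[mask] / pmax(den[mask], 1e-12)
  out
}

#' Whole-cookie browning classification
#'
#' Thresholds a cookie's mean browning score with the fitted class limits;
#' a score exactly on a limit is assigned to the more-baked class.
#'
#' @param mean_score Scalar mean browning score (vectorised).
#' @param limits Vector from [compute_class_limits()] or a model with limits.
#' @return Character class label(s).
#' @export
classify_cookie <- function(mean_score, limits) {
  if (inherits(limits, "fda_model")) {
    limits <- c(limit_under_adequate = limits$limit_under_adequate,
                limit_adequate_over = limits$limit_adequate_over)
  }
  cls <- browning_classes()
  ifelse(mean_score > limits[["limit_under_adequate"]], cls[1],
         ifelse(mean_score > limits[["limit_adequate_over"]], cls[2], cls[3]))
}
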