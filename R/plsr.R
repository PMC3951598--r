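#' Gravimetric water content
#'
#' Fraction of water per total cookie weight from the before/after drying
#' weights: `X = (initial - dried) / initial`, reported in percent.
#'
#' @param initial_mass_g Cookie mass before drying (g).
#' @param dried_mass_g Cookie mass after drying to constant weight (g).
#' @return Water content in percent (vectorised).
#' @examples
#' water_fraction(10, 9)  # 10
#' @export
water_fraction <- function(initial_mass_g, dried_mass_g) {
  if (any(dried_mass_g > initial_mass_g)) {
    stop("dried mass exceeds initial mass")
  }
  if (any(dried_mass_g <= 0 | initial_mass_g <= 0)) {
    stop("masses must be positive")
  }
  100 * (initial_mass_g - dried_mass_g) / initial_mass_g
}

#' Mean surface spectrum of a cookie
#'
#' Per-band mean reflectance over the surface mask, optionally excluding
#' bands (e.g. to run an 18-band analysis on a 19-band instrument).
#'
#' @param img A [spectral_image()].
#' @param mask Logical surface mask (defaults to `img$mask`).
#' @param exclude_nm Wavelengths (nm) to drop from the result.
#' @return Named numeric vector (names = wavelengths in nm).
#' @export
mean_spectrum <- function(img, mask = img$mask, exclude_nm = NULL) {
  if (is.null(mask) || !any(mask)) stop("empty mask")
  nb <- dim(img$cube)[3]
  px <- matrix(img$cube[rep(mask, nb)], ncol = nb)
  out <- stats::setNames(colMeans(px), img$wavelengths_nm)
  if (!is.null(exclude_nm)) out <- out[!img$wavelengths_nm %in% exclude_nm]
  out
}

#' Train/test split specification
#'
#' @param train_fraction Fraction of samples assigned to training (2/3 by
#'   default, the conventional split for this calibration size).
#' @param n_folds Folds for cross-validated component selection.
#' @param seed Integer seed for the shuffle.
#' @return List of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 2 / 3, n_folds = 5L, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_folds >= 2)
  structure(list(train_fraction = train_fraction, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)), class = "split_spec")
}

#' Random train/test partition
#'
#' Seeded shuffle followed by a deterministic cut:
#' `|train| = round(train_fraction * n)`; train and test are disjoint and
#' exhaustive.
#'
#' @param ids Vector of sample identifiers (or an integer count).
#' @param spec A [split_spec()].
#' @return List with `train` and `test` id vectors.
#' @export
split_train_test <- function(ids, spec = split_spec()) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- seq_len(ids)
  n <- length(ids)
  if (n < 3) stop("need at least 3 samples to split")
  perm <- withr::with_seed(spec$seed, sample.int(n))
  n_train <- round(spec$train_fraction * n)
  list(train = ids[perm[seq_len(n_train)]],
       test = ids[perm[(n_train + 1L):n]])
}

#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression of a single response on spectra, using
#' the NIPALS algorithm: predictors and response are mean-centred (variance
#' scaling optional, off by default since all bands share reflectance
#' units); each component extracts the weight vector `w = X'y / |X'y|`,
#' scores `t = X w`, loadings `p = X't / t't`, `q = y't / t't`, then
#' deflates `X` and `y`. The final coefficient vector
#' `B = W (P'W)^{-1} q` maps a centred spectrum directly to the response.
#'
#' Zero-variance predictor columns are dropped with a warning and get a
#' zero coefficient.
#'
#' @param spectra Matrix, one row per sample, one column per band.
#' @param y Numeric response (water content in percent).
#' @param n_components Number of latent components.
#' @param scale Logical: autoscale predictor columns to unit variance.
#' @param wavelengths_nm Optional wavelength grid stored with the model.
#' @return Object of class `plsr_model` with centring/scaling vectors,
#'   per-component `weights`, `x_loadings`, `y_loadings`, the
#'   `coefficient_vector` (length = number of bands, on the centred scale)
#'   and `intercept` so that `predict = spectrum . coef + intercept`.
#' @export
fit_plsr <- function(spectra, y, n_components, scale = FALSE,
                     wavelengths_nm = NULL) {
  X <- as.matrix(spectra)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n_components >= 1)
  if (n <= n_components) stop("need more samples than components")

  x_mean <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 1e-12
  if (!all(keep)) warning(sum(!keep), " zero-variance predictor column(s) dropped")
  x_scale <- if (scale) ifelse(keep, sds, 1) else rep(1, p)
  Xc <- sweep(sweep(X[, keep, drop = FALSE], 2, x_mean[keep]), 2,
              x_scale[keep], "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  pk <- ncol(Xc)
  A <- min(n_components, pk)
  W <- P <- matrix(0, pk, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { A <- a - 1L; break }
    w <- w / nw
    tt <- Xc %*% w
    t2 <- sum(tt^2)
    pv <- crossprod(Xc, tt) / t2
    qa <- sum(yc * tt) / t2
    Xc <- Xc - tt %*% t(pv)
    yc <- yc - tt * qa
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  if (A < 1) stop("response is orthogonal to all predictors")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]

  b_kept <- W %*% solve(crossprod(P, W), q)
  coef <- numeric(p)
  coef[keep] <- b_kept / x_scale[keep]
  intercept <- y_mean - sum(x_mean * coef)

  structure(list(
    n_components = A,
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = q,
    kept_bands = which(keep),
    coefficient_vector = coef,
    intercept = intercept,
    scaled = scale,
    wavelengths_nm = wavelengths_nm
  ), class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d component(s), %d bands\n",
              x$n_components, length(x$coefficient_vector)))
  invisible(x)
}

#' Predict water content from spectra
#'
#' @param object A [fit_plsr()] model.
#' @param newdata Matrix (rows = samples) or single spectrum vector.
#' @param ... Unused.
#' @return Predicted response (percent water).
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != length(object$coefficient_vector)) {
    stop(sprintf("model has %d bands but data has %d",
                 length(object$coefficient_vector), ncol(X)))
  }
  as.vector(X %*% object$coefficient_vector) + object$intercept
}

#' Select the PLSR component count by cross-validation
#'
#' K-fold cross-validation on the training set: samples are shuffled with
#' the split seed and the folds cut contiguously from the shuffled order.
#' For each candidate component count the mean across-fold RMSEP is
#' computed; the smallest count whose CV error is within 1 % of the minimum
#' is returned (parsimony tie rule).
#'
#' @param spectra Training spectra matrix.
#' @param y Training response.
#' @param spec A [split_spec()] (uses `n_folds` and `seed`).
#' @param max_components Largest component count to try.
#' @return List with `n_components` (the selection) and `cv_rmsep` (the
#'   error curve).
#' @export
cv_select_components <- function(spectra, y, spec = split_spec(),
                                 max_components = 10L) {
  X <- as.matrix(spectra)
  n <- nrow(X)
  if (n < spec$n_folds) stop("fewer samples than folds")
  max_components <- min(max_components, ncol(X), n - ceiling(n / spec$n_folds) - 1L)
  perm <- withr::with_seed(spec$seed, sample.int(n))
  fold_id <- rep(seq_len(spec$n_folds),
                 length.out = 0) # placeholder, replaced below
  sizes <- diff(round(seq(0, n, length.out = spec$n_folds + 1)))
  fold_id <- rep(seq_len(spec$n_folds), times = sizes)[order(perm)]

  errs <- matrix(NA_real_, spec$n_folds, max_components)
  for (f in seq_len(spec$n_folds)) {
    tr <- fold_id != f
    for (a in seq_len(max_components)) {
      m <- suppressWarnings(fit_plsr(X[tr, , drop = FALSE], y[tr], a))
      errs[f, a] <- rmsep(predict(m, X[!tr, , drop = FALSE]), y[!tr])
    }
  }
  curve <- colMeans(errs)
  best <- min(curve)
  list(n_components = which(curve <= best * 1.01)[1], cv_rmsep = curve)
}

#' Root mean squared error of prediction
#'
#' `RMSEP = sqrt( sum((yhat - y)^2) / n )`.
#'
#' @param predicted,measured Equal-length numeric vectors (percent water).
#' @return Non-negative scalar; 0 exactly when predictions are exact.
#' @examples
#' rmsep(c(2.0), c(1.5))  # 0.5
#' @export
rmsep <- function(predicted, measured) {
  if (length(predicted) != length(measured)) stop("length mismatch")
  if (length(predicted) < 1) stop("need at least one pair")
  sqrt(mean((predicted - measured)^2))
}

#' Pixel-wise water-content map
#'
#' Applies the PLSR coefficient vector to every surface pixel and smooths
#' the result with a masked Gaussian filter. For `gaussian_sigma = 0` and a
#' linear model the map average equals the prediction from the mean
#' spectrum.
#'
#' @param img A [spectral_image()].
#' @param mask Logical surface mask (defaults to `img$mask`).
#' @param model A [fit_plsr()] model.
#' @param gaussian_sigma Smoothing SD in pixels; 0 disables smoothing.
#' @return Numeric matrix of percent water (`NA` outside the mask).
#' @export
water_map <- function(img, mask = img$mask, model, gaussian_sigma = 2) {
  check_grid(model$wavelengths_nm, img$wavelengths_nm)
  nb <- dim(img$cube)[3]
  if (nb != length(model$coefficient_vector)) {
    stop(sprintf("model has %d bands but image has %d",
                 length(model$coefficient_vector), nb))
  }
  if (is.null(mask)) stop("no surface mask available")
  px <- matrix(img$cube[rep(mask, nb)], ncol = nb)
  pred <- predict(model, px)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  out[mask] <- pred
  if (gaussian_sigma > 0) out <- masked_gaussian(out, mask, gaussian_sigma)
  out
}

#' PCA of mean spectra
#'
#' Mean-centred principal component analysis of the cookie mean spectra,
#' used as a diagnostic: the first component should track the dominant
#' baking trend (and hence water content).
#'
#' @param spectra Matrix of mean spectra, one row per cookie.
#' @return List with `scores` (samples x components), `explained_variance`
#'   (fractions summing to 1) and the `rotation` matrix.
#' @export
pca_mean_spectra <- function(spectra) {
  X <- as.matrix(spectra)
  if (nrow(X) < 2) stop("need at least two samples")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, explained_variance = ev / sum(ev), rotation = pc$rotation)
}
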