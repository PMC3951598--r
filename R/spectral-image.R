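#' Multispectral image container
#'
#' A `spectral_image` bundles a reflectance cube with its wavelength grid and
#' an optional surface mask. It is the single carrier of pixel data in
#' bakevision: the simulator produces it, segmentation annotates it, and the
#' browning and water models consume it.
#'
#' @param cube Numeric array `height x width x n_bands` of reflectance values
#'   in `[0, 1]`.
#' @param wavelengths_nm Strictly increasing numeric vector of band-center
#'   wavelengths in nanometres; length must equal `dim(cube)[3]`.
#' @param mask Optional logical matrix `height x width`; `TRUE` marks cookie
#'   surface pixels. `NULL` when no segmentation has been applied.
#'
#' @return An object of class `spectral_image`: a list with elements `cube`,
#'   `wavelengths_nm` and `mask`.
#' @examples
#' img <- spectral_image(array(0.5, c(4, 4, 3)), c(450, 630, 970))
#' dim(img$cube)
#' @export
spectral_image <- function(cube, wavelengths_nm, mask = NULL) {
  cube <- unclass(cube)
  if (!is.array(cube) || length(dim(cube)) != 3L) {
    stop("`cube` must be a 3-d array (height x width x bands)")
  }
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(cube)[3L]) {
    stop(sprintf(
      "band count mismatch: cube has %d bands but %d wavelengths given",
      dim(cube)[3L], length(wavelengths_nm)
    ))
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("`wavelengths_nm` must be strictly increasing")
  }
  rng <- range(cube, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("reflectance values must lie in [0, 1]")
  }
  if (!is.null(mask)) {
    if (!is.logical(mask)) mask <- matrix(as.logical(mask), nrow(mask))
    if (!identical(dim(mask), dim(cube)[1:2])) {
      stop("`mask` dimensions must match the cube's spatial dimensions")
    }
  }
  structure(list(cube = cube, wavelengths_nm = wavelengths_nm, mask = mask),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf(
    "<spectral_image> %d x %d pixels, %d bands (%.0f-%.0f nm)%s\n",
    d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
    if (is.null(x$mask)) "" else sprintf(", %d surface px", sum(x$mask))
  ))
  invisible(x)
}

#' Index of the band nearest a target wavelength
#'
#' @param img A [spectral_image()].
#' @param target_nm Wavelength in nanometres.
#' @return Integer band index minimising `|wavelength - target|`.
#' @keywords internal
nearest_band <- function(img, target_nm) {
  which.min(abs(img$wavelengths_nm - target_nm))
}

#' Pseudo-RGB rendering of a multispectral cube
#'
#' Picks the bands nearest 630 nm (red), 525 nm (green) and 450 nm (blue) and
#' contrast-stretches each channel to `[0, 1]` for visual inspection. A
#' channel with no dynamic range is returned unchanged (a constant cube thus
#' renders as flat grey).
#'
#' @param img A [spectral_image()] whose grid covers the visible range.
#' @return Numeric array `height x width x 3` in `[0, 1]`.
#' @examples
#' img <- spectral_image(array(runif(4 * 4 * 3), c(4, 4, 3)), c(450, 525, 630))
#' rgb <- pseudo_rgb(img)
#' @export
pseudo_rgb <- function(img) {
  stopifnot(inherits(img, "spectral_image"))
  if (min(img$wavelengths_nm) >= 500) {
    stop("pseudo-RGB needs at least one band below 500 nm")
  }
  targets <- c(630, 525, 450)
  out <- array(0, c(dim(img$cube)[1:2], 3L))
  for (k in seq_along(targets)) {
    ch <- img$cube[, , nearest_band(img, targets[k])]
    rng <- range(ch)
    if (diff(rng) > 1e-12) ch <- (ch - rng[1]) / diff(rng)
    out[, , k] <- pmin(pmax(ch, 0), 1)
  }
  out
}
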