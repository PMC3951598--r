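#' Segment the cookie surface from the background
#'
#' Adaptive local-mean thresholding on the across-band mean of the visible
#' channels (bands at or below 700 nm; near-infrared contrast varies with
#' water and is excluded). A pixel is foreground when its intensity exceeds
#' the local mean over a square window by more than `offset`. The raw mask
#' is then cleaned by keeping the largest 4-connected component and filling
#' its holes, so exactly one solid surface region remains.
#'
#' Because the threshold is the *local mean* plus an offset, the mask is
#' unaffected by a global gain change provided `offset` is scaled with it.
#'
#' @param img A [spectral_image()].
#' @param window_px Side of the local averaging window; default one quarter
#'   of the shorter image side.
#' @param offset Intensity margin above the local mean required for
#'   foreground.
#' @return Logical mask matrix (`TRUE` = cookie surface).
#' @examples
#' ds <- render_image(baking_condition(8, 180),
#'                    sim_config(image_size = 48L, noise_sd = 0))
#' m <- segment(ds$image)
#' sum(m & ds$image$mask) / sum(ds$image$mask)  # close to 1
#' @export
segment <- function(img, window_px = NULL, offset = 0.02) {
  stopifnot(inherits(img, "spectral_image"))
  vis <- which(img$wavelengths_nm <= 700)
  if (length(vis) == 0L) vis <- seq_along(img$wavelengths_nm)
  intensity <- apply(img$cube[, , vis, drop = FALSE], c(1, 2), mean)

  n <- min(dim(intensity))
  if (is.null(window_px)) window_px <- max(3L, round(n / 4))
  window_px <- as.integer(window_px)
  if (window_px %% 2L == 0L) window_px <- window_px + 1L

  kern <- matrix(1 / window_px^2, window_px, window_px)
  local_mean <- EBImage::filter2(intensity, kern, boundary = "replicate")
  raw <- intensity > local_mean + offset
  if (!any(raw)) stop("no surface found")

  labels <- EBImage::bwlabel(raw)
  counts <- tabulate(labels[labels > 0])
  keep <- which.max(counts)
  mask <- labels == keep
  mask <- EBImage::fillHull(mask) > 0
  matrix(as.logical(mask), nrow(intensity))
}
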