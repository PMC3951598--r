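#' Write a multispectral image to disk
#'
#' The cube is stored as a band-interleaved multi-page TIFF (one 32-bit float
#' page per band, pages ordered by increasing wavelength) with the wavelength
#' grid in a JSON sidecar next to it (`<path>.json` by default). Keeping the
#' wavelengths in a sidecar rather than TIFF tags makes the container
#' readable by any TIFF implementation.
#'
#' @param img A [spectral_image()].
#' @param path Output TIFF path.
#' @param sidecar Path of the JSON sidecar; defaults to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @seealso [read_image()]
#' @export
write_image <- function(img, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(img, "spectral_image"))
  pages <- lapply(seq_along(img$wavelengths_nm), function(b) img$cube[, , b])
  write_float_tiff(pages, path)
  jsonlite::write_json(
    list(wavelengths_nm = img$wavelengths_nm),
    sidecar, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' Read a multispectral image from disk
#'
#' Reads a multi-page TIFF written by [write_image()] and its JSON wavelength
#' sidecar. The sidecar must list exactly one wavelength per TIFF page, in
#' strictly increasing order.
#'
#' @param path TIFF path.
#' @param sidecar JSON sidecar path; defaults to `paste0(path, ".json")`.
#' @return A [spectral_image()] (mask not stored; see [write_mask()]).
#' @export
read_image <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) {
    stop(sprintf("missing wavelength sidecar '%s'", sidecar))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  wl <- as.numeric(jsonlite::read_json(sidecar, simplifyVector = TRUE)$wavelengths_nm)
  if (length(wl) != length(pages)) {
    stop(sprintf(
      "sidecar lists %d wavelengths but TIFF has %d pages",
      length(wl), length(pages)
    ))
  }
  cube <- array(0, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) cube[, , b] <- pages[[b]]
  spectral_image(cube, wl)
}

#' Write / read a surface mask
#'
#' Masks are serialized as single-page 8-bit TIFFs (0 = background,
#' 255 = surface) alongside the image they belong to.
#'
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   logical matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Write a single-band map (score or water) as 32-bit float TIFF
#'
#' Values are stored shifted/scaled to `[0,1]` with the affine transform kept
#' in a JSON sidecar, since baseline TIFF stores normalized intensities.
#'
#' @param map Numeric matrix (may contain `NA` outside the mask; stored as 0).
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  rng <- range(map, na.rm = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- (map - rng[1]) / scale
  norm[is.na(norm)] <- 0
  write_float_tiff(list(norm), path)
  jsonlite::write_json(list(offset = rng[1], scale = scale),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Lays out a dataset the way the pipeline expects it:
#' `images/<set>_<time>_<temp>_<rep>.tif` (+ JSON wavelength sidecars),
#' `wavelengths.json`, `samples.csv` (cookie metadata, masses and panel
#' votes) and `truth.csv` (simulator ground truth). Serialization is
#' deterministic: records are written in design order with fixed column
#' order and full precision, so identical datasets produce byte-identical
#' files.
#'
#' @param dataset A dataset list as returned by [generate_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  recs <- dataset$records
  for (i in seq_len(nrow(recs))) {
    write_image(dataset$images[[i]], file.path(dir, "images", paste0(recs$id[i], ".tif")))
  }
  jsonlite::write_json(
    list(wavelengths_nm = dataset$images[[1]]$wavelengths_nm),
    file.path(dir, "wavelengths.json"), digits = NA, auto_unbox = FALSE
  )
  write_table(recs, file.path(dir, "samples.csv"))
  write_table(dataset$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @param masks_dir Optional directory of `<id>_mask.tif` files to attach.
#' @return A list with `images`, `records`, `truth` (truth may be `NULL` for
#'   real data directories without a `truth.csv`).
#' @export
read_dataset <- function(dir, masks_dir = NULL) {
  recs <- utils::read.csv(file.path(dir, "samples.csv"), stringsAsFactors = FALSE)
  images <- lapply(recs$id, function(id) {
    img <- read_image(file.path(dir, "images", paste0(id, ".tif")))
    if (!is.null(masks_dir)) {
      mp <- file.path(masks_dir, paste0(id, "_mask.tif"))
      if (file.exists(mp)) img$mask <- read_mask(mp)
    }
    img
  })
  tp <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tp)) utils::read.csv(tp, stringsAsFactors = FALSE) else NULL
  list(images = images, records = recs, truth = truth)
}

# Minimal deterministic multi-page 32-bit IEEE-float TIFF writer
# (little-endian, uncompressed, one strip per page, no timestamp tags).
# The tiff package reads float TIFFs but only writes normalized-integer
# samples, which quantize the data; writing the container directly keeps
# the pixels bit-exact. `tiff::readTIFF()` serves as the independent
# reader that validates the files this produces.
write_float_tiff <- function(pages, path) {
  stopifnot(length(pages) > 0)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  entry_short <- function(tag, value) { w2(tag); w2(3L); w4(1L); w2(value); w2(0L) }
  entry_long <- function(tag, value) { w2(tag); w2(4L); w4(1L); w4(value) }
  n_entries <- 10L
  ifd_len <- 2L + 12L * n_entries + 4L
  data_len <- vapply(pages, function(m) 4L * length(m), integer(1))
  # layout: header, then per page [pixel data][IFD]
  data_off <- 8L + cumsum(c(0L, utils::head(data_len + ifd_len, -1L)))
  ifd_off <- data_off + data_len
  writeBin(charToRaw("II"), con)   # little-endian byte order
  w2(42L)                          # TIFF magic
  w4(ifd_off[1])
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    w2(n_entries)
    entry_long(256L, ncol(m))          # ImageWidth
    entry_long(257L, nrow(m))          # ImageLength
    entry_short(258L, 32L)             # BitsPerSample
    entry_short(259L, 1L)              # Compression: none
    entry_short(262L, 1L)              # Photometric: BlackIsZero
    entry_long(273L, data_off[i])      # StripOffsets
    entry_short(277L, 1L)              # SamplesPerPixel
    entry_long(278L, nrow(m))          # RowsPerStrip
    entry_long(279L, data_len[i])      # StripByteCounts
    entry_short(339L, 3L)              # SampleFormat: IEEE float
    w4(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

# Deterministic CSV writer: comma-separated, UTF-8, header, "." decimal,
# no row names, 15 significant digits.
write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Save / load fitted models as JSON
#'
#' Serializes `fda_model`, `plsr_model` and `response_surface` objects to a
#' plain JSON file with full numeric precision, preserving the class so the
#' object round-trips.
#'
#' @param model A fitted bakevision model object.
#' @param path JSON path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the model.
#' @export
write_model <- function(model, path) {
  payload <- list(class = class(model)[1], fields = unclass(model))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- payload$fields
  for (nm in c("loadings", "within_scatter", "between_scatter",
               "weights", "x_loadings")) {
    if (!is.null(fields[[nm]]) && is.null(dim(fields[[nm]])) &&
        length(fields[[nm]]) > 0 && is.list(fields[[nm]])) {
      fields[[nm]] <- do.call(rbind, fields[[nm]])
    }
  }
  structure(fields, class = payload$class)
}
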