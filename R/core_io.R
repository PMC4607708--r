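#' Scan calibration
#'
#' Geometry of an OCT B-scan: axial sampling in micrometres per pixel row,
#' nominal lateral scan length in millimetres and the number of A-scan
#' columns. The lateral sampling (micrometres per column) is always derived
#' as `scan_length_mm * 1000 / n_ascans` and never stored, so the two cannot
#' drift apart.
#'
#' @param axial_scale_um Axial sampling, micrometres per pixel (> 0).
#' @param scan_length_mm Nominal lateral extent of the scan in mm (> 0).
#' @param n_ascans Number of A-scan columns (>= 2).
#' @return An object of class `oct_calibration`.
#' @examples
#' cal <- oct_calibration(3.87, 8.7, 768)
#' lateral_scale_um(cal)  # ~11.33 um per column
#' @export
oct_calibration <- function(axial_scale_um, scan_length_mm, n_ascans) {
  axial_scale_um <- as.numeric(axial_scale_um)
  scan_length_mm <- as.numeric(scan_length_mm)
  n_ascans <- as.integer(n_ascans)
  if (length(axial_scale_um) != 1L || !is.finite(axial_scale_um) ||
      axial_scale_um <= 0) {
    stop("`axial_scale_um` must be a single positive number", call. = FALSE)
  }
  if (length(scan_length_mm) != 1L || !is.finite(scan_length_mm) ||
      scan_length_mm <= 0) {
    stop("`scan_length_mm` must be a single positive number", call. = FALSE)
  }
  if (length(n_ascans) != 1L || is.na(n_ascans) || n_ascans < 2L) {
    stop("`n_ascans` must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(axial_scale_um = axial_scale_um,
         scan_length_mm = scan_length_mm,
         n_ascans = n_ascans),
    class = "oct_calibration"
  )
}

#' Lateral sampling of a calibration
#'
#' @param cal An [oct_calibration()].
#' @return Micrometres per A-scan column.
#' @export
lateral_scale_um <- function(cal) {
  stopifnot(inherits(cal, "oct_calibration"))
  cal$scan_length_mm * 1000 / cal$n_ascans
}

#' @export
print.oct_calibration <- function(x, ...) {
  cat(sprintf("OCT calibration: %.4g um/px axial, %g mm / %d A-scans (%.4g um/col)\n",
              x$axial_scale_um, x$scan_length_mm, x$n_ascans,
              lateral_scale_um(x)))
  invisible(x)
}

#' B-scan container
#'
#' A 2-D intensity image (rows indexed from the top, i.e. the vitreous side,
#' down to the choroid) together with its calibration and an identifier.
#' Column count must match `calibration$n_ascans`.
#'
#' @param image Numeric matrix of non-negative, finite intensities.
#' @param calibration An [oct_calibration()].
#' @param id Scan identifier string.
#' @return An object of class `oct_scan`.
#' @export
oct_scan <- function(image, calibration, id = "scan") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (!inherits(calibration, "oct_calibration")) {
    stop("`calibration` must be an oct_calibration object", call. = FALSE)
  }
  if (ncol(image) != calibration$n_ascans) {
    stop(sprintf(
      "image has %d columns but calibration declares %d A-scans",
      ncol(image), calibration$n_ascans), call. = FALSE)
  }
  if (any(!is.finite(image)) || min(image) < 0) {
    stop("image intensities must be finite and non-negative", call. = FALSE)
  }
  structure(list(image = image, calibration = calibration,
                 id = as.character(id)[1L]),
            class = "oct_scan")
}

#' @export
print.oct_scan <- function(x, ...) {
  cat(sprintf("OCT B-scan '%s': %d rows x %d A-scans, intensities [%.3g, %.3g]\n",
              x$id, nrow(x$image), ncol(x$image),
              min(x$image), max(x$image)))
  print(x$calibration)
  invisible(x)
}

#' @export
dim.oct_scan <- function(x) dim(x$image)

#' @export
plot.oct_scan <- function(x, ...) {
  img <- x$image
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1L]) / diff(rng)
  # image() draws row 1 at the bottom; flip so the vitreous is on top
  graphics::image(t(img[nrow(img):1L, , drop = FALSE]),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("sidecar file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  sc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  required <- c("axial_scale_um_per_px", "scan_length_mm", "n_ascans")
  missing_keys <- setdiff(required, names(sc))
  if (length(missing_keys)) {
    stop(sprintf("sidecar %s is missing required key(s): %s", path,
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  sc
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    # grayscale stored in RGB(A): average the colour channels
    img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  }
  img
}

#' Load a B-scan from an image file and a calibration sidecar
#'
#' Reads a single-channel (or grayscale-in-RGB) PNG or TIFF raster plus a
#' JSON/YAML sidecar holding keys `axial_scale_um_per_px`, `scan_length_mm`,
#' `n_ascans` and optionally `id`. The image column count must equal
#' `n_ascans`.
#'
#' @param image_path Path to a PNG or TIFF file.
#' @param sidecar_path Path to the JSON or YAML calibration sidecar.
#' @return An [oct_scan()].
#' @export
load_bscan <- function(image_path, sidecar_path) {
  sc <- read_sidecar(sidecar_path)
  img <- read_raster(image_path)
  cal <- oct_calibration(sc$axial_scale_um_per_px, sc$scan_length_mm,
                         sc$n_ascans)
  id <- if (!is.null(sc$id)) sc$id else
    tools::file_path_sans_ext(basename(image_path))
  oct_scan(img, cal, id = id)
}

#' Save a B-scan to an image file and a calibration sidecar
#'
#' The image is written as 16-bit TIFF or PNG (intensities are expected in
#' `[0, 1]`; values outside are clipped). The sidecar is JSON or YAML,
#' chosen from the file extension.
#'
#' @param scan An [oct_scan()].
#' @param image_path Output PNG/TIFF path.
#' @param sidecar_path Output JSON/YAML path.
#' @return `invisible(scan)`.
#' @export
save_bscan <- function(scan, image_path, sidecar_path) {
  stopifnot(inherits(scan, "oct_scan"))
  img <- pmin(pmax(scan$image, 0), 1)
  ext <- tolower(tools::file_ext(image_path))
  switch(ext,
    png = png::writePNG(img, image_path),
    tif = ,
    tiff = tiff::writeTIFF(img, image_path, bits.per.sample = 16L),
    stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  sc <- list(axial_scale_um_per_px = scan$calibration$axial_scale_um,
             scan_length_mm = scan$calibration$scan_length_mm,
             n_ascans = scan$calibration$n_ascans,
             id = scan$id)
  sext <- tolower(tools::file_ext(sidecar_path))
  if (sext %in% c("yaml", "yml")) {
    yaml::write_yaml(sc, sidecar_path)
  } else {
    jsonlite::write_json(sc, sidecar_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(scan)
}

#' Rescale scan intensities linearly to [0, 1]
#'
#' Constant images cannot be rescaled; they map to all zeros with a warning.
#' Idempotent on already-normalized input.
#'
#' @param scan An [oct_scan()].
#' @return An [oct_scan()] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(scan) {
  stopifnot(inherits(scan, "oct_scan"))
  rng <- range(scan$image)
  if (diff(rng) == 0) {
    warning("constant image: normalizing to all zeros", call. = FALSE)
    scan$image <- array(0, dim = dim(scan$image))
  } else {
    scan$image <- (scan$image - rng[1L]) / diff(rng)
  }
  scan
}
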