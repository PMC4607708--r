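#' Segmentation configuration
#'
#' Tunable parameters of the boundary-tracing pipeline. Micrometre offsets
#' are converted to pixels with the scan's axial calibration at run time.
#'
#' @param max_shift Flattening: largest admissible per-column axial lag (px).
#' @param max_jump Largest per-column row step of a boundary path (px).
#' @param band_halfwidth Half-width (px) of the band around the initial RPE
#'   row estimate used to refine the RPE centerline.
#' @param isos_offset_um Band for the IS/OS top, micrometres above the RPE
#'   centerline, `c(min, max)`.
#' @param rpe_outer_offset_um Band for the RPE outer border, micrometres
#'   below the centerline, `c(min, max)`.
#' @param ilm_margin_um The ILM is searched from the top of the image down
#'   to this far above the IS/OS top.
#' @param smooth_sigma Axial Gaussian pre-smoothing of the normalized image
#'   before cost construction, in pixels (0 disables).
#' @param smooth_sigma_lateral Lateral Gaussian pre-smoothing in pixels;
#'   retinal boundaries are laterally smooth, so averaging across columns
#'   suppresses speckle without displacing the edges (0 disables).
#' @param confidence_threshold Mean path cost above which a gradient
#'   boundary is flagged low-confidence.
#' @return A list of class `oct_seg_config`.
#' @export
oct_seg_config <- function(max_shift = 20L, max_jump = 2L,
                           band_halfwidth = 10L,
                           isos_offset_um = c(10, 80),
                           rpe_outer_offset_um = c(2, 40),
                           ilm_margin_um = 30,
                           smooth_sigma = 1,
                           smooth_sigma_lateral = 3,
                           confidence_threshold = 0.75) {
  stopifnot(length(isos_offset_um) == 2L, isos_offset_um[1L] > 0,
            isos_offset_um[1L] < isos_offset_um[2L],
            length(rpe_outer_offset_um) == 2L, rpe_outer_offset_um[1L] > 0,
            rpe_outer_offset_um[1L] < rpe_outer_offset_um[2L],
            ilm_margin_um >= 0, smooth_sigma >= 0,
            smooth_sigma_lateral >= 0)
  structure(list(max_shift = as.integer(max_shift),
                 max_jump = as.integer(max_jump),
                 band_halfwidth = as.integer(band_halfwidth),
                 isos_offset_um = as.numeric(isos_offset_um),
                 rpe_outer_offset_um = as.numeric(rpe_outer_offset_um),
                 ilm_margin_um = as.numeric(ilm_margin_um),
                 smooth_sigma = as.numeric(smooth_sigma),
                 smooth_sigma_lateral = as.numeric(smooth_sigma_lateral),
                 confidence_threshold = as.numeric(confidence_threshold)),
            class = "oct_seg_config")
}

# separable anisotropic Gaussian blur; edges handled by replication
gaussian_smooth <- function(img, sigma_axial, sigma_lateral = sigma_axial) {
  img <- smooth_axial(img, sigma_axial)
  t(smooth_axial(t(img), sigma_lateral))
}

um_to_px <- function(um, cal) um / cal$axial_scale_um

# log-scale a normalized image and rescale to [0, 1]: the standard OCT
# display domain, where speckle is additive and homoskedastic and the
# vitreous-to-retina contrast is the strongest edge
log_rescale <- function(img, eps = 0.01) {
  v <- log(img + eps)
  rng <- range(v)
  if (diff(rng) == 0) return(v * 0)
  (v - rng[1L]) / diff(rng)
}

#' Initial estimate of the RPE row
#'
#' The RPE is the most hyper-reflective band, so the row with the highest
#' intensity sum of a flattened scan is a robust starting point. The
#' row-sum profile of a speckled scan is noisy and residual (+/- 1 px)
#' alignment scatter blunts narrow peaks, so the profile is Gaussian
#' smoothed before the argmax; ties go to the smaller row.
#'
#' @param scan A normalized, aligned [oct_scan()] (or matrix).
#' @param smooth_sigma Gaussian smoothing of the row-sum profile (px);
#'   0 disables.
#' @return Integer row index.
#' @export
estimate_rpe_row <- function(scan, smooth_sigma = 2) {
  img <- if (inherits(scan, "oct_scan")) scan$image else scan
  prof <- rowSums(img)
  if (smooth_sigma > 0) {
    prof <- smooth_axial(matrix(prof, ncol = 1L), smooth_sigma)[, 1L]
  }
  which.max(prof)
}

path_with_confidence <- function(path, threshold) {
  path$low_confidence <- path$mean_cost > threshold
  if (path$low_confidence) {
    warning(sprintf("boundary '%s' has mean path cost %.3f > %.3f: low confidence",
                    path$layer_name, path$mean_cost, threshold),
            call. = FALSE)
  }
  path
}

#' Refine the RPE centerline
#'
#' Minimal path through the negated B-scan in a narrow band around the
#' initial row estimate, so the path locks onto the brightest band.
#'
#' @param scan Normalized, aligned [oct_scan()].
#' @param initial_row Starting row estimate (see [estimate_rpe_row()]).
#' @param band_halfwidth Band half-width in pixels.
#' @param max_jump Per-column step bound.
#' @param anchors Optional anchor data frame (`column`, `row`).
#' @param smooth_sigma Axial Gaussian pre-smoothing in pixels.
#' @param smooth_sigma_lateral Lateral Gaussian pre-smoothing in pixels.
#' @return A [shortest_path()] result labelled `RPE_CENTER`.
#' @export
segment_rpe_center <- function(scan, initial_row, band_halfwidth = 10L,
                               max_jump = 2L, anchors = NULL,
                               smooth_sigma = 1, smooth_sigma_lateral = 3) {
  img <- gaussian_smooth(scan$image, smooth_sigma, smooth_sigma_lateral)
  band <- search_band(initial_row - band_halfwidth,
                      initial_row + band_halfwidth,
                      nrow(img), ncol(img))
  shortest_path(negate_image(pmin(pmax(img, 0), 1)), band, max_jump,
                anchors, layer_name = "RPE_CENTER")
}

#' Segment the top of the IS/OS band
#'
#' Minimal path through the dark-to-bright vertical-gradient cost image in a
#' per-column band a configurable distance above the RPE centerline.
#'
#' @param scan Normalized, aligned [oct_scan()].
#' @param rpe_center `boundary_path` for the RPE centerline.
#' @param offset_min_um,offset_max_um Band limits above the centerline, um.
#' @param max_jump Per-column step bound.
#' @param anchors Optional anchors.
#' @param smooth_sigma Axial Gaussian pre-smoothing in pixels.
#' @param smooth_sigma_lateral Lateral Gaussian pre-smoothing in pixels.
#' @param confidence_threshold Mean-cost threshold for the low-confidence flag.
#' @return A `boundary_path` labelled `ISOS`.
#' @export
segment_isos <- function(scan, rpe_center, offset_min_um = 10,
                         offset_max_um = 80, max_jump = 2L, anchors = NULL,
                         smooth_sigma = 1, smooth_sigma_lateral = 3,
                         confidence_threshold = 0.75) {
  stopifnot(offset_min_um > 0, offset_min_um < offset_max_um)
  cal <- scan$calibration
  img <- gaussian_smooth(log_rescale(scan$image), smooth_sigma,
                         smooth_sigma_lateral)
  band <- search_band(rpe_center$rows - round(um_to_px(offset_max_um, cal)),
                      rpe_center$rows - round(um_to_px(offset_min_um, cal)),
                      nrow(img), ncol(img))
  p <- shortest_path(vertical_gradient(img, "dark_to_bright"), band,
                     max_jump, anchors, layer_name = "ISOS")
  path_with_confidence(p, confidence_threshold)
}

#' Segment the outer RPE border
#'
#' As [segment_isos()], but the band lies below the RPE centerline and the
#' gradient polarity is bright-to-dark (RPE into the dimmer choroid).
#'
#' @inheritParams segment_isos
#' @param offset_min_um,offset_max_um Band limits below the centerline, um.
#' @return A `boundary_path` labelled `RPE_OUTER`.
#' @export
segment_rpe_outer <- function(scan, rpe_center, offset_min_um = 2,
                              offset_max_um = 40, max_jump = 2L,
                              anchors = NULL, smooth_sigma = 1,
                              smooth_sigma_lateral = 3,
                              confidence_threshold = 0.75) {
  stopifnot(offset_min_um > 0, offset_min_um < offset_max_um)
  cal <- scan$calibration
  img <- gaussian_smooth(log_rescale(scan$image), smooth_sigma,
                         smooth_sigma_lateral)
  band <- search_band(rpe_center$rows + round(um_to_px(offset_min_um, cal)),
                      rpe_center$rows + round(um_to_px(offset_max_um, cal)),
                      nrow(img), ncol(img))
  p <- shortest_path(vertical_gradient(img, "bright_to_dark"), band,
                     max_jump, anchors, layer_name = "RPE_OUTER")
  path_with_confidence(p, confidence_threshold)
}

#' Segment the inner limiting membrane
#'
#' Dark-to-bright gradient path searched from the top of the image down to a
#' safety margin above the IS/OS top, so the strong outer-retinal edges are
#' excluded and the vitreoretinal surface is the dominant edge in band.
#'
#' @inheritParams segment_isos
#' @param isos `boundary_path` for the IS/OS top.
#' @param margin_um Lower band limit: this far above the IS/OS top.
#' @return A `boundary_path` labelled `ILM`.
#' @export
segment_ilm <- function(scan, isos, margin_um = 30, max_jump = 2L,
                        anchors = NULL, smooth_sigma = 1,
                        smooth_sigma_lateral = 3,
                        confidence_threshold = 0.75) {
  stopifnot(margin_um >= 0)
  cal <- scan$calibration
  img <- gaussian_smooth(log_rescale(scan$image), smooth_sigma,
                         smooth_sigma_lateral)
  band <- search_band(1L, isos$rows - round(um_to_px(margin_um, cal)),
                      nrow(img), ncol(img))
  p <- shortest_path(vertical_gradient(img, "dark_to_bright"), band,
                     max_jump, anchors, layer_name = "ILM")
  path_with_confidence(p, confidence_threshold)
}

shift_anchor_rows <- function(anchors, shifts, sign = -1L) {
  if (is.null(anchors) || NROW(anchors) == 0L) return(anchors)
  a <- as.data.frame(anchors)
  a$row <- a$row + sign * shifts[a$column]
  a
}

check_ordering <- function(ilm, isos, rpe_center, rpe_outer) {
  n <- length(ilm)
  interior <- if (n > 2L) 2L:(n - 1L) else integer(0)
  bad_edge <- which(ilm > isos | isos > rpe_center | rpe_center > rpe_outer)
  bad_int <- intersect(
    which(ilm >= isos | isos >= rpe_center | rpe_center >= rpe_outer),
    interior)
  sort(unique(c(bad_edge, bad_int)))
}

#' Segment all four retinal boundaries of a B-scan
#'
#' Runs the full pipeline: intensity normalization, horizontal alignment by
#' neighbour correlation, initial RPE row estimate, then shortest-path
#' tracing of the RPE centerline (negated intensity), the IS/OS top
#' (dark-to-bright gradient, above the centerline), the RPE outer border
#' (bright-to-dark gradient, below the centerline) and the ILM
#' (dark-to-bright gradient, above the IS/OS). Paths are reported in the
#' original (pre-alignment) row coordinates.
#'
#' Anchor points (in original coordinates) replace interactive correction:
#' the path is forced through them exactly.
#'
#' @param scan An [oct_scan()].
#' @param config An [oct_seg_config()].
#' @param anchors Optional named list of anchor data frames, names among
#'   `ilm`, `isos`, `rpe_center`, `rpe_outer`.
#' @return An object of class `oct_segmentation` with the four
#'   `boundary_path`s, the shift vector, calibration and config.
#' @export
segment_all <- function(scan, config = oct_seg_config(), anchors = list()) {
  stopifnot(inherits(scan, "oct_scan"), inherits(config, "oct_seg_config"))
  norm <- normalize_intensity(scan)
  shifts <- estimate_column_shifts(norm, max_shift = config$max_shift)
  aligned <- apply_shifts(norm, shifts)
  s <- shifts$shifts
  anc <- function(name) shift_anchor_rows(anchors[[name]], s, sign = -1L)

  r0 <- estimate_rpe_row(aligned)
  rpe_center <- segment_rpe_center(aligned, r0,
                                   band_halfwidth = config$band_halfwidth,
                                   max_jump = config$max_jump,
                                   anchors = anc("rpe_center"),
                                   smooth_sigma = config$smooth_sigma,
                                   smooth_sigma_lateral = config$smooth_sigma_lateral)
  isos <- segment_isos(aligned, rpe_center,
                       offset_min_um = config$isos_offset_um[1L],
                       offset_max_um = config$isos_offset_um[2L],
                       max_jump = config$max_jump, anchors = anc("isos"),
                       smooth_sigma = config$smooth_sigma,
                       smooth_sigma_lateral = config$smooth_sigma_lateral,
                       confidence_threshold = config$confidence_threshold)
  rpe_outer <- segment_rpe_outer(aligned, rpe_center,
                                 offset_min_um = config$rpe_outer_offset_um[1L],
                                 offset_max_um = config$rpe_outer_offset_um[2L],
                                 max_jump = config$max_jump,
                                 anchors = anc("rpe_outer"),
                                 smooth_sigma = config$smooth_sigma,
                                 smooth_sigma_lateral = config$smooth_sigma_lateral,
                                 confidence_threshold = config$confidence_threshold)
  ilm <- segment_ilm(aligned, isos, margin_um = config$ilm_margin_um,
                     max_jump = config$max_jump, anchors = anc("ilm"),
                     smooth_sigma = config$smooth_sigma,
                     smooth_sigma_lateral = config$smooth_sigma_lateral,
                     confidence_threshold = config$confidence_threshold)

  # back to original (pre-alignment) coordinates
  for (p in c("ilm", "isos", "rpe_center", "rpe_outer")) {
    obj <- get(p)
    obj$rows <- obj$rows + s
    assign(p, obj)
  }

  bad <- check_ordering(ilm$rows, isos$rows, rpe_center$rows, rpe_outer$rows)
  if (length(bad)) {
    stop(structure(
      class = c("octseg_ordering_error", "error", "condition"),
      list(message = sprintf(
             "boundary ordering violated at %d column(s): %s%s",
             length(bad), paste(utils::head(bad, 10L), collapse = ", "),
             if (length(bad) > 10L) ", ..." else ""),
           call = NULL, columns = bad)))
  }

  structure(list(ilm = ilm, isos = isos, rpe_center = rpe_center,
                 rpe_outer = rpe_outer, shifts = shifts,
                 scan_id = scan$id, calibration = scan$calibration,
                 config = config),
            class = "oct_segmentation")
}

#' @export
print.oct_segmentation <- function(x, ...) {
  cat(sprintf("OCT segmentation of '%s' (%d A-scans)\n", x$scan_id,
              length(x$ilm$rows)))
  for (p in list(x$ilm, x$isos, x$rpe_center, x$rpe_outer)) print(p)
  invisible(x)
}

#' @export
summary.oct_segmentation <- function(object, ...) {
  cal <- object$calibration
  ax <- cal$axial_scale_um
  ret <- (object$rpe_outer$rows - object$ilm$rows) * ax
  rpeos <- (object$rpe_outer$rows - object$isos$rows) * ax
  out <- data.frame(
    layer_pair = c("RETINA", "RPEOS"),
    mean_um = c(mean(ret), mean(rpeos)),
    min_um = c(min(ret), min(rpeos)),
    max_um = c(max(ret), max(rpeos)))
  cat(sprintf("Segmentation '%s': thickness summary (um)\n", object$scan_id))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
as.data.frame.oct_segmentation <- function(x, ...) {
  data.frame(column = seq_along(x$ilm$rows),
             ilm = x$ilm$rows, isos = x$isos$rows,
             rpe_center = x$rpe_center$rows, rpe_outer = x$rpe_outer$rows)
}

#' @export
plot.oct_segmentation <- function(x, scan = NULL, ...) {
  n <- length(x$ilm$rows)
  graphics::plot(NA, xlim = c(1, n),
                 ylim = c(max(x$rpe_outer$rows) + 10, min(x$ilm$rows) - 10),
                 xlab = "A-scan column", ylab = "row (vitreous at top)", ...)
  cols <- c(ILM = "blue", ISOS = "darkgreen", RPE_CENTER = "orange",
            RPE_OUTER = "red")
  for (p in list(x$ilm, x$isos, x$rpe_center, x$rpe_outer)) {
    graphics::lines(seq_len(n), p$rows, col = cols[[p$layer_name]])
  }
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                   cex = 0.7)
  invisible(x)
}

#' Serialize a segmentation to JSON
#'
#' Writes per-layer row arrays (1-based), path costs, the shift vector, the
#' configuration echo and the calibration.
#'
#' @param seg An `oct_segmentation`.
#' @param path Output file.
#' @return `invisible(path)`.
#' @export
write_segmentation_json <- function(seg, path) {
  stopifnot(inherits(seg, "oct_segmentation"))
  lay <- function(p) list(rows = p$rows, cost = p$cost,
                          mean_cost = p$mean_cost,
                          low_confidence = isTRUE(p$low_confidence))
  obj <- list(scan_id = seg$scan_id,
              index_base = 1L,
              layers = list(ilm = lay(seg$ilm), isos = lay(seg$isos),
                            rpe_center = lay(seg$rpe_center),
                            rpe_outer = lay(seg$rpe_outer)),
              shifts = seg$shifts$shifts,
              calibration = unclass(seg$calibration),
              config = unclass(seg$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segmentation written by [write_segmentation_json()]
#'
#' @param path JSON file.
#' @return An `oct_segmentation`.
#' @export
read_segmentation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(l, name) {
    structure(list(rows = as.integer(l$rows), cost = l$cost,
                   mean_cost = l$mean_cost, layer_name = name,
                   low_confidence = isTRUE(l$low_confidence)),
              class = "boundary_path")
  }
  cal <- oct_calibration(obj$calibration$axial_scale_um,
                         obj$calibration$scan_length_mm,
                         obj$calibration$n_ascans)
  cfg <- do.call(oct_seg_config, obj$config)
  structure(list(ilm = mk(obj$layers$ilm, "ILM"),
                 isos = mk(obj$layers$isos, "ISOS"),
                 rpe_center = mk(obj$layers$rpe_center, "RPE_CENTER"),
                 rpe_outer = mk(obj$layers$rpe_outer, "RPE_OUTER"),
                 shifts = oct_shifts(obj$shifts),
                 scan_id = obj$scan_id, calibration = cal, config = cfg),
            class = "oct_segmentation")
}
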