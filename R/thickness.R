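#' Per-column thickness profile
#'
#' Converts a segmentation into micrometre thickness per A-scan column for a
#' layer pair: `RETINA` is ILM to RPE outer border, `RPEOS` is IS/OS top to
#' RPE outer border (the photoreceptor outer segment / RPE complex).
#'
#' @param seg An `oct_segmentation`.
#' @param layer_pair `"RETINA"` or `"RPEOS"`.
#' @param origin_col Column mapped to lateral coordinate 0 mm (default: the
#'   image center).
#' @return An object of class `thickness_profile` with `thickness_um`,
#'   `lateral_mm` and `column`.
#' @export
thickness_profile <- function(seg, layer_pair = c("RETINA", "RPEOS"),
                              origin_col = NULL) {
  stopifnot(inherits(seg, "oct_segmentation"))
  layer_pair <- match.arg(layer_pair)
  inner <- if (layer_pair == "RETINA") seg$ilm$rows else seg$isos$rows
  outer <- seg$rpe_outer$rows
  d <- outer - inner
  if (any(d < 0)) {
    stop("negative row difference: segmentation violates boundary ordering",
         call. = FALSE)
  }
  cal <- seg$calibration
  if (is.null(origin_col)) origin_col <- (cal$n_ascans + 1) / 2
  structure(list(
    column = seq_along(d),
    lateral_mm = (seq_along(d) - origin_col) * lateral_scale_um(cal) / 1000,
    thickness_um = d * cal$axial_scale_um,
    layer_pair = layer_pair,
    origin_col = origin_col,
    calibration = cal,
    scan_id = seg$scan_id),
    class = "thickness_profile")
}

#' @export
as.data.frame.thickness_profile <- function(x, ...) {
  data.frame(scan_id = x$scan_id, layer_pair = x$layer_pair,
             column = x$column, lateral_mm = x$lateral_mm,
             thickness_um = x$thickness_um)
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf("Thickness profile (%s) of '%s': %d columns, %.1f-%.1f um\n",
              x$layer_pair, x$scan_id, length(x$thickness_um),
              min(x$thickness_um), max(x$thickness_um)))
  invisible(x)
}

#' @export
plot.thickness_profile <- function(x, ...) {
  graphics::plot(x$lateral_mm, x$thickness_um, type = "l",
                 xlab = "lateral position (mm)",
                 ylab = sprintf("%s thickness (um)", x$layer_pair), ...)
  invisible(x)
}

moving_average <- function(v, halfwidth) {
  if (halfwidth <= 0) return(v)
  n <- length(v)
  r <- as.integer(halfwidth)
  padded <- c(rep(v[1L], r), v, rep(v[n], r))
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  out <- stats::filter(padded, k, sides = 2L)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Locate the foveal center
#'
#' The foveal center is the minimum of the (moving-average smoothed) retinal
#' thickness profile of a line scan. Ties go to the column nearest the image
#' center, then the smaller index.
#'
#' @param profile A `thickness_profile` of the `RETINA` layer pair.
#' @param smooth_halfwidth Moving-average half-width in columns (default 5;
#'   the raw argmin is speckle-sensitive).
#' @return Integer column index.
#' @export
find_fovea <- function(profile, smooth_halfwidth = 5L) {
  stopifnot(inherits(profile, "thickness_profile"))
  if (profile$layer_pair != "RETINA") {
    stop("the fovea is located on the RETINA thickness profile",
         call. = FALSE)
  }
  v <- profile$thickness_um
  if (length(v) <= 2L * smooth_halfwidth) {
    stop("profile too short for the requested smoothing", call. = FALSE)
  }
  sm <- moving_average(v, smooth_halfwidth)
  cand <- which(sm == min(sm))
  center <- (length(v) + 1) / 2
  cand[order(abs(cand - center), cand)][1L]
}

#' Sample a thickness profile on a lateral offset grid
#'
#' For each requested offset (mm, relative to the fovea column) the nearest
#' column is read; offsets whose target column falls outside the image are
#' masked missing.
#'
#' @param profile A `thickness_profile`.
#' @param fovea_col Column of the foveal center.
#' @param offsets_mm Lateral offsets in mm (default: -3 to +3 by 0.5, the
#'   13-point 6-mm grid).
#' @return Data frame with `offset_mm`, `column`, `thickness_um`, `missing`.
#' @export
sample_points <- function(profile, fovea_col,
                          offsets_mm = seq(-3, 3, by = 0.5)) {
  stopifnot(inherits(profile, "thickness_profile"))
  lat <- lateral_scale_um(profile$calibration)
  n <- length(profile$thickness_um)
  cols <- fovea_col + round(offsets_mm * 1000 / lat)
  missing <- cols < 1L | cols > n
  thick <- rep(NA_real_, length(cols))
  thick[!missing] <- profile$thickness_um[cols[!missing]]
  data.frame(offset_mm = offsets_mm, column = ifelse(missing, NA, cols),
             thickness_um = thick, missing = missing)
}

#' Summarize sampled thickness points
#'
#' Computes the central point thickness (offset 0), the central 1-mm line
#' (unweighted mean of the -0.5, 0 and +0.5 mm points) and the mean over all
#' unmasked grid points.
#'
#' @param samples Data frame from [sample_points()].
#' @return An object of class `thickness_summary` with `cpt_um`,
#'   `line1mm_um`, `allpoints_um`, the per-point table and the missing count.
#' @export
summarize_thickness <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("offset_mm", "thickness_um", "missing") %in% names(samples)))
  central <- c(-0.5, 0, 0.5)
  idx <- match(central, samples$offset_mm)
  if (any(is.na(idx)) || any(samples$missing[idx])) {
    stop("the central -0.5, 0 and +0.5 mm points must be present",
         call. = FALSE)
  }
  cpt <- samples$thickness_um[match(0, samples$offset_mm)]
  structure(list(
    cpt_um = cpt,
    line1mm_um = mean(samples$thickness_um[idx]),
    allpoints_um = mean(samples$thickness_um[!samples$missing]),
    points = samples,
    n_missing = sum(samples$missing)),
    class = "thickness_summary")
}

#' @export
print.thickness_summary <- function(x, ...) {
  cat(sprintf("Thickness summary: CPT %.2f um, 1-mm line %.2f um, all points %.2f um (%d missing)\n",
              x$cpt_um, x$line1mm_um, x$allpoints_um, x$n_missing))
  invisible(x)
}

#' Full thickness quantification of one segmented scan
#'
#' Builds the retinal and RPE/outer-segment thickness profiles, locates the
#' fovea on the retinal profile, samples both profiles on the same offset
#' grid centred at the fovea, and summarizes them.
#'
#' @param seg An `oct_segmentation`.
#' @param offsets_mm Lateral offset grid (mm).
#' @param smooth_halfwidth Fovea-finder smoothing half-width (columns).
#' @return List with `fovea_col` and per-layer-pair `thickness_summary`
#'   objects (`retina`, `rpeos`).
#' @export
quantify_thickness <- function(seg, offsets_mm = seq(-3, 3, by = 0.5),
                               smooth_halfwidth = 5L) {
  ret_prof <- thickness_profile(seg, "RETINA")
  fovea <- find_fovea(ret_prof, smooth_halfwidth)
  rpeos_prof <- thickness_profile(seg, "RPEOS")
  list(fovea_col = fovea,
       retina = summarize_thickness(sample_points(ret_prof, fovea, offsets_mm)),
       rpeos = summarize_thickness(sample_points(rpeos_prof, fovea, offsets_mm)))
}

#' Write per-scan sampled thickness to CSV
#'
#' One row per offset per layer pair: `scan_id, layer_pair, offset_mm,
#' thickness_um, missing`.
#'
#' @param quant Result of [quantify_thickness()].
#' @param scan_id Scan identifier for the `scan_id` column.
#' @param path Output CSV path.
#' @return `invisible(path)`.
#' @export
write_thickness_csv <- function(quant, scan_id, path) {
  rows <- do.call(rbind, lapply(c("retina", "rpeos"), function(lp) {
    pts <- quant[[lp]]$points
    data.frame(scan_id = scan_id,
               layer_pair = if (lp == "retina") "RETINA" else "RPEOS",
               offset_mm = pts$offset_mm, thickness_um = pts$thickness_um,
               missing = pts$missing)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
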