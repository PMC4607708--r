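#' Paired comparison of two devices (or visits)
#'
#' For paired micrometre measurements `a` (device A) and `b` (device B) this
#' computes the paired difference `d = b - a`, its mean and sample SD, the
#' paired t statistic `mean(d) / (sd(d) / sqrt(n))` with a two-sided p-value
#' on n-1 degrees of freedom, Pearson's correlation between the devices, the
#' percent difference `100 * mean(d) / mean(c(a, b) means)` and Bland-Altman
#' limits of agreement at `mean(d) +/- 2 sd(d)`.
#'
#' If the differences have zero variance, the t statistic is undefined and
#' is reported as `NA` with `p = 0` when the mean difference is nonzero and
#' `p = 1` when it is zero.
#'
#' @param values_a,values_b Paired measurements, equal length >= 2.
#' @param eye_id Optional pair identifiers.
#' @param label_a,label_b Device labels carried into tables.
#' @return An object of class `agreement_result`.
#' @export
paired_compare <- function(values_a, values_b, eye_id = NULL,
                           label_a = "A", label_b = "B") {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- b - a
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  if (sd_diff == 0) {
    t_stat <- NA_real_
    p_value <- if (mean_diff != 0) 0 else 1
  } else {
    t_stat <- mean_diff / (sd_diff / sqrt(n))
    p_value <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  }
  r <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_
  structure(list(
    n = n, label_a = label_a, label_b = label_b,
    mean_a = mean(a), mean_b = mean(b),
    sd_a = stats::sd(a), sd_b = stats::sd(b),
    mean_diff = mean_diff, sd_diff = sd_diff,
    pct_diff = 100 * mean_diff / mean(c(mean(a), mean(b))),
    t_stat = t_stat, p_value = p_value, pearson_r = r,
    ba_lower = mean_diff - 2 * sd_diff,
    ba_upper = mean_diff + 2 * sd_diff,
    pairs = data.frame(eye_id = if (is.null(eye_id)) seq_len(n)
                       else eye_id[keep],
                       a = a, b = b)),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Paired agreement (%s vs %s), n = %d\n", x$label_b, x$label_a,
              x$n))
  cat(sprintf("  %s: %.2f (SD %.2f)   %s: %.2f (SD %.2f)\n",
              x$label_a, x$mean_a, x$sd_a, x$label_b, x$mean_b, x$sd_b))
  cat(sprintf("  difference (%s - %s): %.3f (SD %.3f, %.2f%%)\n",
              x$label_b, x$label_a, x$mean_diff, x$sd_diff, x$pct_diff))
  cat(sprintf("  paired t = %.3f, p = %.4g, Pearson r = %.3f\n",
              x$t_stat, x$p_value, x$pearson_r))
  cat(sprintf("  Bland-Altman limits: [%.3f, %.3f]\n", x$ba_lower, x$ba_upper))
  invisible(x)
}

#' Bland-Altman plot data / plot
#'
#' Per-pair mean and difference, with the mean difference and the
#' `mean +/- 2 SD` limits.
#'
#' @param x An `agreement_result`.
#' @return Data frame with `mean` and `diff` (invisible if plotted).
#' @export
bland_altman_data <- function(x) {
  stopifnot(inherits(x, "agreement_result"))
  data.frame(eye_id = x$pairs$eye_id,
             mean = (x$pairs$a + x$pairs$b) / 2,
             diff = x$pairs$b - x$pairs$a)
}

#' @export
plot.agreement_result <- function(x, ...) {
  ba <- bland_altman_data(x)
  graphics::plot(ba$mean, ba$diff,
                 xlab = sprintf("mean of %s and %s (um)", x$label_a, x$label_b),
                 ylab = sprintf("%s - %s (um)", x$label_b, x$label_a), ...)
  graphics::abline(h = x$mean_diff, lty = 2)
  graphics::abline(h = c(x$ba_lower, x$ba_upper), lty = 1)
  invisible(x)
}

#' Read a tidy thickness table
#'
#' Expects columns `eye_id, device, visit, layer_pair, offset_mm,
#' thickness_um` (and optionally `missing`).
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_thickness_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("eye_id", "device", "layer_pair", "offset_mm", "thickness_um")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("thickness table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"visit" %in% names(df)) df$visit <- 1L
  df
}

#' Per-offset and pooled device comparison
#'
#' Compares two devices on a common lateral offset grid: one paired
#' comparison per offset (pairs with a missing member dropped listwise per
#' offset) and a pooled comparison of the per-eye means over the offsets
#' where both devices have data (so within-eye correlation across grid
#' points does not inflate the pooled test).
#'
#' @param table Tidy data frame (see [read_thickness_table()]).
#' @param device_a,device_b Values of the `device` column to compare
#'   (differences are `device_b - device_a`).
#' @param layer_pair Which layer pair to analyze.
#' @return List with `per_offset` (named list of `agreement_result`) and
#'   `pooled` (one `agreement_result` on per-eye means).
#' @export
per_point_compare <- function(table, device_a, device_b,
                              layer_pair = "RETINA") {
  df <- table[table$layer_pair == layer_pair, ]
  if ("missing" %in% names(df)) df <- df[!df$missing, ]
  df <- df[!is.na(df$thickness_um), ]
  da <- df[df$device == device_a, ]
  db <- df[df$device == device_b, ]
  m <- merge(da[, c("eye_id", "offset_mm", "thickness_um")],
             db[, c("eye_id", "offset_mm", "thickness_um")],
             by = c("eye_id", "offset_mm"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    stop("no common (eye, offset) pairs between the two devices",
         call. = FALSE)
  }
  counts <- table(m$offset_mm)
  offsets <- sort(as.numeric(names(counts)[counts >= 2L]))
  if (length(offsets) == 0L) {
    stop("no offset has at least 2 complete pairs", call. = FALSE)
  }
  per_offset <- lapply(offsets, function(o) {
    sub <- m[m$offset_mm == o, ]
    paired_compare(sub$thickness_um_a, sub$thickness_um_b, sub$eye_id,
                   device_a, device_b)
  })
  names(per_offset) <- trimws(format(offsets))
  eye_means <- do.call(rbind, lapply(split(m, m$eye_id), function(s) {
    data.frame(eye_id = s$eye_id[1L], a = mean(s$thickness_um_a),
               b = mean(s$thickness_um_b))
  }))
  pooled <- paired_compare(eye_means$a, eye_means$b, eye_means$eye_id,
                           device_a, device_b)
  list(per_offset = per_offset, pooled = pooled)
}

#' Intra-device repeatability
#'
#' Test-retest summary for paired visits: the mean absolute difference and
#' the Bland-Altman coefficient of repeatability, defined here as
#' `2 * SD(visit2 - visit1)` expressed as a percent of the grand mean of all
#' measurements.
#'
#' @param visit1,visit2 Per-eye summaries (um), paired.
#' @return An object of class `repeatability_result` with `mean_abs_diff`
#'   and `cor_pct`.
#' @export
repeatability <- function(visit1, visit2) {
  v1 <- as.numeric(visit1); v2 <- as.numeric(visit2)
  if (length(v1) != length(v2)) {
    stop("visits must be paired", call. = FALSE)
  }
  keep <- !(is.na(v1) | is.na(v2))
  v1 <- v1[keep]; v2 <- v2[keep]
  if (length(v1) < 2L) stop("need at least 2 paired visits", call. = FALSE)
  d <- v2 - v1
  structure(list(n = length(v1),
                 mean_abs_diff = mean(abs(d)),
                 sd_abs_diff = stats::sd(abs(d)),
                 cor_pct = 100 * 2 * stats::sd(d) / mean(c(v1, v2))),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability (n = %d): mean |diff| %.2f um (SD %.2f), coefficient of repeatability %.2f%%\n",
              x$n, x$mean_abs_diff, x$sd_abs_diff, x$cor_pct))
  invisible(x)
}

#' Device-conversion regression
#'
#' Ordinary least squares fit `y = intercept + slope * x` converting one
#' device's thickness scale to another's.
#'
#' @param x,y Thickness values (um) from the source and target device.
#' @param from,to Device labels.
#' @return An object of class `conversion_fit` with `intercept` and `slope`.
#' @export
fit_conversion <- function(x, y, from = "A", to = "B") {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in x: conversion undefined", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  structure(list(intercept = intercept, slope = slope, n = length(x),
                 from = from, to = to),
            class = "conversion_fit")
}

#' @export
coef.conversion_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.conversion_fit <- function(object, newdata, ...) {
  object$intercept + object$slope * as.numeric(newdata)
}

#' @export
print.conversion_fit <- function(x, ...) {
  cat(sprintf("Conversion %s -> %s (n = %d): %.4f + %s thickness x %.4f\n",
              x$from, x$to, x$n, x$intercept, x$from, x$slope))
  invisible(x)
}

#' Summary table of paired comparisons
#'
#' One row per grid level (e.g. foveal center, central 1-mm line, all
#' points) with per-device mean and SD, the difference (B - A), the percent
#' difference relative to the mean of the two device means, and the p-value.
#'
#' @param results Named list of `agreement_result` objects; names become the
#'   `level` column.
#' @return Data frame of class `agreement_table`.
#' @export
summary_table <- function(results) {
  if (length(results) == 0L) stop("no results supplied", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "agreement_result")))
  out <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(level = names(results)[i] %||% as.character(i),
               mean_a = r$mean_a, sd_a = r$sd_a,
               mean_b = r$mean_b, sd_b = r$sd_b,
               difference = r$mean_diff, pct_difference = r$pct_diff,
               p_value = r$p_value)
  }))
  class(out) <- c("agreement_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || a == "") b else a

#' Difference-table arithmetic from per-device summary statistics
#'
#' The reporting-layer arithmetic on already-summarized cohort values: given
#' per-level per-device means and SDs it computes the difference
#' `mean_b - mean_a` and the percent difference
#' `100 * (mean_b - mean_a) / mean(mean_a, mean_b)`.
#'
#' @param level Character vector of grid levels.
#' @param mean_a,sd_a,mean_b,sd_b Per-level summary statistics (um).
#' @return Data frame with the difference and percent-difference columns.
#' @export
device_difference_table <- function(level, mean_a, sd_a, mean_b, sd_b) {
  diff <- mean_b - mean_a
  data.frame(level = level, mean_a = mean_a, sd_a = sd_a,
             mean_b = mean_b, sd_b = sd_b,
             difference = diff,
             pct_difference = 100 * diff / ((mean_a + mean_b) / 2))
}
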