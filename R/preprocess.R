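#' Per-column axial shifts
#'
#' One integer axial offset per A-scan column, as estimated by
#' [estimate_column_shifts()]. Positive values mean the column content is
#' displaced downwards (towards the choroid) relative to the scan as a
#' whole; [apply_shifts()] undoes the displacement.
#'
#' @param shifts Integer vector, one offset per column.
#' @param reference_column Column whose shift was 0 before median-centering.
#' @param max_shift Bound used during estimation.
#' @return An object of class `oct_shifts`.
#' @export
oct_shifts <- function(shifts, reference_column = 1L, max_shift = max(abs(shifts), 1L)) {
  shifts <- as.integer(round(shifts))
  if (any(abs(shifts) > max_shift)) {
    stop("|shift| exceeds max_shift", call. = FALSE)
  }
  structure(list(shifts = shifts,
                 reference_column = as.integer(reference_column),
                 max_shift = as.integer(max_shift)),
            class = "oct_shifts")
}

#' @export
print.oct_shifts <- function(x, ...) {
  cat(sprintf("Column shifts: %d columns, range [%d, %d] px (max_shift %d)\n",
              length(x$shifts), min(x$shifts), max(x$shifts), x$max_shift))
  invisible(x)
}

as_shift_vector <- function(shifts, n_cols) {
  s <- if (inherits(shifts, "oct_shifts")) shifts$shifts else
    as.integer(round(shifts))
  if (length(s) != n_cols) {
    stop(sprintf("shift vector has length %d but image has %d columns",
                 length(s), n_cols), call. = FALSE)
  }
  s
}

# axial (per-column) Gaussian smoothing with edge replication
smooth_axial <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(img)
  padded <- rbind(img[rep(1L, r), , drop = FALSE], img,
                  img[rep(n, r), , drop = FALSE])
  matrix(stats::filter(padded, k, sides = 2L)[(r + 1L):(r + n), ],
         n, ncol(img))
}

shift_columns <- function(img, shifts) {
  R <- nrow(img)
  out <- img
  for (c in which(shifts != 0L)) {
    src <- pmin(pmax(seq_len(R) + shifts[c], 1L), R)
    out[, c] <- img[src, c]
  }
  out
}

# per-column local reference: boxcar mean across neighbouring columns
local_reference <- function(img, window) {
  C <- ncol(img)
  if (C < 3L || window < 3L) return(img)
  w <- min(window, C)
  if (w %% 2L == 0L) w <- w - 1L
  r <- (w - 1L) %/% 2L
  k <- rep(1 / w, w)
  padded <- cbind(img[, rep(1L, r), drop = FALSE], img,
                  img[, rep(C, r), drop = FALSE])
  out <- t(stats::filter(t(padded), k, sides = 2L))
  matrix(out[, (r + 1L):(r + C)], nrow(img), C)
}

# NCC of every column of A against the correspondingly-indexed column of B
# shifted by each candidate lag; rows of B are w + lag. Returns C x n_lags.
lagged_ncc <- function(A, B, w, lags) {
  Aw <- A[w, , drop = FALSE]
  Aw <- sweep(Aw, 2L, colMeans(Aw))
  ssA <- colSums(Aw * Aw)
  out <- matrix(-Inf, ncol(A), length(lags))
  for (i in seq_along(lags)) {
    Bw <- B[w + lags[i], , drop = FALSE]
    Bw <- sweep(Bw, 2L, colMeans(Bw))
    v <- colSums(Aw * Bw) / sqrt(ssA * colSums(Bw * Bw))
    v[!is.finite(v)] <- 0
    out[, i] <- v
  }
  out
}

# Viterbi decoding of the shift sequence: states are absolute shifts,
# emission[c, ] scores registration of column c to the reference, and
# trans[c-1, ] scores the increment between columns c-1 and c. Ties prefer
# the state earlier in `state_order`.
viterbi_shifts <- function(emission, trans, states, state_order,
                           pair_weight = rep(1, nrow(emission) - 1L)) {
  C <- nrow(emission); S <- length(states)
  # INC[si, sj]: index into the lag axis of `trans` for the increment
  # states[si] - states[sj]; NA where the increment exceeds the lag range
  incm <- outer(states, states, "-") - states[1L] + 1L
  incm[incm < 1L | incm > S] <- NA_integer_
  V <- emission[1L, ]
  back <- matrix(0L, C, S)
  for (c in 2L:C) {
    tr_row <- trans[c - 1L, ]
    tv <- matrix(tr_row[incm], S, S)
    # increments beyond the scored lag range are possible but unobserved:
    # score them like the worst observed lag rather than forbidding them
    tv[is.na(tv)] <- min(tr_row)
    tot <- matrix(V, S, S, byrow = TRUE) + pair_weight[c - 1L] * tv
    j <- state_order[max.col(tot[, state_order, drop = FALSE],
                             ties.method = "first")]
    V <- tot[cbind(seq_len(S), j)] + emission[c, ]
    back[c, ] <- j
  }
  s <- state_order[which.max(V[state_order])]
  path <- integer(C)
  path[C] <- s
  for (c in C:2L) path[c - 1L] <- back[c, path[c]]
  states[path]
}

#' Estimate per-column axial shifts by neighbour correlation
#'
#' Estimates one integer axial displacement per A-scan by maximizing, over
#' the whole scan jointly, the sum of two normalized cross-correlation
#' scores: (i) the correlation between each pair of neighbouring A-scans at
#' their relative lag — neighbouring columns share anatomy, so this term
#' pins the column-to-column displacement increments without confusing them
#' with lateral anatomy — and (ii) the correlation of each column, at its
#' absolute shift, against a scan-level reference profile (the lateral
#' boxcar mean of the provisionally flattened scan), which anchors the
#' absolute displacement so that estimation noise in the increments cannot
#' accumulate into a drift along the scan. The joint maximization over all
#' columns is solved exactly by dynamic programming over the admissible
#' shift states, and the estimate-flatten-re-estimate cycle is iterated so
#' the reference sharpens.
#'
#' Correlation operates on axially smoothed log-intensities: OCT speckle is
#' multiplicative, so on the log scale it is additive with near-constant
#' variance, which is what normalized cross-correlation assumes. The log
#' transform and the smoothing commute with integer translation, so
#' noiseless recovery is exact.
#'
#' The final shifts are median-centred (so flattening does not drift the
#' image) and clamped to `[-max_shift, max_shift]`. Ties prefer the smaller
#' absolute shift, then the negative one.
#'
#' @param scan An [oct_scan()] (or plain numeric matrix).
#' @param max_shift Largest admissible displacement in pixels (>= 1),
#'   default 20.
#' @param presmooth_sigma Axial Gaussian smoothing (px) of the log
#'   intensities before correlation (0 disables).
#' @param n_iter Number of estimate-flatten-re-estimate passes.
#' @param ref_window Width (columns) of the boxcar reference.
#' @param pair_weight Weight of the neighbour-pair term relative to the
#'   reference term.
#' @return An [oct_shifts()] object.
#' @export
estimate_column_shifts <- function(scan, max_shift = 20L,
                                   presmooth_sigma = 1, n_iter = 3L,
                                   ref_window = 31L, pair_weight = 1) {
  img <- if (inherits(scan, "oct_scan")) scan$image else scan
  max_shift <- as.integer(max_shift)
  if (max_shift < 1L) stop("`max_shift` must be >= 1", call. = FALSE)
  C <- ncol(img); R <- nrow(img)
  if (C < 2L) stop("image must have at least 2 columns", call. = FALSE)
  if (R < 2L * max_shift + 4L) {
    stop("image too shallow for the requested max_shift", call. = FALSE)
  }
  mx <- max(img)
  if (mx <= 0) {
    return(oct_shifts(integer(C), max_shift = max_shift))
  }
  # pairwise term on log intensities (multiplicative speckle is additive and
  # homoskedastic there); reference term on amplitude (square-root)
  # intensities, which stabilizes the speckle variance while keeping the
  # bright bands dominant
  sm_log <- smooth_axial(log(img / mx + 0.01), presmooth_sigma)
  sm_amp <- smooth_axial(sqrt(img / mx), presmooth_sigma)

  w <- (max_shift + 1L):(R - max_shift)
  states <- -max_shift:max_shift
  state_order <- order(abs(states), states)  # ties: smaller |s|, then negative
  # neighbour-pair scores: trans[c-1, ] over relative lags (fixed per scan)
  trans <- lagged_ncc(sm_log[, -C, drop = FALSE], sm_log[, -1L, drop = FALSE],
                      w, states)
  # confidence weight per pair: a peak correlation near 1 means the two
  # profiles are near-duplicates up to translation and the measured lag is
  # essentially certain, so the chain term hardens; a weak peak softens it
  peak <- pmin(apply(trans, 1L, max), 1 - 1e-9)
  peak <- pmax(peak, 0)
  pair_w <- pair_weight * peak^2 / (1 - peak^2)

  # initial estimate: when the neighbour correlations are near-perfect the
  # scan is effectively noiseless and the cumulative pairwise lags are exact,
  # so they seed the iteration (and the first reference is already sharp);
  # with weak pair correlations the cumulative sum is a random walk and a
  # zero start (reference from the raw scan) is the better seed
  shifts <- integer(C)
  if (stats::median(peak) >= 0.98) {
    inc <- states[apply(trans, 1L, function(s) {
      m <- max(s)
      state_order[which(s[state_order] >= m - 1e-10)[1L]]
    })]
    shifts <- c(0L, cumsum(as.integer(inc)))
    shifts <- shifts - as.integer(round(stats::median(shifts)))
    shifts <- pmin(pmax(shifts, -max_shift), max_shift)
  }
  for (it in seq_len(n_iter)) {
    al <- shift_columns(sm_amp, shifts)
    ref <- local_reference(al, ref_window)
    emission <- lagged_ncc(ref, sm_amp, w, states)
    new_shifts <- viterbi_shifts(emission, trans, states, state_order,
                                 pair_weight = pair_w)
    if (identical(new_shifts, shifts)) break
    shifts <- new_shifts
  }
  shifts <- shifts - as.integer(round(stats::median(shifts)))
  shifts <- pmin(pmax(shifts, -max_shift), max_shift)
  oct_shifts(shifts, reference_column = which.min(abs(shifts)),
             max_shift = max_shift)
}

#' Undo per-column axial displacement
#'
#' Each column is translated axially by minus its shift, so the estimated
#' displacement is removed; vacated pixels are set to `fill` (default: the
#' image minimum). Output has the same shape as the input.
#'
#' @param scan An [oct_scan()] or numeric matrix.
#' @param shifts An [oct_shifts()] or integer vector, one entry per column.
#' @param fill Intensity for vacated pixels.
#' @return Same type as `scan`.
#' @export
apply_shifts <- function(scan, shifts, fill = NULL) {
  is_scan <- inherits(scan, "oct_scan")
  img <- if (is_scan) scan$image else scan
  s <- as_shift_vector(shifts, ncol(img))
  if (is.null(fill)) fill <- min(img)
  R <- nrow(img)
  out <- matrix(fill, R, ncol(img))
  for (c in which(abs(s) <= R - 1L)) {
    k <- s[c]
    src <- (max(1L, 1L + k)):(min(R, R + k))
    out[src - k, c] <- img[src, c]
  }
  if (is_scan) { scan$image <- out; scan } else out
}
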