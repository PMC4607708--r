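#' Cost image for shortest-path boundary tracing
#'
#' A 2-D array of finite, non-negative path costs with a note on which
#' construction produced it. Out-of-band pixels are excluded at path time
#' (they carry an infinite cost no admissible path can prefer).
#'
#' @param values Numeric matrix of finite costs.
#' @param description How the costs were built.
#' @return An object of class `oct_cost`.
#' @export
oct_cost <- function(values, description = "custom") {
  if (!is.matrix(values) || any(!is.finite(values))) {
    stop("cost values must be a finite numeric matrix", call. = FALSE)
  }
  structure(list(values = values, description = description),
            class = "oct_cost")
}

cost_values <- function(cost) {
  if (inherits(cost, "oct_cost")) cost$values
  else if (is.matrix(cost)) cost
  else stop("expected an oct_cost or a matrix", call. = FALSE)
}

#' Negated-intensity cost image
#'
#' Hyper-reflective (bright) structures become low-cost, so a minimal path
#' follows the brightest band. Input must be normalized to `[0, 1]`.
#'
#' @param values Numeric matrix in `[0, 1]` (or an [oct_scan()]).
#' @return An [oct_cost()] with values `1 - values`.
#' @export
negate_image <- function(values) {
  v <- if (inherits(values, "oct_scan")) values$image else values
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9) {
    stop("intensities must be normalized to [0, 1] before negation",
         call. = FALSE)
  }
  oct_cost(1 - pmin(pmax(v, 0), 1), "negated intensity")
}

#' Polarity-matched vertical-gradient cost image
#'
#' Forward axial difference `g[r, c] = values[r+1, c] - values[r, c]` (the
#' last row gets zero response). Polarity `"dark_to_bright"` keeps positive
#' responses, `"bright_to_dark"` keeps negated ones; the rest are clipped
#' to zero. The retained response is rescaled to `[0, 1]` and negated, so
#' strong polarity-matched edges have low cost.
#'
#' @param values Numeric matrix with at least 2 rows (or an [oct_scan()]).
#' @param polarity `"dark_to_bright"` or `"bright_to_dark"`.
#' @return An [oct_cost()].
#' @export
vertical_gradient <- function(values,
                              polarity = c("dark_to_bright", "bright_to_dark")) {
  polarity <- match.arg(polarity)
  v <- if (inherits(values, "oct_scan")) values$image else values
  if (nrow(v) < 2L) {
    stop("vertical gradient needs at least 2 rows", call. = FALSE)
  }
  g <- rbind(v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE], 0)
  if (polarity == "bright_to_dark") g <- -g
  g[g < 0] <- 0
  mx <- max(g)
  if (mx > 0) g <- g / mx
  oct_cost(1 - g, paste0("negated vertical gradient (", polarity, ")"))
}

#' Per-column admissible row band
#'
#' @param lower,upper Integer vectors (or scalars, recycled) of inclusive
#'   per-column row limits; clipped rows must satisfy `lower <= upper`.
#' @param n_rows,n_cols Image dimensions the band refers to.
#' @return An object of class `oct_band` with `$lower` and `$upper`.
#' @export
search_band <- function(lower, upper, n_rows, n_cols) {
  lower <- as.integer(round(rep_len(lower, n_cols)))
  upper <- as.integer(round(rep_len(upper, n_cols)))
  if (any(upper < 1L) || any(lower > n_rows)) {
    stop("search band lies entirely outside the image for some column",
         call. = FALSE)
  }
  lower <- pmax(lower, 1L)
  upper <- pmin(upper, n_rows)
  if (any(lower > upper)) {
    stop("empty search band after clipping (lower > upper)", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, n_rows = as.integer(n_rows)),
            class = "oct_band")
}

validate_anchors <- function(anchors, n_cols, band) {
  if (is.null(anchors) || NROW(anchors) == 0L) return(NULL)
  a <- as.data.frame(anchors)
  if (!all(c("column", "row") %in% names(a))) {
    stop("anchors must have `column` and `row`", call. = FALSE)
  }
  a <- a[order(a$column), c("column", "row")]
  a$column <- as.integer(round(a$column))
  a$row <- as.integer(round(a$row))
  if (anyDuplicated(a$column)) {
    stop("at most one anchor per column", call. = FALSE)
  }
  if (any(a$column < 1L | a$column > n_cols)) {
    stop("anchor column outside image", call. = FALSE)
  }
  bad <- a$row < band$lower[a$column] | a$row > band$upper[a$column]
  if (any(bad)) {
    stop(sprintf("anchor at column %s lies outside the search band",
                 paste(a$column[bad], collapse = ", ")), call. = FALSE)
  }
  a
}

# running min of v over a window of +/- j entries, Inf-padded
window_min <- function(v, j) {
  n <- length(v)
  out <- v
  for (k in seq_len(min(j, n - 1L))) {
    out <- pmin(out,
                c(v[-seq_len(k)], rep(Inf, k)),
                c(rep(Inf, k), v[seq_len(n - k)]))
  }
  out
}

# DP over columns cs..ce of M (Inf outside band), optional fixed endpoints.
# Returns integer rows for those columns (ties -> smallest row).
dp_segment <- function(M, cs, ce, max_jump, start_row = NULL, end_row = NULL) {
  R <- nrow(M)
  nc <- ce - cs + 1L
  if (nc == 1L) {
    r <- if (!is.null(start_row)) start_row
         else if (!is.null(end_row)) end_row
         else which.min(M[, cs])
    if (!is.finite(M[r, cs])) stop("no feasible path", call. = FALSE)
    return(r)
  }
  D <- matrix(Inf, R, nc)
  if (is.null(start_row)) {
    D[, 1L] <- M[, cs]
  } else {
    D[start_row, 1L] <- M[start_row, cs]
  }
  for (i in 2L:nc) {
    D[, i] <- M[, cs + i - 1L] + window_min(D[, i - 1L], max_jump)
  }
  r <- if (is.null(end_row)) which.min(D[, nc]) else end_row
  if (!is.finite(D[r, nc])) {
    stop("no feasible path through the search band/anchors", call. = FALSE)
  }
  rows <- integer(nc)
  rows[nc] <- r
  for (i in (nc - 1L):1L) {
    win <- max(1L, r - max_jump):min(R, r + max_jump)
    r <- win[which.min(D[win, i])]
    rows[i] <- r
  }
  rows
}

#' Minimum-cost left-to-right boundary path
#'
#' Finds the path (one row per column) minimizing the sum of cost values,
#' subject to a per-column step constraint `|row[c+1] - row[c]| <= max_jump`,
#' a per-column admissible row band, and passage through all anchor points.
#' Each interval between consecutive anchors is solved as an independent
#' constrained problem with fixed endpoint rows. Ties are broken by
#' preferring the smaller row at every argmin, so output is deterministic.
#'
#' @param cost An [oct_cost()] or numeric matrix.
#' @param band An [oct_band()]; default: the full image.
#' @param max_jump Largest admissible per-column row step (>= 1), default 2.
#' @param anchors Optional data frame with `column` and `row` the path must
#'   pass through exactly.
#' @param layer_name Label stored on the result.
#' @return An object of class `boundary_path` with `rows` (integer, one per
#'   column), `cost` (the achieved sum) and `mean_cost`.
#' @export
shortest_path <- function(cost, band = NULL, max_jump = 2L, anchors = NULL,
                          layer_name = "boundary") {
  M <- cost_values(cost)
  R <- nrow(M); C <- ncol(M)
  max_jump <- as.integer(max_jump)
  if (max_jump < 1L) stop("`max_jump` must be >= 1", call. = FALSE)
  if (is.null(band)) band <- search_band(1L, R, R, C)
  if (length(band$lower) != C) {
    stop("band width does not match the cost image", call. = FALSE)
  }
  a <- validate_anchors(anchors, C, band)

  Mb <- M
  row_idx <- seq_len(R)
  for (c in seq_len(C)) {
    out <- row_idx < band$lower[c] | row_idx > band$upper[c]
    if (any(out)) Mb[out, c] <- Inf
  }

  if (is.null(a)) {
    rows <- dp_segment(Mb, 1L, C, max_jump)
  } else {
    # feasibility of consecutive anchor pairs under the step constraint
    if (nrow(a) > 1L) {
      dr <- abs(diff(a$row)); dc <- diff(a$column)
      if (any(dr > max_jump * dc)) {
        stop("infeasible anchor pair: row gap exceeds max_jump * column gap",
             call. = FALSE)
      }
    }
    rows <- integer(C)
    ac <- a$column; ar <- a$row
    if (ac[1L] > 1L) {
      rows[1:ac[1L]] <- dp_segment(Mb, 1L, ac[1L], max_jump,
                                   end_row = ar[1L])
    } else {
      rows[1L] <- ar[1L]
    }
    if (nrow(a) > 1L) {
      for (i in seq_len(nrow(a) - 1L)) {
        seg <- dp_segment(Mb, ac[i], ac[i + 1L], max_jump,
                          start_row = ar[i], end_row = ar[i + 1L])
        rows[ac[i]:ac[i + 1L]] <- seg
      }
    }
    last <- ac[nrow(a)]
    if (last < C) {
      rows[last:C] <- dp_segment(Mb, last, C, max_jump,
                                 start_row = ar[nrow(a)])
    }
  }

  total <- sum(M[cbind(rows, seq_len(C))])
  structure(list(rows = rows, cost = total, mean_cost = total / C,
                 layer_name = layer_name, max_jump = max_jump,
                 low_confidence = FALSE),
            class = "boundary_path")
}

#' @export
print.boundary_path <- function(x, ...) {
  cat(sprintf("Boundary path '%s': %d columns, rows [%d, %d], cost %.4g (mean %.4g)%s\n",
              x$layer_name, length(x$rows), min(x$rows), max(x$rows),
              x$cost, x$mean_cost,
              if (isTRUE(x$low_confidence)) " [LOW CONFIDENCE]" else ""))
  invisible(x)
}
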