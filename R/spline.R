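#' Ciliary spline path
#'
#' The cilium is described by a smooth path through user-supplied control
#' points (image coordinates). The path is densified to a fine polyline with
#' arc-length parameterization; all modules use arc length along this path as
#' the axial coordinate and the signed perpendicular offset as the lateral
#' coordinate.
#'
#' @param points numeric matrix or data.frame with two columns (column, row
#'   position of each control point, in pixel units).
#' @param step densification step along the path, in the same units.
#' @return an object of class `ift_spline` with fields `x`, `y` (densified
#'   path), `s` (cumulative arc length), `tx`, `ty` (unit tangent).
#' @export
ciliary_spline <- function(points, step = 0.25) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2, nrow(p) >= 2)
  # chord-length parameter for the interpolating spline
  d <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  u <- c(0, cumsum(d))
  n_out <- max(2L, ceiling(u[length(u)] / step) * 4L)
  uu <- seq(0, u[length(u)], length.out = n_out)
  if (nrow(p) == 2) {
    xx <- stats::approx(u, p[, 1], uu)$y
    yy <- stats::approx(u, p[, 2], uu)$y
  } else {
    xx <- stats::spline(u, p[, 1], xout = uu, method = "natural")$y
    yy <- stats::spline(u, p[, 2], xout = uu, method = "natural")$y
  }
  s <- c(0, cumsum(sqrt(diff(xx)^2 + diff(yy)^2)))
  tx <- c(diff(xx), NA); ty <- c(diff(yy), NA)
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl
  tx[n_out] <- tx[n_out - 1L]; ty[n_out] <- ty[n_out - 1L]
  structure(list(x = xx, y = yy, s = s, tx = tx, ty = ty,
                 length = s[n_out]),
            class = "ift_spline")
}

#' @export
print.ift_spline <- function(x, ...) {
  cat(sprintf("ciliary spline: arc length %.1f, %d samples\n",
              x$length, length(x$s)))
  invisible(x)
}

# point, tangent and unit normal at arc length s (vectorized)
spline_at <- function(sp, s) {
  s <- pmin(pmax(s, 0), sp$length)
  x <- stats::approx(sp$s, sp$x, s)$y
  y <- stats::approx(sp$s, sp$y, s)$y
  tx <- stats::approx(sp$s, sp$tx, s)$y
  ty <- stats::approx(sp$s, sp$ty, s)$y
  tl <- sqrt(tx^2 + ty^2)
  list(x = x, y = y, tx = tx / tl, ty = ty / tl,
       nx = -ty / tl, ny = tx / tl)
}

# project points onto the spline: nearest densified sample gives arc length,
# signed offset by the cross product with the local tangent
spline_project <- function(sp, px, py) {
  n <- length(px)
  s <- numeric(n); off <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (sp$x - px[i])^2 + (sp$y - py[i])^2
    j <- which.min(d2)
    dx <- px[i] - sp$x[j]; dy <- py[i] - sp$y[j]
    s[i] <- sp$s[j] + dx * sp$tx[j] + dy * sp$ty[j]
    off[i] <- dy * sp$tx[j] - dx * sp$ty[j]
  }
  list(s = s, offset = off)
}

#' Read spline control points from CSV (columns `x`, `y`, pixel units)
#' @param path CSV file of control points.
#' @param step densification step.
#' @export
read_spline <- function(path, step = 0.25) {
  d <- utils::read.csv(path)
  ciliary_spline(cbind(d$x, d$y), step = step)
}
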