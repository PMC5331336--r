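#' Kymograph container
#'
#' A kymograph is a 2-D intensity array with time on the first axis (rows,
#' one frame per row) and axial position along the cilium on the second
#' (columns).
#'
#' @param I intensity matrix, time x position.
#' @param dt_frame frame interval, s.
#' @param dx_pixel axial pixel size, nm.
#' @param channel channel label.
#' @return object of class `kymograph`.
#' @export
kymograph <- function(I, dt_frame, dx_pixel, channel = "ch1") {
  I <- as.matrix(I)
  stopifnot(nrow(I) >= 2, ncol(I) >= 2, dt_frame > 0, dx_pixel > 0)
  if (!all(is.finite(I))) stop("kymograph intensities must be finite")
  structure(list(I = I, dt_frame = dt_frame, dx_pixel = dx_pixel,
                 channel = channel),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph [%s]: %d frames x %d px, dt = %.3f s, dx = %.0f nm\n",
              x$channel, nrow(x$I), ncol(x$I), x$dt_frame, x$dx_pixel))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = (seq_len(ncol(x$I)) - 0.5) * x$dx_pixel / 1000,
                  y = (seq_len(nrow(x$I)) - 0.5) * x$dt_frame,
                  z = t(x$I), xlab = "position (um)", ylab = "time (s)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Axial position grid of a kymograph (pixel centres, nm)
#' @param kym a [kymograph].
#' @export
kymo_positions <- function(kym) (seq_len(ncol(kym$I)) - 0.5) * kym$dx_pixel

#' Frame times of a kymograph (s)
#' @param kym a [kymograph].
#' @export
kymo_times <- function(kym) (seq_len(nrow(kym$I)) - 1) * kym$dt_frame

#' Build a kymograph from an image stack along a spline
#'
#' Samples every frame at equal arc-length steps along the ciliary path and
#' sums the intensity over `width` pixels perpendicular to the path.
#'
#' @param stack image array `[ny, nx, nt]` (an `ift_stack` or plain array
#'   with attributes `pixel_size` and `dt_frame`).
#' @param spline an [ift_spline] in pixel coordinates.
#' @param width integer width of the perpendicular summation band, pixels.
#' @return a [kymograph] with `dx_pixel` equal to the stack pixel size.
#' @export
build_kymograph <- function(stack, spline, width = 3L) {
  stopifnot(length(dim(stack)) == 3, width >= 1L)
  px <- attr(stack, "pixel_size"); dt <- attr(stack, "dt_frame")
  if (is.null(px) || is.null(dt))
    stop("stack must carry pixel_size and dt_frame attributes")
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nt <- dim(stack)[3]
  if (nt < 1L) stop("empty stack")
  s_grid <- seq(0, spline$length, by = 1)
  sp <- spline_at(spline, s_grid)
  offs <- seq_len(width) - (width + 1) / 2
  # sample coordinates: n_arc x width
  cx <- outer(sp$x, rep(1, width)) + outer(sp$nx, offs)
  cy <- outer(sp$y, rep(1, width)) + outer(sp$ny, offs)
  if (any(cx < 0 | cx > nx | cy < 0 | cy > ny))
    stop("spline (plus width) exits the image")
  # pixel-unit coordinate u lies in pixel ceiling(u); fractional index u + 0.5
  rowc <- pmin(pmax(cy + 0.5, 1), ny)
  colc <- pmin(pmax(cx + 0.5, 1), nx)
  K <- matrix(0, nt, length(s_grid))
  for (f in seq_len(nt)) {
    vals <- bilinear(stack[, , f], as.vector(rowc), as.vector(colc))
    K[f, ] <- rowSums(matrix(vals, nrow = length(s_grid)))
  }
  kymograph(K, dt, px)
}
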