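# Small numeric helpers shared across modules.

#' @keywords internal
gauss_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# reflect an out-of-range index back into 1..n without repeating the edge sample
refl_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * (n - 1L))
  j <- ifelse(j >= (n - 1L), 2L * (n - 1L) - j, j)
  j + 1L
}

#' Gaussian smoothing with reflective boundaries
#'
#' Two boundary conventions: `"value"` gathers reflected samples (preserves
#' constants; used for image filtering) and `"mass"` scatters each sample
#' through the kernel and folds out-of-range mass back by reflection
#' (conserves the total exactly; used for intensity/occupancy profiles).
#' @param x numeric vector.
#' @param sigma kernel width in samples; 0 returns the input unchanged.
#' @param conserve `"value"` or `"mass"`.
#' @return smoothed vector, same length.
#' @keywords internal
gauss_smooth_1d <- function(x, sigma, truncate = 4, conserve = "value") {
  k <- gauss_kernel(sigma, truncate)
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(x)
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n)
  if (conserve == "mass") {
    for (o in seq_along(k)) {
      tgt <- refl_idx(idx + (o - 1L - r), n)
      agg <- rowsum(k[o] * x, tgt)
      ti <- as.integer(rownames(agg))
      y[ti] <- y[ti] + agg
    }
  } else {
    for (o in seq_along(k)) {
      y <- y + k[o] * x[refl_idx(idx + (o - 1L - r), n)]
    }
  }
  y
}

# separable 2-D Gaussian blur on a matrix (sigma in pixels, per dimension)
gauss_smooth_mat <- function(I, sigma_row, sigma_col = sigma_row) {
  if (sigma_row > 0) I <- apply(I, 2, gauss_smooth_1d, sigma = sigma_row)
  if (sigma_col > 0) I <- t(apply(I, 1, gauss_smooth_1d, sigma = sigma_col))
  I
}

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance on a fixed-bin histogram; used as the
#' default per-channel threshold for Manders coefficients.
#' @keywords internal
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nbins]; mt <- m[nbins]
  w0 <- w[-nbins]; m0 <- m[-nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, nbins - 1L)
  bc[valid] <- (mt * w0[valid] - n * m0[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(bc)]
}

# centred running mean, window w (odd), edges use shrinking windows
moving_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  r <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - r)
  hi <- pmin(n, seq_len(n) + r)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# bilinear interpolation of matrix img at fractional (row, col) positions;
# coordinates outside the matrix clamp to the border
bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# indices of strict local maxima of a vector (plateau start counts once)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[v[i] > v[i - 1L] & v[i] >= v[i + 1L]]
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
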