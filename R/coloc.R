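# Two-colour kymograph colocalization: registration, corrections,
# thresholded Manders coefficients and on-train intensity ratios.

#' Correction parameters for two-colour kymographs
#'
#' @param background per-channel background estimate (length-2 vector,
#'   channel 1 then channel 2).
#' @param bleach_rate per-channel photobleaching rate, 1/s.
#' @param bleedthrough_alpha fraction of (corrected) channel-1 signal leaking
#'   into channel 2.
#' @param excitation_scale intensity correction factor applied to the
#'   channel-1/channel-2 ratio (compensates different excitation/emission
#'   efficiency of the two fluorophores, calibrated from intensity versus
#'   excitation power).
#' @export
correction_config <- function(background = c(0, 0), bleach_rate = c(0, 0),
                              bleedthrough_alpha = 0, excitation_scale = 1) {
  stopifnot(length(background) == 2, length(bleach_rate) == 2,
            all(bleach_rate >= 0), bleedthrough_alpha >= 0,
            bleedthrough_alpha < 1, excitation_scale > 0)
  structure(list(background = background, bleach_rate = bleach_rate,
                 bleedthrough_alpha = bleedthrough_alpha,
                 excitation_scale = excitation_scale),
            class = "correction_config")
}

#' Fit a photobleaching rate from frame-summed intensity
#'
#' Least-squares fit of log total intensity versus time over the first
#' `n_frames` frames.
#'
#' @param kym a [kymograph].
#' @param n_frames frames used for the fit.
#' @param background per-pixel background subtracted before summing.
#' @return bleaching rate, 1/s (non-negative).
#' @export
fit_bleach_rate <- function(kym, n_frames = 100L, background = 0) {
  n <- min(n_frames, nrow(kym$I))
  tot <- rowSums(kym$I[seq_len(n), , drop = FALSE] - background)
  keep <- tot > 0
  if (sum(keep) < 3L) stop("not enough positive frames to fit bleaching")
  t <- kymo_times(kym)[seq_len(n)][keep]
  fit <- stats::lm.fit(cbind(1, t), log(tot[keep]))
  max(0, -fit$coefficients[2])
}

#' Register two kymograph channels on their static features
#'
#' The time-constant (static) component of each channel is cross-correlated;
#' the shift maximizing the correlation, refined to subpixel precision by
#' parabolic interpolation of the correlation peak, is applied to channel 2.
#' Registration uses non-moving features only, so moving trains cannot bias
#' the alignment.
#'
#' @param kym1,kym2 the two channels ([kymograph]); equal shapes.
#' @param max_shift_px maximum allowed shift, pixels.
#' @param min_correlation normalized correlation below which registration is
#'   declared failed.
#' @return list with `shift` (axial shift in pixels applied to channel 2),
#'   `correlation`, and `kym2` (the shifted channel 2).
#' @export
register_channels <- function(kym1, kym2, max_shift_px = 10,
                              min_correlation = 0.2) {
  stopifnot(all(dim(kym1$I) == dim(kym2$I)))
  s1 <- colMeans(kym1$I); s2 <- colMeans(kym2$I)  # static profile per channel
  s1 <- s1 - mean(s1); s2 <- s2 - mean(s2)
  n <- length(s1)
  shifts <- -max_shift_px:max_shift_px
  # shift d > 0 means channel-2 features sit d pixels to the right
  cc <- vapply(shifts, function(d) {
    i1 <- max(1, 1 - d):min(n, n - d)
    i2 <- i1 + d
    if (length(i1) < 4) return(-Inf)
    a <- s1[i1]; b <- s2[i2]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  cc[!is.finite(cc)] <- -Inf
  j <- which.max(cc)
  shift <- shifts[j]
  if (!is.finite(cc[j]) || cc[j] < min_correlation)
    stop("registration failed: correlation peak ", signif(cc[j], 3),
         " below threshold")
  # parabolic subpixel refinement
  if (j > 1 && j < length(shifts) && all(is.finite(cc[c(j - 1, j + 1)]))) {
    den <- cc[j - 1] - 2 * cc[j] + cc[j + 1]
    if (den < 0) shift <- shift + 0.5 * (cc[j - 1] - cc[j + 1]) / den
  }
  I2 <- kym2$I
  cols <- seq_len(n)
  I2s <- t(apply(I2, 1, function(rw)
    stats::approx(cols, rw, xout = cols + shift, rule = 2)$y))
  list(shift = shift, correlation = cc[j],
       kym2 = kymograph(I2s, kym2$dt_frame, kym2$dx_pixel, kym2$channel))
}

#' Correct a kymograph for background, photobleaching and bleed-through
#'
#' Applies `I' = (I - background) / exp(-bleach_rate t)`, then for channel 2
#' subtracts the configured fraction of the corrected channel-1 signal, and
#' clips at zero.
#'
#' @param kym the [kymograph] to correct.
#' @param cfg a [correction_config].
#' @param channel 1 or 2 (selects background/bleach entries; channel 2 also
#'   gets the bleed-through subtraction).
#' @param other_corrected corrected channel-1 [kymograph] (required for
#'   channel 2 when `bleedthrough_alpha > 0`).
#' @return corrected [kymograph].
#' @export
correct_kymograph <- function(kym, cfg, channel = 1L, other_corrected = NULL) {
  stopifnot(inherits(cfg, "correction_config"), channel %in% c(1L, 2L))
  t <- kymo_times(kym)
  Ic <- (kym$I - cfg$background[channel]) /
    exp(-cfg$bleach_rate[channel] * t)  # recycles down columns (time)
  if (channel == 2L && cfg$bleedthrough_alpha > 0) {
    if (is.null(other_corrected))
      stop("channel-2 correction needs the corrected channel 1")
    Ic <- Ic - cfg$bleedthrough_alpha * other_corrected$I
  }
  kymograph(pmax(Ic, 0), kym$dt_frame, kym$dx_pixel, kym$channel)
}

#' Thresholded Manders colocalization coefficients
#'
#' M1 is the fraction of channel-1 intensity residing in pixels where channel
#' 2 exceeds its threshold, and M2 the converse. Thresholds default to Otsu's
#' method per channel within the region of interest; a Costes-style bisection
#' that zeroes the correlation of below-threshold pixels is available, as is
#' a manual threshold pair.
#'
#' @param kym1,kym2 corrected, directionally filtered [kymograph]s of equal
#'   shape.
#' @param roi axial interval `c(min_nm, max_nm)` restricting the analysis.
#' @param method `"otsu"`, `"costes"` or `"manual"`.
#' @param thresholds length-2 numeric, used when `method = "manual"`.
#' @return list `M1`, `M2`, `t1`, `t2`, `n_pixels`.
#' @export
manders_coefficients <- function(kym1, kym2, roi = NULL,
                                 method = c("otsu", "costes", "manual"),
                                 thresholds = NULL) {
  method <- match.arg(method)
  stopifnot(all(dim(kym1$I) == dim(kym2$I)))
  x <- kymo_positions(kym1)
  cols <- if (is.null(roi)) seq_along(x) else which(x >= roi[1] & x <= roi[2])
  if (!length(cols)) stop("roi outside the axial range")
  I1 <- kym1$I[, cols]; I2 <- kym2$I[, cols]
  if (sum(I1) <= 0 || sum(I2) <= 0)
    stop("all-zero channel: Manders coefficients undefined")
  if (method == "otsu") {
    t1 <- otsu_threshold(I1); t2 <- otsu_threshold(I2)
  } else if (method == "costes") {
    t1 <- costes_threshold(I1, I2); t2 <- costes_threshold(I2, I1)
  } else {
    stopifnot(length(thresholds) == 2)
    t1 <- thresholds[1]; t2 <- thresholds[2]
  }
  M1 <- sum(I1[I2 > t2]) / sum(I1)
  M2 <- sum(I2[I1 > t1]) / sum(I2)
  list(M1 = M1, M2 = M2, t1 = t1, t2 = t2, n_pixels = length(I1))
}

# Costes-style bisection: largest threshold on `a` such that the correlation
# of the pixel pairs with a <= t is not positive
costes_threshold <- function(a, b, iters = 30L) {
  lo <- min(a); hi <- max(a)
  for (i in seq_len(iters)) {
    t <- (lo + hi) / 2
    sel <- a <= t
    if (sum(sel) < 3L || stats::sd(a[sel]) == 0 || stats::sd(b[sel]) == 0) {
      lo <- t; next
    }
    if (stats::cor(a[sel], b[sel]) > 0) hi <- t else lo <- t
  }
  (lo + hi) / 2
}

#' Channel intensity ratio along a train
#'
#' Samples both corrected kymographs along one train trace, forms the
#' excitation-corrected channel-1 / channel-2 ratio at every sample, and
#' averages it over a ciliary segment (proximal 0--3.5 um for kinesin-II
#' comparisons, distal 4.0--7.5 um for OSM-3 comparisons).
#'
#' @param kym1,kym2 corrected [kymograph]s.
#' @param trace train trace (data.frame `t`, `x`) from
#'   [extract_train_traces].
#' @param cfg a [correction_config] (supplies `excitation_scale`).
#' @param segment axial interval `c(min_nm, max_nm)` for the average.
#' @return list `ratio` (per-sample data.frame `t`, `x_nm`, `ratio`) and
#'   `segment_mean`.
#' @export
train_intensity_ratio <- function(kym1, kym2, trace, cfg = correction_config(),
                                  segment = c(0, 3500)) {
  row <- trace$t / kym1$dt_frame + 1
  col <- trace$x / kym1$dx_pixel + 0.5
  v1 <- bilinear(kym1$I, row, col)
  v2 <- bilinear(kym2$I, row, col)
  ok <- v2 > 0
  if (!any(ok)) stop("channel 2 non-positive along the whole trace")
  r <- rep(NA_real_, length(v1))
  r[ok] <- cfg$excitation_scale * v1[ok] / v2[ok]
  seg <- ok & trace$x >= segment[1] & trace$x <= segment[2]
  list(ratio = data.frame(t = trace$t, x_nm = trace$x, ratio = r),
       segment_mean = if (any(seg)) mean(r[seg]) else NA_real_)
}
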