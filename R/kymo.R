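# Ensemble kymograph analysis: directional separation, train traces,
# velocity / motor-number / frequency / flux profiles.

fft_freqs <- function(n) {
  f <- 0:(n - 1)
  ifelse(f <= n %/% 2, f, f - n)
}

#' Separate a kymograph into directional components by Fourier filtering
#'
#' Moving structures appear in the 2-D spectrum of a kymograph on lines whose
#' slope sign encodes the direction of motion: anterograde structures
#' (position increasing with time) occupy the quadrants where temporal and
#' spatial frequency have opposite signs, retrograde ones the same-sign
#' quadrants, and non-moving structures the zero-temporal-frequency band.
#' The three spectral masks partition the spectrum (they sum to one
#' everywhere), with a raised-cosine soft edge across the spatial-frequency
#' axis to limit ringing, so the unclipped components (`clip = FALSE`)
#' reconstruct the input exactly. With `clip = TRUE` the directional
#' components are clipped at zero (directional ripple is meaningless as an
#' intensity) and the clipped mass is folded into the static component,
#' which keeps the three-component sum equal to the input wherever that sum
#' is non-negative.
#'
#' @param kym a [kymograph], at least 8 x 8.
#' @param soft_band half-width of the raised-cosine transition across the
#'   spatial-frequency axis, in DFT bins.
#' @param static_band extent of the raised-cosine taper of the static
#'   (zero-temporal-frequency) band, in DFT bins; a hard notch at the zero
#'   row would ring in time.
#' @param clip clip negative ripple of the components at zero.
#' @return list with [kymograph] components `antero`, `retro`, `static`.
#' @export
fourier_directional_filter <- function(kym, soft_band = 2, static_band = 1,
                                       clip = TRUE) {
  I <- kym$I
  nt <- nrow(I); nx <- ncol(I)
  if (nt < 8 || nx < 8) stop("kymograph must be at least 8x8")
  if (!all(is.finite(I))) stop("non-finite kymograph")
  FT <- matrix(fft_freqs(nt), nt, nx)
  FX <- matrix(fft_freqs(nx), nt, nx, byrow = TRUE)
  FI <- stats::fft(I)
  # raised-cosine step 0 -> 1 over [-b, b]
  sstep <- function(u, b) {
    w <- 0.5 * (1 + sin(pi * pmin(pmax(u / b, -1), 1) / 2))
    w
  }
  m_static <- ifelse(abs(FT) < static_band,
                     0.5 * (1 + cos(pi * abs(FT) / static_band)), 0)
  wa <- sstep(-sign(FT) * FX, soft_band)
  # Nyquist rows/columns have ambiguous sign: split evenly to keep the
  # spectrum Hermitian and the components real
  if (nt %% 2 == 0) wa[FT == -(nt %/% 2)] <- 0.5
  if (nx %% 2 == 0) wa[FX == -(nx %/% 2)] <- 0.5
  m_a <- (1 - m_static) * wa
  m_r <- (1 - m_static) * (1 - wa)
  inv <- function(m) Re(stats::fft(FI * m, inverse = TRUE)) / (nt * nx)
  comp <- list(antero = inv(m_a), retro = inv(m_r), static = inv(m_static))
  if (clip) {
    # clip directional ripple at zero and fold the clipped mass into the
    # static component, so the three components still sum to the input
    # wherever that sum is non-negative
    comp$antero <- pmax(comp$antero, 0)
    comp$retro <- pmax(comp$retro, 0)
    comp$static <- pmax(I - comp$antero - comp$retro, 0)
  }
  lapply(comp, function(C)
    kymograph(C, kym$dt_frame, kym$dx_pixel, kym$channel))
}

peak_prominences <- function(v, idx) {
  vapply(idx, function(i) {
    lmin <- v[i]; j <- i
    while (j > 1 && v[j - 1] <= v[i]) { j <- j - 1; lmin <- min(lmin, v[j]) }
    lmin_l <- if (j == 1 && v[j] <= v[i]) min(lmin, v[1]) else lmin
    rmin <- v[i]; j <- i; n <- length(v)
    while (j < n && v[j + 1] <= v[i]) { j <- j + 1; rmin <- min(rmin, v[j]) }
    v[i] - max(lmin_l, rmin)
  }, numeric(1))
}

#' Extract train traces from a directionally filtered kymograph
#'
#' Ridge following: per-frame local intensity maxima above a robust threshold
#' are refined to subpixel position by parabolic interpolation and linked
#' frame-to-frame to the nearest active trace (ties broken by distance, then
#' intensity), with gap closing over one missed frame.
#'
#' @param kym a [kymograph] (one directional component).
#' @param min_frames discard traces shorter than this many frames.
#' @param max_step_px maximum frame-to-frame jump, pixels.
#' @param threshold_k detection threshold: median + k * MAD of the image.
#' @param gap maximum number of consecutive missed frames within a trace.
#' @return list of traces; each is a data.frame `t` (s), `x` (nm),
#'   `intensity`, with attribute `direction` (+1 anterograde, -1 retrograde).
#' @export
extract_train_traces <- function(kym, min_frames = 5L, max_step_px = 6,
                                 threshold_k = 3, gap = 1L) {
  I <- kym$I
  thr <- stats::median(I) + threshold_k * stats::mad(I)
  open <- list()   # each: list(rows of (frame, xpx, int), last_frame, last_x)
  done <- list()
  for (f in seq_len(nrow(I))) {
    v <- moving_mean(I[f, ], 3L)
    pk <- local_maxima(v)
    pk <- pk[I[f, pk] > thr]
    if (length(pk)) {
      dx <- 0.5 * (v[pk - 1L] - v[pk + 1L]) /
        (v[pk - 1L] - 2 * v[pk] + v[pk + 1L])
      dx[!is.finite(dx) | abs(dx) > 1] <- 0
      px <- pk + dx
      pint <- I[f, pk]
    } else { px <- numeric(0); pint <- numeric(0) }
    # match open traces to peaks, nearest first
    used <- rep(FALSE, length(px))
    if (length(open) && length(px)) {
      lastx <- vapply(open, function(o) o$last_x, numeric(1))
      D <- abs(outer(lastx, px, "-"))
      repeat {
        if (!any(is.finite(D)) || min(D, na.rm = TRUE) > max_step_px) break
        ij <- arrayInd(which.min(D), dim(D))
        i <- ij[1]; j <- ij[2]
        o <- open[[i]]
        o$frames <- c(o$frames, f); o$xs <- c(o$xs, px[j])
        o$ints <- c(o$ints, pint[j])
        o$last_frame <- f; o$last_x <- px[j]
        open[[i]] <- o
        used[j] <- TRUE
        D[i, ] <- Inf; D[, j] <- Inf
      }
    }
    # retire stale traces, start new ones
    if (length(open)) {
      stale <- vapply(open, function(o) f - o$last_frame > gap + 1L, logical(1))
      done <- c(done, open[stale])
      open <- open[!stale]
    }
    for (j in which(!used)) {
      open[[length(open) + 1L]] <- list(frames = f, xs = px[j], ints = pint[j],
                                        last_frame = f, last_x = px[j])
    }
  }
  done <- c(done, open)
  out <- list()
  for (o in done) {
    if (length(o$frames) < min_frames) next
    tr <- data.frame(t = (o$frames - 1) * kym$dt_frame,
                     x = (o$xs - 0.5) * kym$dx_pixel,
                     intensity = o$ints)
    attr(tr, "direction") <- if (stats::median(diff(tr$x)) >= 0) 1 else -1
    out[[length(out) + 1L]] <- tr
  }
  out
}

#' Position-dependent velocity profile from traces
#'
#' Finite-difference velocities of every trace are assigned to the position
#' bin of the step midpoint; each bin reports mean, s.e.m. and sample count.
#' Works on train traces from [extract_train_traces] as well as on
#' single-molecule trajectories (any data.frame with `t` and `x`).
#'
#' @param traces list of data.frames with columns `t` (s) and `x` (nm).
#' @param breaks bin edges in nm, or a single number giving the bin width
#'   (default 250 nm bins spanning the data).
#' @param absolute report speeds (|dx/dt|) rather than signed velocities.
#' @return data.frame `x_nm` (bin centre), `mean`, `sem`, `n`.
#' @export
position_velocity_profile <- function(traces, breaks = 250, absolute = TRUE) {
  if (!length(traces)) stop("no traces")
  xm <- numeric(0); vv <- numeric(0)
  for (tr in traces) {
    if (nrow(tr) < 2L) next
    v <- diff(tr$x) / diff(tr$t)
    xm <- c(xm, (tr$x[-1] + tr$x[-nrow(tr)]) / 2)
    vv <- c(vv, if (absolute) abs(v) else v)
  }
  if (!length(vv)) stop("no displacement samples")
  if (length(breaks) == 1L)
    breaks <- seq(floor(min(xm) / breaks) * breaks,
                  ceiling(max(xm) / breaks + 1e-9) * breaks, by = breaks)
  bin <- findInterval(xm, breaks, all.inside = TRUE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  agg_n <- tabulate(bin, length(centers))
  agg_m <- vapply(seq_along(centers), function(b)
    if (agg_n[b]) mean(vv[bin == b]) else NA_real_, numeric(1))
  agg_s <- vapply(seq_along(centers), function(b)
    if (agg_n[b] > 1) stats::sd(vv[bin == b]) / sqrt(agg_n[b]) else NA_real_,
    numeric(1))
  data.frame(x_nm = centers, mean = agg_m, sem = agg_s, n = agg_n)
}

#' Convert fluorescence intensity to motor count
#'
#' Uses the calibrated single-fluorophore intensity and the number of
#' labelled subunits per motor (two tagged light-intermediate-chain subunits
#' per IFT-dynein dimer).
#'
#' @param intensity fluorescence intensity (same units as the calibration).
#' @param I_single_fluor calibrated intensity of one fluorophore.
#' @param subunits_per_motor labelled subunits per motor complex.
#' @export
intensity_to_motor_count <- function(intensity, I_single_fluor,
                                     subunits_per_motor = 2) {
  if (I_single_fluor <= 0) stop("calibration intensity must be positive")
  intensity / (subunits_per_motor * I_single_fluor)
}

#' Detect train passages in an intensity-versus-time series
#'
#' The series (kymograph intensity at a fixed position) is smoothed with a
#' short moving average and peaks with prominence above `k` times the MAD of
#' the first-difference noise are counted as train passages.
#'
#' @param series intensity versus time at a fixed position.
#' @param dt_frame frame interval, s.
#' @param smooth_window moving-average window, frames.
#' @param k prominence threshold in units of the noise MAD.
#' @return list with `times` (s), `n` and `frequency` (trains/s).
#' @export
detect_train_peaks <- function(series, dt_frame, smooth_window = 3L, k = 3) {
  if (length(series) < 5L) stop("series too short")
  s <- moving_mean(series, smooth_window)
  noise <- stats::mad(diff(series)) / sqrt(2)
  idx <- local_maxima(s)
  if (length(idx) && noise > 0) {
    prom <- peak_prominences(s, idx)
    idx <- idx[prom >= k * noise]
  } else if (noise == 0) {
    # noiseless series: any strict local maximum with nonzero prominence
    idx <- idx[peak_prominences(s, idx) > 0]
  }
  duration <- length(series) * dt_frame
  list(times = (idx - 1) * dt_frame, n = length(idx),
       frequency = length(idx) / duration)
}

#' Motor flux profile from a directional kymograph
#'
#' The average number of motors present at each position is obtained from the
#' time-integrated fluorescence intensity divided by (subunits x
#' single-fluorophore intensity x number of frames); multiplying by the local
#' velocity gives the flux profile. When no bleaching correction has been
#' applied, only the first `first_n_frames` frames are used so bleaching does
#' not bias the intensity-calibrated quantities.
#'
#' @param kym directionally filtered [kymograph].
#' @param velocity velocity profile (data.frame `x_nm`, `mean` from
#'   [position_velocity_profile]) or a single speed in nm/s.
#' @param I_single_fluor calibrated single-fluorophore intensity.
#' @param subunits_per_motor labelled subunits per motor.
#' @param background per-pixel background intensity to subtract.
#' @param bleach_corrected set TRUE if the kymograph is already bleaching
#'   corrected; otherwise only the first `first_n_frames` frames are used.
#' @param first_n_frames frames used when `bleach_corrected` is FALSE.
#' @return data.frame of class `flux_profile`: `x_nm`, `motors` (average
#'   motors per pixel), `v` (nm/s), `flux` (= motors x v).
#' @export
compute_flux <- function(kym, velocity, I_single_fluor,
                         subunits_per_motor = 2, background = 0,
                         bleach_corrected = FALSE, first_n_frames = 100L) {
  frames <- if (bleach_corrected) seq_len(nrow(kym$I))
            else seq_len(min(first_n_frames, nrow(kym$I)))
  x <- kymo_positions(kym)
  Isum <- colMeans(kym$I[frames, , drop = FALSE]) - background
  motors <- intensity_to_motor_count(pmax(Isum, 0), I_single_fluor,
                                     subunits_per_motor)
  v <- if (is.data.frame(velocity)) {
    ok <- is.finite(velocity$mean)
    stats::approx(velocity$x_nm[ok], velocity$mean[ok], xout = x,
                  rule = 2)$y
  } else rep(velocity, length(x))
  out <- data.frame(x_nm = x, motors = motors, v = v, flux = motors * v)
  class(out) <- c("flux_profile", "data.frame")
  out
}
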