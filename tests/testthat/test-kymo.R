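# Ensemble kymograph analysis: directional separation, traces, profiles.

test_that("Fourier filter sends directional energy to the right component", {
  # line fully inside the field; moving (non-static) energy must end up in
  # the anterograde component
  ky <- line_kymograph(v_nm_s = 900, x0 = 1500, nt = 40)
  fd <- fourier_directional_filter(ky, clip = FALSE)
  energy <- function(I) sum((I - mean(I))^2)
  e_mov <- energy(fd$antero$I) + energy(fd$retro$I)
  expect_gt(energy(fd$antero$I) / e_mov, 0.95)
  expect_lt(energy(fd$retro$I) / e_mov, 0.05)
})

test_that("a time-constant kymograph is entirely static", {
  I <- matrix(rep(exp(-((1:90) - 40)^2 / 200), each = 64), 64, 90)
  ky <- kymograph(I, 0.15, 100)
  fd <- fourier_directional_filter(ky)
  expect_equal(fd$static$I, I, tolerance = 1e-8)
  expect_lt(max(fd$antero$I), 1e-8 * max(I))
  expect_lt(max(fd$retro$I), 1e-8 * max(I))
})

test_that("components reconstruct the input and recover both line slopes", {
  ka <- line_kymograph(900, x0 = 1500, nt = 40)
  kr <- line_kymograph(-900, x0 = 7500, nt = 40)
  ky <- kymograph(ka$I + kr$I, 0.15, 100)
  # unclipped components partition the spectrum exactly
  fd0 <- fourier_directional_filter(ky, clip = FALSE)
  recon0 <- fd0$antero$I + fd0$retro$I + fd0$static$I
  expect_equal(recon0, ky$I, tolerance = 1e-10)
  # clipped components of a realistic dense kymograph reconstruct within 5%
  cfg <- kinetics_config()
  tset <- simulate_train_set(cfg, duration = 30, seed = 31)
  kyd <- render_kymograph(tset,
                          optics_config(photons_per_frame = 30,
                                        background_rate = 5,
                                        shot_noise = FALSE),
                          30, 9000, dt_frame = 0.15)
  fdd <- fourier_directional_filter(kyd)
  recon <- fdd$antero$I + fdd$retro$I + fdd$static$I
  expect_lt(sqrt(sum((recon - kyd$I)^2)) / sqrt(sum(kyd$I^2)), 0.05)
  # each two-line component recovers its line's slope (longest trace)
  fd <- fourier_directional_filter(ky)
  longest <- function(trs) trs[[which.max(vapply(trs, nrow, numeric(1)))]]
  tr_a <- extract_train_traces(fd$antero, min_frames = 10)
  tr_r <- extract_train_traces(fd$retro, min_frames = 10)
  expect_gte(length(tr_a), 1)
  expect_gte(length(tr_r), 1)
  expect_lt(abs(trace_slope(longest(tr_a)) - 900) / 900, 0.05)
  expect_lt(abs(trace_slope(longest(tr_r)) + 900) / 900, 0.05)
})

test_that("trace extraction finds lines and ignores blank images", {
  ky <- line_kymograph(1200)
  tr <- extract_train_traces(ky, min_frames = 10)
  expect_length(tr, 1)
  expect_equal(attr(tr[[1]], "direction"), 1)
  expect_lt(abs(trace_slope(tr[[1]]) - 1200) / 1200, 0.05)
  blank <- kymograph(matrix(1, 32, 32), 0.15, 100)
  expect_length(extract_train_traces(blank), 0)
  # two parallel lines separated by >= 3 psf widths give two traces
  k2 <- kymograph(line_kymograph(1200, x0 = 1000)$I +
                    line_kymograph(1200, x0 = 3000)$I, 0.15, 100)
  expect_length(extract_train_traces(k2, min_frames = 10), 2)
})

test_that("velocity profiles recover constant speed and the slow-down dip", {
  cfg <- kinetics_config(sigma_loc = 0, pause_rate = 0)
  set.seed(20)
  traces <- lapply(1:40, function(i)
    attr(simulate_trajectory(flat_cfg(P_AR = 0, P_RA = 0), "anterograde",
                             x0 = stats::runif(1, 0, 3000), duration = 3),
         "truth"))
  vp <- position_velocity_profile(traces, breaks = 250)
  good <- vp$n >= 10
  expect_true(all(abs(vp$mean[good] - 1700) / 1700 < 0.05))
  # single two-point trace: exactly dx/dt in one bin
  one <- list(data.frame(t = c(0, 0.15), x = c(1000, 1255)))
  vp1 <- position_velocity_profile(one, breaks = c(1000, 1250))
  expect_equal(vp1$mean, 255 / 0.15)
  expect_equal(vp1$n, 1)
  # transition-zone dip: minimum bin within one bin of the dip centre
  set.seed(21)
  dip_traces <- lapply(1:60, function(i)
    attr(simulate_trajectory(cfg, "anterograde", x0 = 0, duration = 2),
         "truth"))
  vpd <- position_velocity_profile(dip_traces, breaks = 250)
  sel <- vpd$n >= 10 & vpd$x_nm < 2000
  expect_lt(abs(vpd$x_nm[sel][which.min(vpd$mean[sel])] - 1000), 375)
})

test_that("intensity converts to motor counts through the calibration", {
  expect_equal(intensity_to_motor_count(2 * 15, 15), 1)
  expect_equal(intensity_to_motor_count(80 * 15, 15), 40)
  expect_error(intensity_to_motor_count(10, 0), "positive")
  # rendered train of 25 motors recovers ~25 with shot noise
  cfg <- flat_cfg()
  tset <- simulate_train_set(cfg, duration = 8, n_antero = 1, n_retro = 0,
                             motors_antero = 25, seed = 22)
  opt <- optics_config(photons_per_frame = 50, background_rate = 2,
                       seed = 23)
  ky <- render_kymograph(tset, opt, 8, 9000, dt_frame = 0.15)
  # peak row intensity integrated across the line-spread
  f <- 20
  tot <- sum(ky$I[f, ] - 2)
  n_mot <- intensity_to_motor_count(tot, 50 / 2)  # 50 photons = 2 subunits
  expect_lt(abs(n_mot - 25) / 25, 0.15)
})

test_that("peak detection counts well-separated train passages", {
  t_idx <- 1:120
  ser <- rowSums(vapply(c(15, 35, 55, 80, 105), function(c0)
    80 * exp(-(t_idx - c0)^2 / 8), numeric(120)))
  ser <- ser + stats::rnorm(120, 0, 1)
  set.seed(24)
  pk <- detect_train_peaks(ser, 0.15)
  expect_equal(pk$n, 5)
  expect_equal(detect_train_peaks(rep(3, 60), 0.15)$n, 0)
  expect_error(detect_train_peaks(1:3, 0.15), "short")
})

test_that("recovered departure-frequency ratio matches the generator", {
  cfg <- kinetics_config()
  set.seed(25)
  tset <- simulate_train_set(cfg, duration = 120)
  opt <- optics_config(photons_per_frame = 30, background_rate = 3,
                       seed = 26)
  ky <- render_kymograph(tset, opt, 120, 9000, dt_frame = 0.15)
  fd <- fourier_directional_filter(ky)
  x_col <- 45
  f_a <- detect_train_peaks(fd$antero$I[, x_col], 0.15)$frequency
  f_r <- detect_train_peaks(fd$retro$I[, x_col], 0.15)$frequency
  expect_gt(f_r / f_a, 1.6 - 0.5)
  expect_lt(f_r / f_a, 1.6 + 0.5)
})

test_that("flux is linear in motor load and direction-balanced at equal throughput", {
  cfg <- flat_cfg()
  opt <- optics_config(photons_per_frame = 10, background_rate = 0,
                       shot_noise = FALSE)
  mk_flux <- function(n_motors, n_trains, retro = FALSE) {
    tset <- simulate_train_set(cfg, duration = 60,
                               n_antero = if (retro) 0 else n_trains,
                               n_retro = if (retro) n_trains else 0,
                               motors_antero = n_motors,
                               motors_retro = n_motors, seed = 27)
    ky <- render_kymograph(tset, opt, 60, 9000, dt_frame = 0.15)
    compute_flux(ky, 1700, I_single_fluor = 10 / 2, bleach_corrected = TRUE)
  }
  f1 <- mk_flux(20, 12)
  f2 <- mk_flux(40, 12)
  mid <- 20:70
  expect_equal(mean(f2$flux[mid]) / mean(f1$flux[mid]), 2, tolerance = 0.02)
  # equal throughput: 40-motor antero trains vs twice as many 20-motor retro
  fa <- mk_flux(40, 10)
  fr <- mk_flux(20, 20, retro = TRUE)
  expect_lt(abs(mean(fr$flux[mid]) / mean(fa$flux[mid]) - 1), 0.10)
  # rescaling intensities together with the calibration changes nothing
  ky <- render_kymograph(simulate_train_set(cfg, duration = 30, n_antero = 5,
                                            n_retro = 0, seed = 28),
                         opt, 30, 9000, dt_frame = 0.15)
  fA <- compute_flux(ky, 1700, 5, bleach_corrected = TRUE)
  kyS <- kymograph(ky$I * 7, ky$dt_frame, ky$dx_pixel)
  fB <- compute_flux(kyS, 1700, 35, bleach_corrected = TRUE)
  expect_equal(fA$flux, fB$flux, tolerance = 1e-10)
  # empty kymograph: zero flux everywhere
  f0 <- compute_flux(kymograph(matrix(0, 16, 16), 0.15, 100), 1700, 5)
  expect_true(all(f0$flux == 0))
})

test_that("build_kymograph slopes match the generator ground truth", {
  cfg <- flat_cfg(P_AR = 0, P_RA = 0)
  tr <- simulate_trajectory(cfg, "anterograde", seed = 29, x0 = 200,
                            duration = 4.5)
  opt <- optics_config(photons_per_frame = 300, background_rate = 2,
                       seed = 30)
  st <- render_image_stack(list(tr), opt, duration = 4.5, L = 9000)
  ky <- build_kymograph(st, straight_spline(90, 15), width = 5)
  tra <- extract_train_traces(ky, min_frames = 8)
  expect_gte(length(tra), 1)
  slopes <- vapply(tra, trace_slope, numeric(1))
  expect_lt(abs(slopes[which.max(vapply(tra, nrow, numeric(1)))] - 1700) /
              1700, 0.05)
  expect_error(build_kymograph(st, ciliary_spline(cbind(c(-20, 200),
                                                        c(7, 7)))),
               "exits")
})
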