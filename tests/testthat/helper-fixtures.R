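# Fixtures shared across test files; everything is generated in code.

flat_profile <- function(v = 1700, L = 9000) speed_profile(c(0, L), c(v, v), L = L)

# kinetics with a flat speed profile and switchable noise/pauses
flat_cfg <- function(P_AR = 0.14, P_RA = 0.07, sigma_loc = 0, pause_rate = 0,
                     L = 9000, ...) {
  kinetics_config(L = L, v_antero = flat_profile(L = L),
                  v_retro = flat_profile(L = L),
                  P_AR = P_AR, P_RA = P_RA, sigma_loc = sigma_loc,
                  pause_rate = pause_rate, ...)
}

# noiseless kymograph with one straight moving line (Gaussian cross-section)
line_kymograph <- function(v_nm_s, x0 = 1000, nt = 64, nx = 90,
                           dt = 0.15, dx = 100, sigma = 150, amp = 100,
                           bg = 0) {
  I <- matrix(bg, nt, nx)
  centers <- (seq_len(nx) - 0.5) * dx
  for (f in seq_len(nt)) {
    x <- x0 + v_nm_s * (f - 1) * dt
    I[f, ] <- I[f, ] + amp * exp(-(centers - x)^2 / (2 * sigma^2))
  }
  kymograph(I, dt, dx)
}

# straight horizontal spline spanning an nx-wide image
straight_spline <- function(nx, ny) {
  ciliary_spline(cbind(c(0, nx), c(ny / 2, ny / 2)))
}

# least-squares slope of a trace (nm/s)
trace_slope <- function(tr) unname(stats::coef(stats::lm(x ~ t, tr))[2])
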