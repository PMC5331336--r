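# Stochastic single-motor simulator: links single-molecule switching
# statistics to the ensemble motor distribution along the cilium.

#' Configuration of the stochastic single-motor simulator
#'
#' A single motor shuttles along a track of length `L`, moving at the
#' position-dependent velocity of its current direction and switching
#' direction stochastically with per-distance hazards `P_AR` and `P_RA`. At
#' the tip it is forced to turn (pause `tau_AR_tip`, default none); at the
#' base it is forced to turn after an exponentially distributed pause of
#' mean `tau_RA_base_mean`. One event is a base-to-base round trip (possibly
#' with many intermediate reversals).
#'
#' Two sampling modes are provided: `"exact"` draws the distance to the next
#' reversal from the continuous exponential distribution; `"step"` walks the
#' track in discrete steps of `step` nm with per-step turn probability
#' `P * step` (sampled as the equivalent geometric step count). At nanometre
#' steps the two are indistinguishable; `"step"` exists to validate the
#' hazard discretization.
#'
#' @param L track length, nm.
#' @param step discretization step for `"step"` mode, nm; must divide `L`.
#' @param v_antero,v_retro speed profiles ([speed_profile]), nm/s.
#' @param P_AR,P_RA turnaround probability densities, 1/um.
#' @param tau_AR_tip pause at the forced tip turn, s.
#' @param tau_RA_base_mean mean of the exponential pause at the base, s.
#' @param n_events number of simulated motor round trips.
#' @param base_returns base arrivals that end one event.
#' @param bin occupancy histogram bin width, nm.
#' @param psf_sigma width of the Gaussian used by [psf_smooth] when
#'   presenting the occupancy, nm.
#' @param overlap_x0,overlap_scale parameters of the phasmid-overlap
#'   correction (see [overlap_correction]), nm.
#' @param tip_region extent of the region below the tip within which the
#'   forced turn happens (0 = exactly at the tip), nm.
#' @param mode `"exact"` or `"step"`.
#' @param seed optional RNG seed.
#' @export
sim_config <- function(L = 9000, step = 1,
                       v_antero = speed_profile(L = L),
                       v_retro = speed_profile(L = L),
                       P_AR = 0.14, P_RA = 0.07,
                       tau_AR_tip = 0, tau_RA_base_mean = 0.5,
                       n_events = 10000, base_returns = 1L,
                       bin = 50, psf_sigma = 150,
                       overlap_x0 = 3500, overlap_scale = 200,
                       tip_region = 0,
                       mode = c("exact", "step"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(L > 0, step > 0, P_AR >= 0, P_RA >= 0, n_events >= 1,
            tau_AR_tip >= 0, tau_RA_base_mean >= 0, bin > 0,
            tip_region >= 0, tip_region < L)
  if (abs(L / step - round(L / step)) > 1e-9) stop("step must divide L")
  if (P_AR * step / 1000 > 1 || P_RA * step / 1000 > 1)
    stop("per-step turn probability exceeds 1; reduce step")
  structure(list(L = L, step = step, v_antero = v_antero, v_retro = v_retro,
                 P_AR = P_AR, P_RA = P_RA, tau_AR_tip = tau_AR_tip,
                 tau_RA_base_mean = tau_RA_base_mean,
                 n_events = as.integer(n_events),
                 base_returns = as.integer(base_returns),
                 bin = bin, psf_sigma = psf_sigma,
                 overlap_x0 = overlap_x0, overlap_scale = overlap_scale,
                 tip_region = tip_region, mode = mode, seed = seed),
            class = "sim_config")
}

# distance to the next reversal, nm (hazard P in 1/um)
draw_turn_distance <- function(P, step, mode) {
  if (P <= 0) return(Inf)
  if (mode == "exact") return(stats::rexp(1, P / 1000))
  (stats::rgeom(1, P * step / 1000) + 1) * step
}

#' Run the stochastic single-motor simulation
#'
#' Simulates `n_events` motor round trips and accumulates the time-weighted
#' occupancy (time spent per 50 nm position bin, including pauses) and the
#' per-direction turnaround-location histograms.
#'
#' @param cfg a [sim_config].
#' @return object of class `ift_sim`: `occupancy` (data.frame `x_nm`,
#'   `time_s`), `turns_ar`, `turns_ra` (per-bin turnaround counts, boundary
#'   turns included), `n_events`, `clean_transit_frac` (fraction of events
#'   whose first excursion reached the tip without a reversal), `N_AR_mid`,
#'   `N_RA_mid` (mid-track turn counts), `D_antero_um`, `D_retro_um`
#'   (total distances travelled) and the configuration.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set_seed_if(cfg$seed)
  v_a <- speed_at(cfg$v_antero, seq(0, cfg$L, length.out = 64))
  v_r <- speed_at(cfg$v_retro, seq(0, cfg$L, length.out = 64))
  if (any(v_a <= 0) || any(v_r <= 0)) stop("speed must be positive on track")

  nb <- ceiling(cfg$L / cfg$bin)
  centers <- (seq_len(nb) - 0.5) * cfg$bin
  resid_a <- cfg$bin / speed_at(cfg$v_antero, centers)
  resid_r <- cfg$bin / speed_at(cfg$v_retro, centers)
  tip_turn_at <- function()
    if (cfg$tip_region > 0) stats::runif(1, cfg$L - cfg$tip_region, cfg$L)
    else cfg$L

  cap <- 8L * cfg$n_events
  p_lo <- numeric(cap); p_hi <- numeric(cap); p_dir <- integer(cap)
  np <- 0L
  t_ar <- numeric(cap); t_ra <- numeric(cap)
  n_ar <- 0L; n_ra <- 0L
  add_pass <- function(lo, hi, dirn) {
    np <<- np + 1L
    if (np > length(p_lo)) {
      p_lo <<- c(p_lo, numeric(cap)); p_hi <<- c(p_hi, numeric(cap))
      p_dir <<- c(p_dir, integer(cap))
    }
    p_lo[np] <<- lo; p_hi[np] <<- hi; p_dir[np] <<- dirn
  }
  base_pause_total <- 0
  tip_pause_total <- 0
  clean <- logical(cfg$n_events)
  mid_ar <- 0L; mid_ra <- 0L

  for (e in seq_len(cfg$n_events)) {
    x <- 0; dirn <- 1L; returns <- 0L; first <- TRUE
    repeat {
      if (dirn > 0L) {
        d <- draw_turn_distance(cfg$P_AR, cfg$step, cfg$mode)
        x_tip <- tip_turn_at()
        if (d >= x_tip - x) {
          add_pass(x, x_tip, 1L)
          if (first) { clean[e] <- TRUE; first <- FALSE }
          n_ar <- n_ar + 1L
          if (n_ar > length(t_ar)) t_ar <- c(t_ar, numeric(cap))
          t_ar[n_ar] <- x_tip
          tip_pause_total <- tip_pause_total + cfg$tau_AR_tip
          x <- x_tip; dirn <- -1L
        } else {
          add_pass(x, x + d, 1L)
          if (first) first <- FALSE
          n_ar <- n_ar + 1L
          if (n_ar > length(t_ar)) t_ar <- c(t_ar, numeric(cap))
          t_ar[n_ar] <- x + d
          mid_ar <- mid_ar + 1L
          x <- x + d; dirn <- -1L
        }
      } else {
        d <- draw_turn_distance(cfg$P_RA, cfg$step, cfg$mode)
        if (d >= x) {
          add_pass(0, x, -1L)
          if (cfg$tau_RA_base_mean > 0)
            base_pause_total <- base_pause_total +
              stats::rexp(1, 1 / cfg$tau_RA_base_mean)
          n_ra <- n_ra + 1L
          if (n_ra > length(t_ra)) t_ra <- c(t_ra, numeric(cap))
          t_ra[n_ra] <- 0
          x <- 0; dirn <- 1L
          returns <- returns + 1L
          if (returns >= cfg$base_returns) break
        } else {
          add_pass(x - d, x, -1L)
          n_ra <- n_ra + 1L
          if (n_ra > length(t_ra)) t_ra <- c(t_ra, numeric(cap))
          t_ra[n_ra] <- x - d
          mid_ra <- mid_ra + 1L
          x <- x - d; dirn <- 1L
        }
      }
    }
  }

  lo <- p_lo[seq_len(np)]; hi <- p_hi[seq_len(np)]; dirs <- p_dir[seq_len(np)]
  occ <- numeric(nb)
  for (dd in c(1L, -1L)) {
    sel <- dirs == dd
    if (!any(sel)) next
    occ <- occ + coverage_profile(lo[sel], hi[sel], cfg$bin, nb) *
      (if (dd > 0L) resid_a else resid_r)
  }
  occ[1] <- occ[1] + base_pause_total
  occ[nb] <- occ[nb] + tip_pause_total
  bin_of <- function(v) pmin(pmax(ceiling(v / cfg$bin), 1L), nb)
  turns_ar <- tabulate(bin_of(t_ar[seq_len(n_ar)]), nb)
  turns_ra <- tabulate(bin_of(pmax(t_ra[seq_len(n_ra)], cfg$bin / 2)), nb)
  structure(list(
    occupancy = data.frame(x_nm = centers, time_s = occ),
    turns_ar = turns_ar, turns_ra = turns_ra,
    n_events = cfg$n_events,
    clean_transit_frac = mean(clean),
    N_AR_mid = mid_ar, N_RA_mid = mid_ra,
    D_antero_um = sum((hi - lo)[dirs == 1L]) / 1000,
    D_retro_um = sum((hi - lo)[dirs == -1L]) / 1000,
    config = cfg), class = "ift_sim")
}

# fractional bin coverage summed over intervals [lo, hi] (difference-array
# trick for the fully covered bins, explicit fractions for the edge bins)
coverage_profile <- function(lo, hi, bin, nb) {
  blo <- pmin(pmax(floor(lo / bin) + 1L, 1L), nb)
  bhi <- pmin(pmax(floor((hi - 1e-12) / bin) + 1L, 1L), nb)
  cover <- numeric(nb)
  same <- blo == bhi
  wtab <- function(idx, w) {
    out <- numeric(nb)
    if (!length(idx)) return(out)
    agg <- rowsum(w, idx)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  cover <- cover + wtab(blo[same], (hi[same] - lo[same]) / bin)
  if (any(!same)) {
    l <- lo[!same]; h <- hi[!same]; bl <- blo[!same]; bh <- bhi[!same]
    cover <- cover + wtab(bl, (bl * bin - l) / bin)
    cover <- cover + wtab(bh, (h - (bh - 1L) * bin) / bin)
    # full interior bins bl+1 .. bh-1 via cumulative difference counts
    d <- tabulate(pmin(bl + 1L, nb + 1L), nb + 1L) -
      tabulate(pmin(bh, nb + 1L), nb + 1L)
    cover <- cover + cumsum(d)[seq_len(nb)]
  }
  cover
}

#' Phasmid-overlap correction factor
#'
#' The two phasmid cilia overlap in the distal segment, so measured
#' intensities there collect signal from two cilia. Profiles are multiplied
#' by `2 - 1/(exp((x - x0)/scale) + 1)`: the factor rises smoothly from 1
#' (proximal, single cilium) to 2 (distal, two overlapping cilia), passing
#' 1.5 at `x0`.
#'
#' @param x axial position, nm.
#' @param x0 midpoint of the transition, nm.
#' @param scale transition width, nm.
#' @export
overlap_correction <- function(x, x0 = 3500, scale = 200) {
  stopifnot(all(is.finite(x)))
  2 - 1 / (exp((x - x0) / scale) + 1)
}

#' Gaussian smoothing of a spatial profile (PSF emulation)
#'
#' Convolves a profile with a Gaussian of the microscope's point-spread
#' width, with reflective boundaries; total mass is conserved.
#'
#' @param profile numeric vector.
#' @param psf_sigma Gaussian width in the units of the grid spacing `dx`.
#' @param dx grid spacing.
#' @export
psf_smooth <- function(profile, psf_sigma, dx = 1) {
  stopifnot(psf_sigma >= 0)
  if (psf_sigma == 0) return(profile)
  gauss_smooth_1d(profile, psf_sigma / dx, conserve = "mass")
}

#' Presented occupancy profile of a simulation
#'
#' Applies the phasmid-overlap correction and the PSF smoothing configured
#' in the simulation to the raw time-in-position histogram, giving the
#' profile comparable to a measured ensemble fluorescence distribution.
#'
#' @param sim an `ift_sim` result.
#' @param corrected apply the overlap correction.
#' @param smoothed apply the PSF smoothing.
#' @return data.frame `x_nm`, `occupancy_raw`, `occupancy`.
#' @export
occupancy_profile <- function(sim, corrected = TRUE, smoothed = TRUE) {
  cfg <- sim$config
  occ <- sim$occupancy$time_s
  out <- occ
  if (corrected)
    out <- out * overlap_correction(sim$occupancy$x_nm, cfg$overlap_x0,
                                    cfg$overlap_scale)
  if (smoothed) out <- psf_smooth(out, cfg$psf_sigma, cfg$bin)
  data.frame(x_nm = sim$occupancy$x_nm, occupancy_raw = occ, occupancy = out)
}

#' @export
print.ift_sim <- function(x, ...) {
  cat(sprintf("stochastic motor simulation: %d events (P_AR = %.3f, P_RA = %.3f /um)\n",
              x$n_events, x$config$P_AR, x$config$P_RA))
  cat(sprintf("  clean base-to-tip transits: %.1f%%\n",
              100 * x$clean_transit_frac))
  cat(sprintf("  mid-track turns: %d A-to-R, %d R-to-A over %.0f / %.0f um\n",
              x$N_AR_mid, x$N_RA_mid, x$D_antero_um, x$D_retro_um))
  invisible(x)
}

#' @export
plot.ift_sim <- function(x, ...) {
  pr <- occupancy_profile(x)
  graphics::plot(pr$x_nm / 1000, pr$occupancy / max(pr$occupancy),
                 type = "l", xlab = "position (um)",
                 ylab = "relative occupancy", ...)
  invisible(x)
}

#' Compare two spatial profiles up to amplitude
#'
#' Least-squares amplitude scaling of the first profile onto the second,
#' then the root-mean-square residual normalized by the RMS of the second
#' profile. Invariant to rescaling either input; 0 for proportional
#' profiles.
#'
#' @param sim_profile data.frame with `x_nm` and a value column, or numeric
#'   vector.
#' @param measured_profile same form; resampled onto the first grid when
#'   x-grids differ.
#' @return list `scale`, `residual`.
#' @export
compare_distributions <- function(sim_profile, measured_profile) {
  get_xy <- function(p) {
    if (is.data.frame(p)) {
      ycol <- setdiff(names(p), "x_nm")[length(setdiff(names(p), "x_nm"))]
      list(x = p$x_nm, y = p[[ycol]])
    } else list(x = seq_along(p), y = as.numeric(p))
  }
  a <- get_xy(sim_profile); b <- get_xy(measured_profile)
  if (length(a$y) != length(b$y) || !isTRUE(all.equal(a$x, b$x))) {
    if (is.null(b$x)) stop("incompatible grids")
    b$y <- stats::approx(b$x, b$y, xout = a$x, rule = 2)$y
  }
  s <- sum(a$y * b$y) / sum(a$y^2)
  list(scale = s,
       residual = sqrt(mean((s * a$y - b$y)^2)) / sqrt(mean(b$y^2)))
}
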