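#' Kinetic parameters of the synthetic single-motor generator
#'
#' Describes the motility model used to generate ground-truth IFT-dynein
#' trajectories: directed runs at a position-dependent speed with a
#' transition-zone slow-down, direction-specific turnaround hazards expressed
#' as probability densities per micrometre travelled, within-run pauses,
#' diffusion at the ciliary base, stationary particles, and camera sampling
#' with Gaussian localization noise.
#'
#' Turnarounds follow a continuous exponential-distance model: the distance to
#' the next directional switch is exponentially distributed with mean `1/P`
#' (`P_AR` for anterograde motors, `P_RA` for retrograde ones). Under this
#' model the probability of covering a distance `d` without switching is
#' `exp(-P d)`, which is the arithmetic that links the hazards to reach
#' probabilities and run lengths.
#'
#' @param L cilium length, nm.
#' @param v_antero,v_retro speed profiles (see [speed_profile]), nm/s.
#' @param P_AR anterograde-to-retrograde turnaround probability density,
#'   per micrometre travelled.
#' @param P_RA retrograde-to-anterograde turnaround probability density.
#' @param pause_rate rate of within-run pauses, per second of moving time.
#' @param pause_mean mean pause duration, s (exponential).
#' @param D_base diffusion coefficient of base-diffusive motors, nm^2/s.
#' @param base_region axial extent of the base region, nm.
#' @param class_fractions mixture weights of the generated behaviour classes
#'   `anterograde`, `retrograde`, `base_diffusive`, `stationary`; must sum
#'   to 1. Trajectories of the directed classes may switch direction through
#'   the hazards, so a "turnaround" class emerges rather than being drawn.
#' @param dt_frame camera frame interval, s.
#' @param sigma_loc localization noise (Gaussian s.d.), nm.
#' @param track_min_s,track_mean_s observable track duration: `track_min_s`
#'   plus an exponential excess of mean `track_mean_s` (photobleaching-limited
#'   observation window).
#' @param track_max_s hard cap on track duration, s.
#' @param turn_pause_mean mean pause at a mid-track directional switch, s
#'   (0 = instantaneous switches).
#' @param seed optional RNG seed stored with the configuration.
#' @return a list of class `kinetics_config`.
#' @export
kinetics_config <- function(L = 9000,
                            v_antero = speed_profile(L = L),
                            v_retro = speed_profile(L = L),
                            P_AR = 0.14, P_RA = 0.07,
                            pause_rate = 0.15, pause_mean = 0.7,
                            D_base = 4e4, base_region = 500,
                            class_fractions = c(anterograde = 0.44,
                                                retrograde = 0.26,
                                                base_diffusive = 0.21,
                                                stationary = 0.09),
                            dt_frame = 0.15, sigma_loc = 40,
                            track_min_s = 0.30, track_mean_s = 1.0,
                            track_max_s = 12, turn_pause_mean = 0,
                            seed = NULL) {
  stopifnot(L > 0, P_AR >= 0, P_RA >= 0, pause_rate >= 0, pause_mean > 0,
            D_base >= 0, base_region > 0, dt_frame > 0, sigma_loc >= 0,
            track_min_s >= 0, track_mean_s > 0)
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  need <- c("anterograde", "retrograde", "base_diffusive", "stationary")
  if (!all(need %in% names(class_fractions)))
    stop("class_fractions must name: ", paste(need, collapse = ", "))
  cfg <- list(L = L, v_antero = v_antero, v_retro = v_retro,
              P_AR = P_AR, P_RA = P_RA,
              pause_rate = pause_rate, pause_mean = pause_mean,
              D_base = D_base, base_region = base_region,
              class_fractions = class_fractions,
              dt_frame = dt_frame, sigma_loc = sigma_loc,
              track_min_s = track_min_s, track_mean_s = track_mean_s,
              track_max_s = track_max_s, turn_pause_mean = turn_pause_mean,
              seed = seed)
  # cumulative travel-time tables T(x) = integral_0^x dx'/v(x')
  cfg$tab_a <- travel_table(v_antero, L)
  cfg$tab_r <- travel_table(v_retro, L)
  class(cfg) <- "kinetics_config"
  cfg
}

#' Piecewise-linear speed profile
#'
#' Default: 1700 nm/s along proximal and distal segments with a linear dip to
#' 800 nm/s centred in the transition zone (0.5--1.5 um), emulating the
#' slow-down of IFT trains crossing transition-zone structures. Only the
#' plateau speed (~1.7 um/s) is an experimentally reported value; the dip
#' depth is a model default.
#'
#' @param x_knots,v_knots knot positions (nm) and speeds (nm/s).
#' @param L cilium length used for the default knots, nm.
#' @return function-like object of class `speed_profile`.
#' @export
speed_profile <- function(x_knots = c(0, 500, 1000, 1500, L),
                          v_knots = c(1700, 1700, 800, 1700, 1700),
                          L = 9000) {
  stopifnot(length(x_knots) == length(v_knots), all(v_knots > 0),
            !is.unsorted(x_knots))
  structure(list(x = x_knots, v = v_knots), class = "speed_profile")
}

#' Evaluate a speed profile at axial positions (nm)
#' @param profile a [speed_profile].
#' @param x positions, nm.
#' @export
speed_at <- function(profile, x) {
  stats::approx(profile$x, profile$v, xout = x, rule = 2)$y
}

travel_table <- function(profile, L, dx = 5) {
  xg <- seq(0, L, by = dx)
  if (xg[length(xg)] < L) xg <- c(xg, L)
  v <- speed_at(profile, (xg[-1] + xg[-length(xg)]) / 2)
  list(x = xg, t = c(0, cumsum(diff(xg) / v)))
}

# travel time between axial positions using a cumulative table
travel_time <- function(tab, x0, x1) {
  abs(stats::approx(tab$x, tab$t, x1, rule = 2)$y -
        stats::approx(tab$x, tab$t, x0, rule = 2)$y)
}

track_duration <- function(cfg) {
  min(cfg$track_min_s + stats::rexp(1, 1 / cfg$track_mean_s), cfg$track_max_s)
}

#' Simulate one single-motor trajectory
#'
#' Generates a continuous-time ground-truth path for one behaviour class,
#' samples it at the camera frame interval and corrupts the positions with
#' Gaussian localization noise. Directed motors move at the configured
#' position-dependent speed and switch direction stochastically with the
#' exponential-distance hazard of their current direction; within-run pauses
#' occur as a Poisson process in time with exponential durations. A directed
#' trajectory ends when the motor reaches the ciliary base or tip (the
#' particle leaves the observable pool) or when the observation window ends.
#' Base-diffusive motors perform reflected Brownian motion confined to the
#' base region; stationary motors do not move.
#'
#' @param cfg a [kinetics_config].
#' @param class one of `"anterograde"`, `"retrograde"`, `"base_diffusive"`,
#'   `"stationary"`.
#' @param seed optional RNG seed.
#' @param x0 start position, nm; default drawn uniformly over the class's
#'   natural range.
#' @param duration observation window, s; default drawn from the configured
#'   track-duration distribution.
#' @param id trajectory id.
#' @return an [ift_trajectory]; attributes `class` (generated class),
#'   `truth` (noiseless sampled path) and `events` (exact switch and pause
#'   locations/times) carry the ground truth.
#' @export
simulate_trajectory <- function(cfg, class = "anterograde", seed = NULL,
                                x0 = NULL, duration = NULL, id = 1L) {
  stopifnot(inherits(cfg, "kinetics_config"))
  classes <- c("anterograde", "retrograde", "base_diffusive", "stationary")
  class <- match.arg(class, classes)
  set_seed_if(seed)
  if (is.null(duration)) duration <- track_duration(cfg)

  if (class %in% c("anterograde", "retrograde")) {
    dir0 <- if (class == "anterograde") 1 else -1
    if (is.null(x0)) x0 <- stats::runif(1, 0.02 * cfg$L, 0.98 * cfg$L)
    res <- directed_path(cfg, dir0, x0, duration)
    poly <- res$poly; events <- res$events
  } else if (class == "base_diffusive") {
    if (is.null(x0)) x0 <- stats::runif(1, 0, cfg$base_region)
    tf <- seq(0, duration, by = cfg$dt_frame)
    steps <- stats::rnorm(length(tf) - 1L, 0,
                          sqrt(2 * cfg$D_base * cfg$dt_frame))
    xr <- x0 + cumsum(c(0, steps))
    b <- cfg$base_region
    xm <- xr %% (2 * b)
    poly <- data.frame(t = tf, x = ifelse(xm > b, 2 * b - xm, xm))
    events <- empty_events()
  } else { # stationary
    if (is.null(x0)) x0 <- stats::runif(1, 0, cfg$L)
    tf <- seq(0, duration, by = cfg$dt_frame)
    poly <- data.frame(t = tf, x = rep(x0, length(tf)))
    events <- empty_events()
  }

  t_end <- min(duration, max(poly$t))
  tf <- seq(0, t_end, by = cfg$dt_frame)
  if (length(tf) < 2L) tf <- c(0, cfg$dt_frame)
  x_true <- stats::approx(poly$t, poly$x, xout = tf, rule = 2)$y
  events <- events[events$t_s <= t_end + 1e-9, , drop = FALSE]
  x_obs <- x_true + stats::rnorm(length(tf), 0, cfg$sigma_loc)
  y_obs <- stats::rnorm(length(tf), 0, cfg$sigma_loc)
  tr <- ift_trajectory(tf, x_obs, y_obs, id = id, dt_frame = cfg$dt_frame,
                       events = events)
  attr(tr, "class_true") <- class
  attr(tr, "truth") <- data.frame(t = tf, x = x_true)
  tr
}

empty_events <- function() {
  data.frame(event = character(0), t_s = numeric(0), x_nm = numeric(0),
             stringsAsFactors = FALSE)
}

# continuous-time directed path with hazards, pauses and absorbing boundaries;
# returns a fine (t, x) polyline and the exact event log
directed_path <- function(cfg, dir, x0, duration) {
  t_cur <- 0; x_cur <- x0
  pts_t <- 0; pts_x <- x0  # start point
  ev <- list()
  repeat {
    P_nm <- (if (dir > 0) cfg$P_AR else cfg$P_RA) / 1000
    d_turn <- if (P_nm > 0) stats::rexp(1, P_nm) else Inf
    d_bnd <- if (dir > 0) cfg$L - x_cur else x_cur
    d_run <- min(d_turn, d_bnd)
    tab <- if (dir > 0) cfg$tab_a else cfg$tab_r
    x_tgt <- x_cur + dir * d_run
    move_t <- travel_time(tab, x_cur, x_tgt)
    n_pause <- stats::rpois(1, cfg$pause_rate * move_t)
    pause_at <- sort(stats::runif(n_pause, 0, d_run))
    pause_dur <- stats::rexp(max(n_pause, 0), 1 / cfg$pause_mean)
    bounds <- c(0, pause_at, d_run)
    for (k in seq_len(length(bounds) - 1L)) {
      seg_d <- bounds[k + 1L] - bounds[k]
      if (seg_d > 0) {
        n_s <- max(2L, ceiling(seg_d / 50))
        xs <- seq(x_cur, x_cur + dir * seg_d, length.out = n_s)
        ts <- t_cur + travel_time(tab, x_cur, xs)
        pts_t <- c(pts_t, ts[-1]); pts_x <- c(pts_x, xs[-1])
        t_cur <- ts[n_s]; x_cur <- xs[n_s]
      }
      if (k <= n_pause) {
        ev[[length(ev) + 1L]] <- data.frame(
          event = c("pause_start", "pause_end"),
          t_s = c(t_cur, t_cur + pause_dur[k]), x_nm = x_cur)
        t_cur <- t_cur + pause_dur[k]
        pts_t <- c(pts_t, t_cur); pts_x <- c(pts_x, x_cur)
      }
      if (t_cur >= duration) break
    }
    if (t_cur >= duration) break
    if (d_run == d_bnd) break  # reached base or tip: track ends
    ev[[length(ev) + 1L]] <- data.frame(
      event = if (dir > 0) "turn_AR" else "turn_RA",
      t_s = t_cur, x_nm = x_cur)
    if (cfg$turn_pause_mean > 0) {
      dp <- stats::rexp(1, 1 / cfg$turn_pause_mean)
      t_cur <- t_cur + dp
      pts_t <- c(pts_t, t_cur); pts_x <- c(pts_x, x_cur)
      if (t_cur >= duration) break
    }
    dir <- -dir
  }
  events <- if (length(ev)) do.call(rbind, ev) else empty_events()
  list(poly = data.frame(t = pts_t, x = pts_x), events = events)
}

#' Simulate a mixture of single-motor trajectories
#'
#' Draws behaviour classes from `cfg$class_fractions` and simulates each
#' trajectory independently. The generated (not observed) class labels are
#' attached as attribute `classes`.
#'
#' @param cfg a [kinetics_config].
#' @param n number of trajectories.
#' @param seed optional RNG seed.
#' @return list of [ift_trajectory] objects.
#' @export
simulate_mixture <- function(cfg, n, seed = NULL) {
  set_seed_if(seed)
  cls <- sample(names(cfg$class_fractions), n, replace = TRUE,
                prob = cfg$class_fractions)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- simulate_trajectory(cfg, cls[i], id = i)
  attr(out, "classes") <- cls
  out
}

#' Simulate IFT train paths departing base and tip
#'
#' Trains depart the base (anterograde) and tip (retrograde) as Poisson
#' processes at the configured frequencies and transit the full cilium at the
#' position-dependent train speed; every motor of one train shares the train's
#' path, so a train is represented by a single path weighted by its motor
#' count. Default motor numbers emulate large anterograde trains (40--50
#' motors) and smaller, more frequent retrograde trains (20--30 motors,
#' departure frequency 1.6x the anterograde one).
#'
#' @param cfg a [kinetics_config].
#' @param duration movie duration, s.
#' @param freq_antero,freq_retro train departure frequencies, per s.
#' @param motors_antero,motors_retro integer vectors to draw per-train motor
#'   counts from.
#' @param n_antero,n_retro optional fixed train counts (override the Poisson
#'   draws; departures then uniform over the movie).
#' @param seed optional RNG seed.
#' @return list of train paths ([ift_trajectory] objects with attributes
#'   `n_motors`, `weight` and `direction`).
#' @export
simulate_train_set <- function(cfg, duration = 30,
                               freq_antero = 0.75, freq_retro = 1.2,
                               motors_antero = 40:50, motors_retro = 20:30,
                               n_antero = NULL, n_retro = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "kinetics_config"), duration > 0)
  if (!length(motors_antero) || !length(motors_retro))
    stop("motors-per-train distribution must be non-empty")
  set_seed_if(seed)
  na <- if (is.null(n_antero)) stats::rpois(1, freq_antero * duration) else n_antero
  nr <- if (is.null(n_retro)) stats::rpois(1, freq_retro * duration) else n_retro
  dep_a <- sort(stats::runif(na, 0, duration))
  dep_r <- sort(stats::runif(nr, 0, duration))
  out <- list(); id <- 0L
  mk <- function(t0, dirn) {
    tab <- if (dirn > 0) cfg$tab_a else cfg$tab_r
    transit <- tab$t[length(tab$t)]
    tf <- seq(0, transit, by = cfg$dt_frame)
    # retrograde trains run the same speed table from the tip downwards
    xs <- if (dirn > 0) stats::approx(tab$t, tab$x, tf, rule = 2)$y
          else stats::approx(tab$t, tab$x, transit - tf, rule = 2)$y
    keep <- (tf + t0) <= duration
    if (sum(keep) < 2L) return(NULL)
    ift_trajectory(tf[keep] + t0, xs[keep], id = id, dt_frame = cfg$dt_frame)
  }
  for (t0 in dep_a) {
    id <- id + 1L
    tr <- mk(t0, 1)
    if (is.null(tr)) next
    attr(tr, "n_motors") <- sample(rep(motors_antero, 2), 1)
    attr(tr, "weight") <- attr(tr, "n_motors")
    attr(tr, "direction") <- "anterograde"
    out[[length(out) + 1L]] <- tr
  }
  for (t0 in dep_r) {
    id <- id + 1L
    tr <- mk(t0, -1)
    if (is.null(tr)) next
    attr(tr, "n_motors") <- sample(rep(motors_retro, 2), 1)
    attr(tr, "weight") <- attr(tr, "n_motors")
    attr(tr, "direction") <- "retrograde"
    out[[length(out) + 1L]] <- tr
  }
  out
}

#' Optical model of the rendering stage
#'
#' @param pixel_size camera pixel size, nm.
#' @param psf_sigma Gaussian point-spread-function width, nm.
#' @param photons_per_frame expected photons emitted per motor per frame.
#' @param background_rate expected background photons per pixel per frame.
#' @param bleach_rate photobleaching rate, 1/s (single exponential).
#' @param bleedthrough_alpha fraction of channel-1 signal leaking into
#'   channel 2.
#' @param shot_noise apply Poisson photon noise.
#' @param seed optional RNG seed.
#' @export
optics_config <- function(pixel_size = 100, psf_sigma = 150,
                          photons_per_frame = 200, background_rate = 5,
                          bleach_rate = 0, bleedthrough_alpha = 0,
                          shot_noise = TRUE, seed = NULL) {
  stopifnot(pixel_size > 0, psf_sigma >= 0, photons_per_frame >= 0,
            background_rate >= 0, bleach_rate >= 0,
            bleedthrough_alpha >= 0, bleedthrough_alpha < 1)
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 photons_per_frame = photons_per_frame,
                 background_rate = background_rate,
                 bleach_rate = bleach_rate,
                 bleedthrough_alpha = bleedthrough_alpha,
                 shot_noise = shot_noise, seed = seed),
            class = "optics_config")
}

# expected (noise-free, background-free) kymograph signal of a trajectory set
expected_kymo_signal <- function(trajectories, optics, duration, L, dt_frame) {
  nx <- ceiling(L / optics$pixel_size)
  nt <- max(2L, floor(duration / dt_frame + 1e-9))
  centers <- (seq_len(nx) - 0.5) * optics$pixel_size
  E <- matrix(0, nt, nx)
  for (tr in trajectories) {
    w <- attr(tr, "weight"); if (is.null(w)) w <- 1
    rows <- round(tr$t / dt_frame) + 1L
    keep <- rows >= 1L & rows <= nt
    if (!any(keep)) next
    amp <- w * optics$photons_per_frame *
      exp(-optics$bleach_rate * tr$t[keep]) * optics$pixel_size
    prof <- amp * exp(-outer(tr$x[keep], centers, "-")^2 /
                        (2 * optics$psf_sigma^2)) /
      (optics$psf_sigma * sqrt(2 * pi))
    agg <- rowsum(prof, rows[keep])
    E[as.integer(rownames(agg)), ] <- E[as.integer(rownames(agg)), ] + agg
  }
  E
}

#' Render kymographs from trajectories
#'
#' Produces the raw kymograph (time x axial position) a microscope would
#' record from a set of emitting motors: each frame row is the sum of the
#' Gaussian line-spread contributions of all motors, attenuated by
#' single-exponential photobleaching, plus uniform background, with optional
#' Poisson shot noise. When a second trajectory set is given, a two-channel
#' pair is rendered and a fraction `bleedthrough_alpha` of the channel-1
#' signal leaks into channel 2.
#'
#' @param trajectories channel-1 trajectory list (an attribute `weight`
#'   multiplies a trajectory's brightness, e.g. motors per train).
#' @param optics an [optics_config].
#' @param duration movie duration, s.
#' @param L axial extent, nm.
#' @param dt_frame frame interval, s; defaults to the trajectories' interval.
#' @param ch2_trajectories optional channel-2 trajectory list.
#' @return a [kymograph], or a list `ch1`, `ch2` of kymographs.
#' @export
render_kymograph <- function(trajectories, optics, duration, L,
                             dt_frame = NULL, ch2_trajectories = NULL) {
  if (!length(trajectories)) stop("empty trajectory list")
  if (is.null(dt_frame)) dt_frame <- attr(trajectories[[1]], "dt_frame")
  set_seed_if(optics$seed)
  E1 <- expected_kymo_signal(trajectories, optics, duration, L, dt_frame)
  finish <- function(E) {
    E <- E + optics$background_rate
    I <- if (optics$shot_noise)
      matrix(stats::rpois(length(E), E), nrow(E)) else E
    kymograph(I, dt_frame, optics$pixel_size)
  }
  if (is.null(ch2_trajectories)) return(finish(E1))
  E2 <- if (length(ch2_trajectories))
    expected_kymo_signal(ch2_trajectories, optics, duration, L, dt_frame)
  else matrix(0, nrow(E1), ncol(E1))
  E2 <- E2 + optics$bleedthrough_alpha * E1
  k1 <- finish(E1); k1$channel <- "ch1"
  k2 <- finish(E2); k2$channel <- "ch2"
  list(ch1 = k1, ch2 = k2)
}

#' Render a 2-D image stack from trajectories
#'
#' Renders time-lapse frames of motors moving along a (possibly curved)
#' ciliary path. Motor axial positions are mapped onto the path spline;
#' lateral offsets displace the emitter along the local normal. Each emitter
#' contributes an integrated 2-D Gaussian PSF; background and Poisson noise
#' as in [render_kymograph].
#'
#' @param trajectories trajectory list.
#' @param optics an [optics_config].
#' @param duration movie duration, s.
#' @param spline an [ift_spline] in pixel coordinates mapping arc length to
#'   image position; default is a straight horizontal path through the
#'   vertical centre.
#' @param ny,nx image size in pixels; `nx` defaults to span `L`.
#' @param L axial extent, nm (used for the default geometry).
#' @param dt_frame frame interval, s.
#' @return numeric array `[ny, nx, nt]` of class `ift_stack` with attributes
#'   `pixel_size` (nm) and `dt_frame` (s).
#' @export
render_image_stack <- function(trajectories, optics, duration, spline = NULL,
                               ny = 15, nx = NULL, L = 9000,
                               dt_frame = NULL) {
  if (!length(trajectories)) stop("empty trajectory list")
  if (is.null(dt_frame)) dt_frame <- attr(trajectories[[1]], "dt_frame")
  if (is.null(nx)) nx <- ceiling(L / optics$pixel_size)
  if (is.null(spline))
    spline <- ciliary_spline(cbind(c(0, nx), c(ny / 2, ny / 2)))
  set_seed_if(optics$seed)
  nt <- max(2L, floor(duration / dt_frame + 1e-9))
  spx <- optics$psf_sigma / optics$pixel_size
  stack <- array(optics$background_rate, dim = c(ny, nx, nt))
  r <- max(2L, ceiling(4 * spx))
  for (tr in trajectories) {
    w <- attr(tr, "weight"); if (is.null(w)) w <- 1
    frames <- round(tr$t / dt_frame) + 1L
    keep <- frames >= 1L & frames <= nt
    if (!any(keep)) next
    sp <- spline_at(spline, tr$x[keep] / optics$pixel_size)
    cx <- sp$x + sp$nx * tr$y[keep] / optics$pixel_size
    cy <- sp$y + sp$ny * tr$y[keep] / optics$pixel_size
    amp <- w * optics$photons_per_frame * exp(-optics$bleach_rate * tr$t[keep])
    fr <- frames[keep]
    for (k in seq_along(fr)) {
      cols <- max(1L, floor(cx[k] - r)):min(nx, ceiling(cx[k] + r))
      rws <- max(1L, floor(cy[k] - r)):min(ny, ceiling(cy[k] + r))
      gx <- stats::dnorm(cols - 0.5, cx[k], spx)
      gy <- stats::dnorm(rws - 0.5, cy[k], spx)
      stack[rws, cols, fr[k]] <- stack[rws, cols, fr[k]] +
        amp[k] * outer(gy, gx)
    }
  }
  if (optics$shot_noise)
    stack <- array(stats::rpois(length(stack), stack), dim = dim(stack))
  structure(stack, pixel_size = optics$pixel_size, dt_frame = dt_frame,
            class = "ift_stack")
}

#' Write / read an image stack as multi-page TIFF
#'
#' Frames are stored as 16-bit pages after scaling by the stack maximum (the
#' scale is not preserved in the file; intensities are relative).
#' @param stack an `ift_stack` array.
#' @param path TIFF file path.
#' @export
write_stack_tiff <- function(stack, path) {
  mx <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param pixel_size,dt_frame metadata to attach on read (TIFF pages carry
#'   none).
#' @export
read_stack_tiff <- function(path, pixel_size = 100, dt_frame = 0.15) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) stack[, , i] <- pages[[i]]
  structure(stack, pixel_size = pixel_size, dt_frame = dt_frame,
            class = "ift_stack")
}
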