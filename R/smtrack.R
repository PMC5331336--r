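# Single-molecule analysis: spot detection and linking, spline projection,
# trajectory classification and event rules.

#' Classification rules for single-molecule trajectories
#'
#' Encodes the event, stationary and turnaround definitions used to classify
#' single-motor trajectories:
#' an *event* is a trajectory at least `min_event_duration` long with a
#' maximum displacement of at least `min_event_displacement`; *stationary*
#' stretches are runs of consecutive interframe displacements below
#' `stationary_step` spanning at least `stationary_frames` frames; a
#' *turnaround* is a local extremum of the axial coordinate with at least
#' `turn_steps` consecutive same-direction steps before and after the turn.
#' Steps smaller than `stationary_step` are sign-neutral: they neither break
#' nor extend a directional run (localization noise would otherwise break
#' genuine runs).
#'
#' @param min_event_duration minimum event duration, s.
#' @param min_event_displacement minimum maximum-displacement, nm.
#' @param stationary_step interframe displacement below which a step counts
#'   as stationary / sign-neutral, nm.
#' @param stationary_frames minimum frames in a stationary stretch.
#' @param turn_steps directional steps required on both sides of a turn.
#' @param dt_frame frame interval, s.
#' @param smooth_window running-mean window (frames) applied to the axial
#'   coordinate before the step-based rules during classification; 1
#'   disables smoothing.
#' @param directionality_min minimum net displacement / path length for the
#'   directed classes.
#' @param stationary_cover minimum fraction of frames one stationary stretch
#'   must cover for the stationary class.
#' @param stationary_max_range maximum range (max - min of the smoothed
#'   axial coordinate, nm) of a stationary trajectory; separates truly
#'   immobile particles from confined diffusion, whose small interframe
#'   steps would otherwise satisfy the stationary rule.
#' @param msd_band log-log MSD slope band (lags 1-5) for the diffusive
#'   class. On sub-second tracks the slope estimate is noisy, so the default
#'   band is wide and chiefly excludes clearly ballistic remnants.
#' @param base_region centroid bound for the base-diffusive class, nm.
#' @param hazard_min_x positions below this (nm) are excluded from
#'   turnaround-hazard statistics (both turn counts and at-risk distance, a
#'   consistent spatial thinning of the hazard process): motors diffusing in
#'   the crowded base region produce apparent short directional excursions
#'   that are not train transport, and excluding the region removes that
#'   contamination symmetrically.
#' @export
class_rules <- function(min_event_duration = 0.600,
                        min_event_displacement = 200,
                        stationary_step = 50,
                        stationary_frames = 4L,
                        turn_steps = 3L,
                        dt_frame = 0.150,
                        smooth_window = 3L,
                        directionality_min = 0.5,
                        stationary_cover = 0.8,
                        stationary_max_range = 100,
                        msd_band = c(-0.5, 1.6),
                        base_region = 1000,
                        hazard_min_x = 1000) {
  stopifnot(min_event_duration > 0, min_event_displacement > 0,
            stationary_step > 0, stationary_frames >= 2L, turn_steps >= 1L,
            dt_frame > 0, smooth_window >= 1L)
  structure(list(min_event_duration = min_event_duration,
                 min_event_displacement = min_event_displacement,
                 stationary_step = stationary_step,
                 stationary_frames = as.integer(stationary_frames),
                 turn_steps = as.integer(turn_steps),
                 dt_frame = dt_frame,
                 smooth_window = as.integer(smooth_window),
                 directionality_min = directionality_min,
                 stationary_cover = stationary_cover,
                 stationary_max_range = stationary_max_range,
                 msd_band = msd_band, base_region = base_region,
                 hazard_min_x = hazard_min_x),
            class = "class_rules")
}

#' Filter trajectories to analysable events
#'
#' Keeps trajectories lasting at least `min_event_duration` whose maximum
#' displacement from the start reaches `min_event_displacement`; everything
#' else is returned in `rejected` with a reason code.
#'
#' @param trajectories list of [ift_trajectory].
#' @param rules a [class_rules].
#' @param require_displacement apply the displacement criterion. The class
#'   census (which must retain stationary and confined-diffusive particles)
#'   uses `FALSE` and filters on duration alone; analyses of directed events
#'   use the default.
#' @return list with `kept`, `rejected` and `reasons`.
#' @export
filter_events <- function(trajectories, rules = class_rules(),
                          require_displacement = TRUE) {
  reasons <- vapply(trajectories, function(tr) {
    dur <- tr$t[nrow(tr)] - tr$t[1]
    if (dur < rules$min_event_duration - 1e-9) return("too_short")
    if (require_displacement &&
        max(abs(tr$x - tr$x[1])) < rules$min_event_displacement)
      return("displacement")
    "kept"
  }, character(1))
  list(kept = trajectories[reasons == "kept"],
       rejected = trajectories[reasons != "kept"],
       reasons = reasons)
}

#' Stationary stretches of an axial trajectory
#'
#' Maximal runs of consecutive interframe displacements below
#' `stationary_step` that span at least `stationary_frames` frames.
#'
#' @param x axial positions (nm) or an [ift_trajectory].
#' @param rules a [class_rules].
#' @return data.frame `start`, `end` (frame indices, 1-based, inclusive),
#'   `n_frames`, `duration_s`.
#' @export
detect_stationary_segments <- function(x, rules = class_rules()) {
  if (is.data.frame(x)) x <- x$x
  small <- abs(diff(x)) < rules$stationary_step
  out <- list()
  r <- rle(small)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    n_frames <- r$lengths[k] + 1L   # steps -> frames
    if (n_frames < rules$stationary_frames) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts[k], end = ends[k] + 1L, n_frames = n_frames,
      duration_s = r$lengths[k] * rules$dt_frame)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      n_frames = integer(0), duration_s = numeric(0)))
  do.call(rbind, out)
}

# signs of interframe steps with sub-threshold steps neutralized to 0
step_signs <- function(x, stationary_step) {
  d <- diff(x)
  s <- sign(d)
  s[abs(d) < stationary_step] <- 0L
  as.integer(s)
}

# maximal directional runs over sign-neutralized steps: a run is a maximal
# stretch of steps with no opposite-sign step, containing >= turn_steps
# signed steps. Returns step-index ranges with direction.
directional_runs <- function(s, turn_steps) {
  n <- length(s)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (s[i] == 0L) { i <- i + 1L; next }
    dir <- s[i]
    j <- i
    while (j < n && s[j + 1L] != -dir) j <- j + 1L
    # trim trailing neutral steps
    jj <- j
    while (jj > i && s[jj] == 0L) jj <- jj - 1L
    if (sum(s[i:jj] == dir) >= turn_steps)
      runs[[length(runs) + 1L]] <- list(from = i, to = jj, dir = dir)
    i <- j + 1L
  }
  runs
}

#' Detect directional switches (turnarounds)
#'
#' A frame hosts a turnaround when at least `turn_steps` consecutive
#' same-direction steps precede it and at least `turn_steps` consecutive
#' opposite-direction steps follow; sub-threshold steps are sign-neutral and
#' do not break either run. The neutral frames between the two runs define
#' the pause duration at the turn; the turn location is the extremum of the
#' axial coordinate between the runs.
#'
#' @param x axial positions (nm) or an [ift_trajectory].
#' @param rules a [class_rules].
#' @return data.frame `frame` (index of the extremum), `t_s`, `x_nm`,
#'   `direction` (`"AR"` anterograde-to-retrograde or `"RA"`),
#'   `pause_s` (neutral time at the turn).
#' @export
detect_turnarounds <- function(x, rules = class_rules()) {
  tvec <- NULL
  if (is.data.frame(x)) { tvec <- x$t; x <- x$x }
  n <- length(x)
  empty <- data.frame(frame = integer(0), t_s = numeric(0), x_nm = numeric(0),
                      direction = character(0), pause_s = numeric(0))
  if (n < 2 * rules$turn_steps + 1) return(empty)
  if (is.null(tvec)) tvec <- (seq_len(n) - 1L) * rules$dt_frame
  s <- step_signs(x, rules$stationary_step)
  runs <- directional_runs(s, rules$turn_steps)
  if (length(runs) < 2L) return(empty)
  out <- list()
  for (k in seq_len(length(runs) - 1L)) {
    a <- runs[[k]]; b <- runs[[k + 1L]]
    if (a$dir == b$dir) next
    # frames between the end of run a and the start of run b
    gap_steps <- (a$to + 1L):(b$from - 1L)
    gap_steps <- gap_steps[gap_steps >= a$to + 1L & gap_steps <= b$from - 1L]
    if (b$from == a$to + 1L) gap_steps <- integer(0)
    pause_s <- length(gap_steps) * rules$dt_frame
    span <- (a$to + 1L):b$from              # candidate extremum frames
    xi <- if (a$dir > 0) span[which.max(x[span])] else span[which.min(x[span])]
    out[[length(out) + 1L]] <- data.frame(
      frame = xi, t_s = tvec[xi], x_nm = x[xi],
      direction = if (a$dir > 0) "AR" else "RA", pause_s = pause_s)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# log-log MSD slope over lags 1..max_lag
msd_slope <- function(x, dt, max_lag = 5L) {
  n <- length(x)
  lags <- seq_len(min(max_lag, n - 2L))
  if (length(lags) < 2L) return(NA_real_)
  msd <- vapply(lags, function(k) mean((x[(k + 1):n] - x[1:(n - k)])^2),
                numeric(1))
  if (any(msd <= 0)) return(NA_real_)
  stats::coef(stats::lm.fit(cbind(1, log(lags * dt)), log(msd)))[2]
}

#' Classify a single-molecule trajectory
#'
#' Applies the behaviour taxonomy in priority order: any detected turnaround
#' makes the trajectory a `turnaround`; otherwise a trajectory whose net
#' displacement is at least `directionality_min` of its path length is
#' `anterograde` or `retrograde` by the sign of the net displacement (with
#' contained stationary stretches recorded as pauses); otherwise a single
#' stationary stretch covering `stationary_cover` of the frames makes it
#' `stationary`; otherwise a non-directed trajectory with a diffusive MSD
#' exponent whose centroid lies in the base region is `base_diffusive`;
#' anything else is `rejected`. Turnaround detection, directional runs and
#' the directionality ratio operate on the raw coordinate (the sign-neutral
#' step rule absorbs localization noise there); stationary and pause
#' detection, whose 50 nm criterion would be broken by 40 nm localization
#' noise, run on a `smooth_window`-frame running mean. The MSD slope uses
#' the raw coordinate.
#'
#' @param trajectory an [ift_trajectory] (after event filtering).
#' @param rules a [class_rules].
#' @return list of class `ift_classified`: `class`, `trajectory`, `turns`
#'   (data.frame as [detect_turnarounds]), `pauses` (stationary stretches
#'   within directed trajectories), `d_antero`, `d_retro` (at-risk distance
#'   per direction, nm; see Details) and `d_antero_obs`, `d_retro_obs`
#'   (uncensored run distances).
#'
#' @details The per-direction distances are computed from the maximal
#' directional runs of the (smoothed) trajectory. Because a turnaround can
#' only be detected if `turn_steps` frames follow it, distance travelled in
#' the final `turn_steps` frames of a track is excluded from the at-risk
#' distances `d_antero` / `d_retro`; using the at-risk distance as the
#' denominator makes the hazard estimator the standard censored-exponential
#' maximum-likelihood estimator.
#' @export
classify_trajectory <- function(trajectory, rules = class_rules()) {
  x <- trajectory$x
  n <- length(x)
  x_sm <- moving_mean(x, rules$smooth_window)
  turns <- detect_turnarounds(
    data.frame(t = trajectory$t, x = x), rules)
  stat <- detect_stationary_segments(x_sm, rules)
  s <- step_signs(x, rules$stationary_step)
  runs <- directional_runs(s, rules$turn_steps)
  dists <- run_distances(x, s, runs, n, rules$turn_steps,
                         xmin = rules$hazard_min_x,
                         neutral = rules$stationary_step)

  path_len <- sum(abs(diff(x)))
  net <- x[n] - x[1]
  cls <- NULL
  if (nrow(turns) > 0) {
    cls <- "turnaround"
  } else if (path_len > 0 && abs(net) / path_len >= rules$directionality_min &&
             abs(net) >= rules$min_event_displacement) {
    cls <- if (net > 0) "anterograde" else "retrograde"
  } else if (nrow(stat) > 0 &&
             max(stat$n_frames) >= rules$stationary_cover * n &&
             diff(range(x_sm)) <= rules$stationary_max_range) {
    cls <- "stationary"
  } else {
    slope <- msd_slope(x, attr(trajectory, "dt_frame"))
    centroid <- mean(x)
    if (!is.na(slope) && slope >= rules$msd_band[1] &&
        slope <= rules$msd_band[2] && centroid <= rules$base_region &&
        (path_len == 0 || abs(net) / path_len < rules$directionality_min)) {
      cls <- "base_diffusive"
    } else cls <- "rejected"
  }
  pauses <- if (cls %in% c("anterograde", "retrograde", "turnaround"))
    stat else stat[0, ]
  structure(list(class = cls, trajectory = trajectory, turns = turns,
                 pauses = pauses,
                 d_antero = dists$ar[1], d_retro = dists$ar[2],
                 d_antero_obs = dists$obs[1], d_retro_obs = dists$obs[2]),
            class = "ift_classified")
}

# Observed and at-risk distances per direction from directional runs.
#
# A turnaround is only detectable if `turn_steps` signed steps precede it and
# `turn_steps` steps follow before the track ends. The at-risk distance of a
# run therefore excludes (a) the distance covered by the run's first
# `turn_steps` signed steps (left truncation: a turn earlier in the run would
# not have produced this run structure) and (b) anything in the final
# `turn_steps` frames of the track (right censoring: no room for the
# post-turn run). With an exponential-distance hazard both corrections are
# exact by memorylessness, making N / D_at_risk the censored-exponential
# maximum-likelihood estimator.
#
# Edge sub-steps: the detector works on whole camera steps, but a turn
# occurring *inside* a boundary step is still caught when the step's
# apparent sign cooperates. When a run ends in a detected turn the motor
# covered on average half a step of additional at-risk distance inside the
# turn step; at the truncation start and at a track-end censor the
# detectable window similarly reaches a fraction of a step beyond the frame
# positions (a quarter step once the sign-neutral band is accounted for).
# These fractions matter because the at-risk windows of frame-limited
# tracks are only a few steps long.
run_distances <- function(x, s, runs, n, turn_steps, xmin = 0,
                          neutral = 50) {
  obs <- c(0, 0); ar <- c(0, 0)
  last_ok <- n - turn_steps            # last frame index fully at risk
  for (ri in seq_along(runs)) {
    r <- runs[[ri]]
    i0 <- r$from; i1 <- r$to + 1L      # frame range of the run
    k <- if (r$dir > 0) 1L else 2L
    obs[k] <- obs[k] + abs(x[i1] - x[i0])
    sig <- which(s[r$from:r$to] == r$dir) + r$from - 1L  # signed step indices
    if (length(sig) < turn_steps) next
    j_lo <- sig[turn_steps] + 1L       # frame after the turn_steps-th step
    j_hi <- min(i1, last_ok)
    if (j_hi < j_lo) next
    head_sig <- sig[seq_len(turn_steps)]
    step_lo <- mean(abs(x[head_sig + 1L] - x[head_sig]))
    tail_sig <- sig[max(1L, length(sig) - turn_steps + 1L):length(sig)]
    step_hi <- mean(abs(x[tail_sig + 1L] - x[tail_sig]))
    ends_in_turn <- ri < length(runs) && runs[[ri + 1L]]$dir == -r$dir
    censored <- !ends_in_turn && i1 >= last_ok
    # a turn inside the boundary camera step is still detected while the
    # step's apparent sign stays within the neutral band
    edge_lo <- max(0, (step_lo - neutral) / 2)
    edge_hi <- max(0, (step_hi - neutral) / 2)
    lo_pos <- x[j_lo] - r$dir * edge_lo
    hi_pos <- x[j_hi] +
      r$dir * (if (ends_in_turn && x[i1] >= xmin) 0.5 * step_hi
               else if (censored) edge_hi else 0)
    span <- sort(c(lo_pos, hi_pos))
    ar[k] <- ar[k] + max(0, span[2] - max(span[1], xmin))
  }
  list(obs = obs, ar = ar)
}

#' Classify a set of trajectories
#'
#' @param trajectories list of [ift_trajectory] (after [filter_events]).
#' @param rules a [class_rules].
#' @return object of class `ift_classification`: a list of `ift_classified`
#'   with a summary `table` attribute.
#' @export
classify_trajectories <- function(trajectories, rules = class_rules()) {
  out <- lapply(trajectories, classify_trajectory, rules = rules)
  cls <- vapply(out, function(z) z$class, character(1))
  attr(out, "classes") <- cls
  attr(out, "hazard_min_x") <- rules$hazard_min_x
  class(out) <- "ift_classification"
  out
}

#' @export
print.ift_classification <- function(x, ...) {
  tab <- table(attr(x, "classes"))
  cat("single-molecule classification of", length(x), "trajectories\n")
  sh <- class_shares(tab)
  for (nm in names(sh))
    cat(sprintf("  %-14s %4d  (%.0f%%)\n", nm, tab[[nm]], sh[[nm]]))
  invisible(x)
}

#' Class shares in percent from a count table
#'
#' @param counts named numeric vector or table of per-class counts.
#' @param digits rounding of the returned percentages; `NA` for unrounded.
#' @return named vector of percentages of the total.
#' @export
class_shares <- function(counts, digits = 0) {
  p <- 100 * as.numeric(counts) / sum(counts)
  if (!is.na(digits)) p <- round(p, digits)
  names(p) <- names(counts)
  p
}

#' Summary pause statistics of a classified set
#'
#' @param classified an `ift_classification`.
#' @return list: `n_pauses`, `mean_s`, `sd_s`, `max_s`, `durations_s`,
#'   `frac_pausing` (named, per directed class: fraction of trajectories of
#'   that class containing at least one pause) and `turn_pauses_s` (pause
#'   durations at turnarounds).
#' @export
pause_statistics <- function(classified) {
  dur <- numeric(0)
  frac <- c(anterograde = NA_real_, retrograde = NA_real_)
  for (cl in c("anterograde", "retrograde")) {
    sel <- Filter(function(z) z$class == cl, classified)
    if (length(sel)) {
      has <- vapply(sel, function(z) nrow(z$pauses) > 0, logical(1))
      frac[cl] <- mean(has)
    }
  }
  for (z in classified)
    if (z$class %in% c("anterograde", "retrograde", "turnaround"))
      dur <- c(dur, z$pauses$duration_s)
  turn_pauses <- unlist(lapply(classified, function(z) z$turns$pause_s))
  list(n_pauses = length(dur),
       mean_s = if (length(dur)) mean(dur) else NA_real_,
       sd_s = if (length(dur) > 1) stats::sd(dur) else NA_real_,
       max_s = if (length(dur)) max(dur) else NA_real_,
       durations_s = dur,
       frac_pausing = frac,
       turn_pauses_s = if (is.null(turn_pauses)) numeric(0) else turn_pauses)
}

#' Detect and link single-molecule spots in an image stack
#'
#' Per-frame spot detection (difference-of-Gaussians band-pass, local maxima
#' above a robust threshold, Gaussian-weighted centroid refinement) followed
#' by nearest-neighbour frame-to-frame linking with a maximum step and
#' one-frame gap closing.
#'
#' @param stack image array `[ny, nx, nt]` with `pixel_size` (nm) and
#'   `dt_frame` (s) attributes.
#' @param psf_sigma_px expected spot width, pixels.
#' @param threshold_k detection threshold in MADs above the median of the
#'   band-passed frame.
#' @param max_step_nm maximum frame-to-frame displacement, nm.
#' @param gap frames a trajectory may skip (gap closing).
#' @param min_frames discard shorter trajectories.
#' @return list of [ift_trajectory] in image coordinates: `x` = column
#'   position (nm), `y` = row position (nm).
#' @export
detect_and_link <- function(stack, psf_sigma_px = 1.5, threshold_k = 5,
                            max_step_nm = 600, gap = 1L, min_frames = 3L) {
  px <- attr(stack, "pixel_size"); dt <- attr(stack, "dt_frame")
  nt <- dim(stack)[3]
  if (nt < 2L) stop("stack needs at least 2 frames")
  open <- list(); done <- list()
  for (f in seq_len(nt)) {
    fr <- stack[, , f]
    bp <- gauss_smooth_mat(fr, psf_sigma_px) -
      gauss_smooth_mat(fr, 2.5 * psf_sigma_px)
    # absolute floor guards against numerically flat frames
    thr <- max(stats::median(bp) + threshold_k * stats::mad(bp),
               1e-6 * max(abs(fr)))
    cand <- which(bp > thr, arr.ind = TRUE)
    # strict local maxima in a 3x3 neighbourhood
    keep <- logical(nrow(cand))
    ny <- nrow(fr); nx <- ncol(fr)
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      rr <- max(1, r - 1):min(ny, r + 1); cc <- max(1, c - 1):min(nx, c + 1)
      keep[i] <- bp[r, c] >= max(bp[rr, cc])
    }
    cand <- cand[keep, , drop = FALSE]
    pos <- matrix(numeric(0), 0, 2)
    if (nrow(cand)) {
      rc_rad <- max(2L, ceiling(2.5 * psf_sigma_px))
      pos <- t(apply(cand, 1, function(rc) {
        r <- rc[1]; c <- rc[2]
        rr <- max(1, r - rc_rad):min(ny, r + rc_rad)
        cc <- max(1, c - rc_rad):min(nx, c + rc_rad)
        w <- pmax(bp[rr, cc], 0)   # band-passed image is background-free
        if (sum(w) == 0) return(c(r, c))
        c(sum(rr * rowSums(w)) / sum(w), sum(cc * colSums(w)) / sum(w))
      }))
    }
    used <- rep(FALSE, nrow(pos))
    if (length(open) && nrow(pos)) {
      lastp <- t(vapply(open, function(o) o$last, numeric(2)))
      D <- outer(seq_len(nrow(lastp)), seq_len(nrow(pos)), Vectorize(
        function(i, j) sqrt(sum((lastp[i, ] - pos[j, ])^2)) * px))
      repeat {
        if (!any(is.finite(D)) || min(D) > max_step_nm) break
        ij <- arrayInd(which.min(D), dim(D))
        i <- ij[1]; j <- ij[2]
        o <- open[[i]]
        o$frames <- c(o$frames, f); o$rows <- c(o$rows, pos[j, 1])
        o$cols <- c(o$cols, pos[j, 2]); o$last <- pos[j, ]
        o$last_frame <- f
        open[[i]] <- o
        used[j] <- TRUE
        D[i, ] <- Inf; D[, j] <- Inf
      }
    }
    if (length(open)) {
      stale <- vapply(open, function(o) f - o$last_frame > gap + 1L,
                      logical(1))
      done <- c(done, open[stale])
      open <- open[!stale]
    }
    for (j in seq_len(nrow(pos))) if (!used[j])
      open[[length(open) + 1L]] <- list(frames = f, rows = pos[j, 1],
                                        cols = pos[j, 2], last = pos[j, ],
                                        last_frame = f)
  }
  done <- c(done, open)
  out <- list(); id <- 0L
  for (o in done) {
    if (length(o$frames) < min_frames) next
    id <- id + 1L
    out[[id]] <- ift_trajectory((o$frames - 1) * dt,
                                (o$cols - 0.5) * px,
                                (o$rows - 0.5) * px,
                                id = id, dt_frame = dt)
  }
  out
}

#' Project an image-coordinate trajectory onto the ciliary spline
#'
#' Converts a trajectory tracked in image coordinates into axial/lateral
#' cilium coordinates: `x` becomes the arc length of the nearest spline
#' point, `y` the signed perpendicular offset. Points farther from the path
#' than `tube_radius` are flagged.
#'
#' @param trajectory [ift_trajectory] with `x`, `y` in nm image coordinates.
#' @param spline an [ift_spline] in pixel coordinates.
#' @param pixel_size nm per pixel (to scale the spline to nm).
#' @param tube_radius flag distance, nm.
#' @return [ift_trajectory] in axial coordinates, attribute `flagged` marks
#'   out-of-tube points.
#' @export
project_onto_spline <- function(trajectory, spline, pixel_size = 100,
                                tube_radius = 500) {
  pr <- spline_project(spline, trajectory$x / pixel_size,
                       trajectory$y / pixel_size)
  out <- ift_trajectory(trajectory$t, pr$s * pixel_size,
                        pr$offset * pixel_size,
                        id = attr(trajectory, "id"),
                        dt_frame = attr(trajectory, "dt_frame"),
                        events = attr(trajectory, "events"))
  attr(out, "flagged") <- abs(pr$offset * pixel_size) > tube_radius
  out
}
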