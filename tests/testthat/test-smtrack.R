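# Single-molecule rules: event filter, stationary/turnaround detection,
# classification, hazard and pause statistics, detection/linking, projection.

test_that("event filter applies the duration and displacement thresholds", {
  rules <- class_rules()
  mk <- function(n, dx) ift_trajectory((0:(n - 1)) * 0.15,
                                       cumsum(c(0, rep(dx, n - 1))))
  f <- filter_events(list(mk(5, 75), mk(3, 200), mk(10, 15)), rules)
  expect_equal(unname(f$reasons), c("kept", "too_short", "displacement"))
  expect_length(f$kept, 1)
  # duration-only mode keeps the small-displacement track
  f2 <- filter_events(list(mk(10, 15)), rules, require_displacement = FALSE)
  expect_equal(unname(f2$reasons), "kept")
})

test_that("stationary segments follow the interframe-displacement rule", {
  rules <- class_rules()
  s0 <- detect_stationary_segments(rep(100, 10), rules)
  expect_equal(nrow(s0), 1)
  expect_equal(s0$n_frames, 10)
  expect_equal(nrow(detect_stationary_segments(cumsum(rep(60, 8)), rules)), 0)
  # steps [10,10,10,80,10,10,10]: two 4-frame candidate runs
  x <- cumsum(c(0, 10, 10, 10, 80, 10, 10, 10))
  s2 <- detect_stationary_segments(x, rules)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$n_frames, c(4, 4))
  expect_equal(s2$duration_s, c(0.45, 0.45))
})

test_that("turnaround detection finds the constructed extremum with its pause", {
  rules <- class_rules()
  tu <- detect_turnarounds(c(0, 200, 400, 600, 400, 200, 0), rules)
  expect_equal(nrow(tu), 1)
  expect_equal(tu$direction, "AR")
  expect_equal(tu$x_nm, 600)
  expect_equal(tu$pause_s, 0)
  expect_equal(nrow(detect_turnarounds(seq(0, 1800, by = 200), rules)), 0)
  # ramp up 4 steps, 3 stationary frames, ramp down 4 steps: pause 450 ms
  x <- c(seq(0, 800, by = 200), 800, 800, 800, seq(600, 0, by = -200))
  tp <- detect_turnarounds(x, rules)
  expect_equal(nrow(tp), 1)
  expect_equal(tp$direction, "AR")
  expect_equal(tp$pause_s, 0.45)
  # retrograde-to-anterograde version
  tr <- detect_turnarounds(2000 - c(0, 200, 400, 600, 400, 200, 0), rules)
  expect_equal(tr$direction, "RA")
})

test_that("mirroring a trajectory swaps turnaround directions", {
  cfg <- kinetics_config()
  set.seed(50)
  rules <- class_rules()
  checked <- 0
  for (i in 1:60) {
    tr <- simulate_trajectory(cfg, sample(c("anterograde", "retrograde"), 1))
    tu <- detect_turnarounds(tr$x, rules)
    tm <- detect_turnarounds(cfg$L - tr$x, rules)
    expect_equal(nrow(tu), nrow(tm))
    if (nrow(tu)) {
      checked <- checked + 1
      expect_equal(tm$direction,
                   ifelse(tu$direction == "AR", "RA", "AR"))
      expect_equal(tm$x_nm, cfg$L - tu$x_nm)
    }
  }
  expect_gt(checked, 0)
})

test_that("classification is deterministic and respects time reversal", {
  cfg <- kinetics_config()
  rules <- class_rules()
  tr <- simulate_trajectory(cfg, "anterograde", seed = 51, duration = 2)
  z1 <- classify_trajectory(tr, rules)
  z2 <- classify_trajectory(tr, rules)
  expect_identical(z1$class, z2$class)
  expect_identical(z1$turns, z2$turns)
  # time reversal swaps the directed labels
  rev_tr <- ift_trajectory(tr$t, rev(tr$x), rev(tr$y),
                           dt_frame = attr(tr, "dt_frame"))
  zr <- classify_trajectory(rev_tr, rules)
  if (z1$class %in% c("anterograde", "retrograde")) {
    expect_equal(zr$class,
                 c(anterograde = "retrograde",
                   retrograde = "anterograde")[[z1$class]])
  }
})

test_that("constructed and generated trajectories get the expected classes", {
  rules <- class_rules()
  # clean directed run
  up <- ift_trajectory((0:9) * 0.15, seq(2000, 2000 + 9 * 255, by = 255))
  expect_equal(classify_trajectory(up, rules)$class, "anterograde")
  # constructed switch: up 10 steps, down 10 steps
  x <- c(seq(2000, 4550, by = 255), seq(4295, 2000, by = -255))
  sw <- ift_trajectory(seq_along(x) * 0.15, x)
  zs <- classify_trajectory(sw, rules)
  expect_equal(zs$class, "turnaround")
  expect_equal(nrow(zs$turns), 1)
  expect_equal(zs$turns$direction, "AR")
  # generated anterograde motors without true turns are labelled anterograde
  cfg <- kinetics_config()
  set.seed(52)
  hits <- 0; total <- 0
  for (i in 1:40) {
    tr <- simulate_trajectory(cfg, "anterograde", duration = 1.5)
    if (nrow(traj_events(tr)[traj_events(tr)$event %in%
                             c("turn_AR", "turn_RA"), ])) next
    total <- total + 1
    hits <- hits + (classify_trajectory(tr, rules)$class == "anterograde")
  }
  expect_gt(hits / total, 0.8)
  # generated motor with one mid-cilium switch: turnaround with an AR event
  set.seed(53)
  found <- FALSE
  for (i in 1:200) {
    tr <- simulate_trajectory(cfg, "anterograde", x0 = 3000, duration = 3)
    ev <- traj_events(tr)
    ar <- ev[ev$event == "turn_AR", ]
    if (nrow(ar) != 1 || nrow(ev[ev$event == "turn_RA", ]) > 0) next
    if (ar$t_s < 0.7 || ar$t_s > tr$t[nrow(tr)] - 0.7) next
    z <- classify_trajectory(tr, rules)
    expect_equal(z$class, "turnaround")
    expect_gte(sum(z$turns$direction == "AR"), 1)
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("turnaround statistics reproduce the count arithmetic", {
  fit <- turnaround_from_counts(34, 242.9, 4, 57.1, L = 9)
  expect_equal(fit$P_AR, 34 / 242.9)
  expect_equal(round(fit$P_AR, 3), 0.14)
  expect_equal(fit$se_AR, sqrt(34) / 242.9)
  expect_equal(round(fit$se_AR, 2), 0.02)
  expect_equal(coef(fit), c(P_AR = 34 / 242.9, P_RA = 4 / 57.1))
  ci <- confint(fit)
  expect_true(ci[1, 1] < fit$P_AR & fit$P_AR < ci[1, 2])
  s <- summary(fit)
  expect_equal(s$run_length_antero, 242.9 / 34)
  expect_equal(s$reach_tip, exp(-9 * 34 / 242.9))
  # delta-method errors
  expect_equal(s$run_length_antero_se, fit$se_AR / fit$P_AR^2)
  expect_equal(s$reach_tip_se, 9 * exp(-9 * fit$P_AR) * fit$se_AR)
  # zero turns: zero hazard, certain reach, infinite run length
  f0 <- turnaround_from_counts(0, 50, 0, 50)
  expect_equal(f0$P_AR, 0)
  expect_equal(summary(f0)$reach_tip, 1)
  expect_equal(summary(f0)$run_length_antero, Inf)
  expect_error(turnaround_from_counts(1, 0, 1, 10), "positive")
})

test_that("hazard estimates are consistent with the generator across rates", {
  rules <- class_rules()
  # at the observed hazard scale the estimator is consistent within
  # counting error; at twice that scale runs approach the detector's
  # three-step resolution and a small (~10-15%) shrinkage appears, so the
  # high-rate combination carries a relative allowance on top of the
  # counting error
  for (pq in list(c(0.05, 0.05), c(0.14, 0.07), c(0.3, 0.14))) {
    cfg <- kinetics_config(P_AR = pq[1], P_RA = pq[2])
    set.seed(54 + round(100 * pq[1]))
    trajs <- simulate_mixture(cfg, 400)
    kept <- filter_events(trajs, rules, require_displacement = FALSE)$kept
    fit <- turnaround_statistics(classify_trajectories(kept, rules))
    bias_allow <- if (max(pq) >= 0.3) 0.15 * pq else c(0, 0)
    expect_lt(abs(fit$P_AR - pq[1]),
              bias_allow[1] + 2.5 * max(fit$se_AR, 0.02))
    expect_lt(abs(fit$P_RA - pq[2]),
              bias_allow[2] + 2.5 * max(fit$se_RA, 0.02))
  }
})

test_that("pause statistics summarize detected pauses and recover the generator mean", {
  rules <- class_rules()
  # constructed: directed run interrupted by a six-frame plateau
  x <- c(seq(0, 1020, by = 255), rep(1030, 6), seq(1285, 2305, by = 255))
  tr <- ift_trajectory(seq_along(x) * 0.15, x, dt_frame = 0.15)
  cl <- classify_trajectories(list(tr), rules)
  ps <- pause_statistics(cl)
  expect_equal(ps$n_pauses, 1)
  expect_gt(ps$mean_s, 0.3); expect_lt(ps$mean_s, 1.0)
  # pause-free set
  x2 <- seq(0, 2550, by = 255)
  cl2 <- classify_trajectories(list(ift_trajectory(seq_along(x2) * 0.15, x2)),
                               rules)
  expect_equal(pause_statistics(cl2)$n_pauses, 0)
  expect_equal(unname(pause_statistics(cl2)$frac_pausing["anterograde"]), 0)
  # generator recovery: detected pause durations vs ground truth above the
  # detection floor (stationary rule needs >= 4 frames)
  cfg <- kinetics_config(pause_rate = 0.4, pause_mean = 0.7,
                         track_mean_s = 2)
  set.seed(55)
  true_d <- c()
  cls <- list()
  for (i in 1:500) {
    tr <- simulate_trajectory(cfg, "anterograde")
    ev <- traj_events(tr)
    st <- ev$t_s[ev$event == "pause_start"]
    en <- ev$t_s[ev$event == "pause_end"]
    m <- min(length(st), length(en))
    true_d <- c(true_d, en[seq_len(m)] - st[seq_len(m)])
    cls[[length(cls) + 1]] <- tr
  }
  ps3 <- pause_statistics(classify_trajectories(cls, rules))
  floor_s <- (rules$stationary_frames - 1) * rules$dt_frame
  truth_mean <- mean(true_d[true_d >= floor_s])
  expect_gt(ps3$n_pauses, 50)
  expect_lt(abs(ps3$mean_s - truth_mean) / truth_mean, 0.15)
})

test_that("spline projection recovers arc length and lateral offset", {
  # straight spline along the image x-axis: identity on x
  sp <- ciliary_spline(cbind(c(0, 100), c(10, 10)))
  tr <- ift_trajectory((0:4) * 0.15, c(0, 1000, 2000, 3000, 4000),
                       rep(1000, 5))
  pr <- project_onto_spline(tr, sp, pixel_size = 100)
  expect_equal(pr$x, tr$x, tolerance = 1e-6)
  # a point on the spline has zero lateral offset
  tr0 <- ift_trajectory(c(0, 0.15), c(500, 600), c(1000, 1000))
  pr0 <- project_onto_spline(tr0, sp, pixel_size = 100)
  expect_lt(max(abs(pr0$y)), 1e-6)
  # quarter circle: arc length within 1%
  th <- seq(0, pi / 2, length.out = 40)
  R <- 50
  qc <- ciliary_spline(cbind(R * cos(th), R * sin(th) + 1), step = 0.1)
  th_pts <- c(0.3, 0.8, 1.2)
  trq <- ift_trajectory(seq_along(th_pts) * 0.15,
                        R * cos(th_pts) * 100,
                        (R * sin(th_pts) + 1) * 100)
  prq <- project_onto_spline(trq, qc, pixel_size = 100)
  expect_lt(max(abs(prq$x - R * th_pts * 100) / (R * th_pts * 100)), 0.01)
})

test_that("spot detection and linking recover rendered motors", {
  cfg <- flat_cfg(P_AR = 0, P_RA = 0, sigma_loc = 0)
  tr <- simulate_trajectory(cfg, "anterograde", seed = 56, x0 = 1500,
                            duration = 3)
  opt <- optics_config(photons_per_frame = 400, background_rate = 2,
                       seed = 57)
  st <- render_image_stack(list(tr), opt, duration = 3, L = 9000)
  got <- detect_and_link(st)
  expect_length(got, 1)
  expect_gte(nrow(got[[1]]), nrow(tr) - 2)
  m <- min(nrow(got[[1]]), nrow(tr))
  rmse <- sqrt(mean((got[[1]]$x[1:m] - attr(tr, "truth")$x[1:m])^2))
  expect_lte(rmse, 40)
  # blank stack: nothing found
  blank <- structure(array(2, dim = c(15, 60, 6)), pixel_size = 100,
                     dt_frame = 0.15, class = "ift_stack")
  expect_length(detect_and_link(blank), 0)
  # two well-separated motors: two unbroken trajectories
  tr2 <- simulate_trajectory(cfg, "anterograde", seed = 58, x0 = 5000,
                             duration = 3)
  st2 <- render_image_stack(list(tr, tr2), opt, duration = 3, L = 9000)
  got2 <- detect_and_link(st2)
  expect_length(got2, 2)
})
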