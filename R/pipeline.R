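# End-to-end recovery pipeline: generate synthetic single-motor data with
# known kinetics, classify, estimate hazards, simulate the ensemble
# distribution and compare against the ground-truth simulation.

#' Run the synthetic-data recovery pipeline
#'
#' Generates a mixture of single-motor trajectories from a
#' [kinetics_config], applies the event filter and classifier, estimates the
#' turnaround hazards, runs the stochastic ensemble simulator at both the
#' true and the recovered hazards and reports the occupancy residual between
#' the two. This chain — single-molecule statistics in, ensemble
#' distribution out — is the package's integration test.
#'
#' @param cfg a [kinetics_config] (the ground truth).
#' @param n_trajectories number of trajectories to generate.
#' @param rules a [class_rules].
#' @param n_events simulator round trips for the comparison stage.
#' @param seed RNG seed controlling every stage.
#' @param out optional directory; when given, classified-trajectory and
#'   statistics outputs plus a JSON run manifest are written there.
#' @return list of class `ift_recovery`: `fit` (the `ift_turnarounds`
#'   object), `class_table`, `class_shares`, `velocity` (recovered directed
#'   speed profile), `occupancy_residual`, `truth` (the true parameters)
#'   and `manifest`.
#' @export
run_recovery_pipeline <- function(cfg = kinetics_config(),
                                  n_trajectories = 2000,
                                  rules = class_rules(dt_frame = cfg$dt_frame),
                                  n_events = 4000, seed = 1, out = NULL) {
  t0 <- proc.time()[["elapsed"]]
  set_seed_if(seed)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- tic()
  trajs <- simulate_mixture(cfg, n_trajectories)
  timings["generate_s"] <- tic() - stage

  stage <- tic()
  # duration-only filter: the census must retain stationary and confined
  # particles, which rarely displace 200 nm
  flt <- filter_events(trajs, rules, require_displacement = FALSE)
  cls <- classify_trajectories(flt$kept, rules)
  timings["classify_s"] <- tic() - stage

  stage <- tic()
  fit <- turnaround_statistics(cls, L = cfg$L / 1000)
  tab <- table(factor(attr(cls, "classes"),
                      levels = c("anterograde", "retrograde",
                                 "base_diffusive", "stationary",
                                 "turnaround", "rejected")))
  directed <- Filter(function(z)
    z$class %in% c("anterograde", "retrograde"), cls)
  vel <- position_velocity_profile(
    lapply(directed, function(z) z$trajectory), breaks = 250)
  timings["estimate_s"] <- tic() - stage

  stage <- tic()
  sim_true <- run_simulation(sim_config(
    L = cfg$L, P_AR = cfg$P_AR, P_RA = cfg$P_RA,
    v_antero = cfg$v_antero, v_retro = cfg$v_retro, n_events = n_events))
  sim_rec <- run_simulation(sim_config(
    L = cfg$L, P_AR = fit$P_AR, P_RA = fit$P_RA,
    v_antero = cfg$v_antero, v_retro = cfg$v_retro, n_events = n_events))
  res <- compare_distributions(occupancy_profile(sim_rec),
                               occupancy_profile(sim_true))
  timings["simulate_s"] <- tic() - stage

  manifest <- list(
    tool = "iftflow",
    version = as.character(utils::packageVersion("iftflow")),
    seed = seed,
    n_trajectories = n_trajectories,
    n_events = n_events,
    kinetics = cfg[c("L", "P_AR", "P_RA", "pause_rate", "pause_mean",
                     "D_base", "base_region", "dt_frame", "sigma_loc",
                     "track_min_s", "track_mean_s", "track_max_s")],
    class_fractions = as.list(cfg$class_fractions),
    rules = unclass(rules),
    timings_s = as.list(round(timings, 3)),
    total_s = round(tic() - t0, 3))

  report <- structure(list(
    fit = fit,
    class_table = tab,
    class_shares = class_shares(tab, digits = NA),
    velocity = vel,
    occupancy_residual = res$residual,
    n_kept = length(cls),
    truth = list(P_AR = cfg$P_AR, P_RA = cfg$P_RA,
                 class_fractions = cfg$class_fractions),
    manifest = manifest), class = "ift_recovery")

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(
      id = vapply(cls, function(z) attr(z$trajectory, "id")[1], numeric(1)),
      class = attr(cls, "classes"),
      n_pauses = vapply(cls, function(z) nrow(z$pauses), numeric(1)),
      d_antero_nm = vapply(cls, function(z) z$d_antero, numeric(1)),
      d_retro_nm = vapply(cls, function(z) z$d_retro, numeric(1))),
      file.path(out, "classified.csv"), row.names = FALSE)
    s <- summary(fit)
    jsonlite::write_json(list(
      P_AR = fit$P_AR, se_AR = fit$se_AR,
      P_RA = fit$P_RA, se_RA = fit$se_RA,
      N_AR = fit$N_AR, N_RA = fit$N_RA,
      D_antero_um = fit$D_antero, D_retro_um = fit$D_retro,
      run_length_antero_um = s$run_length_antero,
      run_length_retro_um = s$run_length_retro,
      reach_tip = s$reach_tip, reach_base = s$reach_base,
      occupancy_residual = res$residual),
      file.path(out, "stats.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.ift_recovery <- function(x, ...) {
  cat("synthetic-data recovery report\n")
  cat(sprintf("  trajectories kept: %d\n", x$n_kept))
  cat(sprintf("  hazards: true (%.3f, %.3f), recovered (%.3f +/- %.3f, %.3f +/- %.3f) /um\n",
              x$truth$P_AR, x$truth$P_RA, x$fit$P_AR, x$fit$se_AR,
              x$fit$P_RA, x$fit$se_RA))
  sh <- round(x$class_shares, 1)
  cat("  class shares (%):",
      paste(names(sh), sh, sep = " ", collapse = ", "), "\n")
  cat(sprintf("  occupancy residual (recovered vs true hazards): %.3f\n",
              x$occupancy_residual))
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat per-module sections (`kinetics`, `rules`, `sim`); unknown keys are
#' rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return list with `kinetics` ([kinetics_config]), `rules`
#'   ([class_rules]) and `sim` ([sim_config]) entries.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, args, what) {
    if (is.null(args)) return(fn())
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop("unknown ", what, " keys: ", paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  list(kinetics = build(kinetics_config, y$kinetics, "kinetics"),
       rules = build(class_rules, y$rules, "rules"),
       sim = build(sim_config, y$sim, "sim"))
}
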