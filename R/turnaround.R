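#' Turnaround-hazard estimation from classified trajectories
#'
#' Fits the direction-specific turnaround probability densities of single
#' IFT-dynein motors. Under the exponential-distance switching model, the
#' probability per micrometre travelled of an anterograde motor reversing
#' (`P_AR`) is estimated as the total number of anterograde-to-retrograde
#' turnarounds divided by the total anterograde at-risk distance travelled
#' (and symmetrically `P_RA` for retrograde motors). Counting errors are
#' Poisson (`sd = sqrt(N) / D`); derived quantities follow by the delta
#' method: the effective run length is `1/P` and the probability for a motor
#' starting at one end to reach the other end of a cilium of length `L`
#' without reversing is `exp(-P L)`.
#'
#' Only trajectories moving with trains enter the statistics (classes
#' `anterograde`, `retrograde`, `turnaround`): motors diffusing at the base
#' or parked produce apparent short directional excursions that are not
#' train transport. Turns located below the `hazard_min_x` rule are likewise
#' excluded, matching the spatial window of the at-risk distances.
#'
#' @param classified an `ift_classification` from [classify_trajectories],
#'   or a list of `ift_classified` objects.
#' @param L cilium length in micrometres (used for reach probabilities).
#' @param min_x spatial exclusion bound, nm; defaults to the `hazard_min_x`
#'   used during classification.
#' @return an object of class `ift_turnarounds`; see
#'   [turnaround_from_counts] for its fields and available methods.
#' @seealso [reach_probability], [run_length_from_hazard]
#' @export
turnaround_statistics <- function(classified, L = 9, min_x = NULL) {
  if (is.null(min_x)) {
    min_x <- attr(classified, "hazard_min_x")
    if (is.null(min_x)) min_x <- 0
  }
  use <- vapply(classified, function(z)
    z$class %in% c("anterograde", "retrograde", "turnaround"), logical(1))
  classified <- classified[use]
  count_turns <- function(z, dirn)
    sum(z$turns$direction == dirn & z$turns$x_nm >= min_x)
  n_ar <- sum(vapply(classified, count_turns, numeric(1), dirn = "AR"))
  n_ra <- sum(vapply(classified, count_turns, numeric(1), dirn = "RA"))
  d_a <- sum(vapply(classified, function(z) z$d_antero, numeric(1))) / 1000
  d_r <- sum(vapply(classified, function(z) z$d_retro, numeric(1))) / 1000
  turnaround_from_counts(n_ar, d_a, n_ra, d_r, L = L)
}

#' Turnaround statistics from raw counts and distances
#'
#' Builds the hazard-estimate object directly from turn counts and travelled
#' distances (the sufficient statistics of the exponential-distance model).
#'
#' @param n_ar,n_ra numbers of anterograde-to-retrograde and
#'   retrograde-to-anterograde turnarounds.
#' @param d_antero,d_retro total at-risk distances travelled in each
#'   direction, micrometres.
#' @param L cilium length, micrometres.
#' @return object of class `ift_turnarounds` with fields `N_AR`, `N_RA`,
#'   `D_antero`, `D_retro`, `P_AR`, `P_RA` (hazards, 1/um), `se_AR`, `se_RA`
#'   (Poisson standard errors) and `L`. Methods: `print`, `summary`, `coef`,
#'   `confint`, `simulate` (runs the stochastic motor simulator at the
#'   fitted hazards).
#' @export
turnaround_from_counts <- function(n_ar, d_antero, n_ra, d_retro, L = 9) {
  if (d_antero <= 0 || d_retro <= 0)
    stop("travelled distances must be positive")
  structure(list(N_AR = n_ar, N_RA = n_ra,
                 D_antero = d_antero, D_retro = d_retro,
                 P_AR = n_ar / d_antero, P_RA = n_ra / d_retro,
                 se_AR = sqrt(n_ar) / d_antero,
                 se_RA = sqrt(n_ra) / d_retro,
                 L = L),
            class = "ift_turnarounds")
}

#' Probability of covering a distance without a turnaround
#'
#' Exponential survival of the per-distance switching hazard: a motor with
#' turnaround probability density `P` (per um) covers `L` um without
#' reversing with probability `exp(-P L)`; applied over the cilium length
#' this is the probability of reaching the far end (tip for anterograde
#' motors, base for retrograde ones).
#'
#' @param P turnaround probability density, 1/um.
#' @param L distance, um.
#' @param se_P optional standard error of `P`; if given, a delta-method
#'   standard error is attached as attribute `"se"`.
#' @export
reach_probability <- function(P, L, se_P = NULL) {
  p <- exp(-P * L)
  if (!is.null(se_P)) attr(p, "se") <- L * exp(-P * L) * se_P
  p
}

#' Effective run length from a turnaround hazard
#'
#' Mean distance travelled before a directional switch: `1/P`.
#' @param P turnaround probability density, 1/um.
#' @param se_P optional standard error of `P` (delta-method error attached
#'   as attribute `"se"`).
#' @export
run_length_from_hazard <- function(P, se_P = NULL) {
  rl <- ifelse(P > 0, 1 / P, Inf)
  if (!is.null(se_P)) attr(rl, "se") <- ifelse(P > 0, se_P / P^2, NA_real_)
  rl
}

#' @export
coef.ift_turnarounds <- function(object, ...) {
  c(P_AR = object$P_AR, P_RA = object$P_RA)
}

#' @export
confint.ift_turnarounds <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- coef(object)
  se <- c(object$se_AR, object$se_RA)
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' @export
print.ift_turnarounds <- function(x, ...) {
  cat("IFT-dynein turnaround hazards (exponential-distance model)\n")
  cat(sprintf("  P_AR = %.3f +/- %.3f /um  (%d turns over %.1f um anterograde)\n",
              x$P_AR, x$se_AR, x$N_AR, x$D_antero))
  cat(sprintf("  P_RA = %.3f +/- %.3f /um  (%d turns over %.1f um retrograde)\n",
              x$P_RA, x$se_RA, x$N_RA, x$D_retro))
  invisible(x)
}

#' @export
summary.ift_turnarounds <- function(object, ...) {
  rl_a <- run_length_from_hazard(object$P_AR, object$se_AR)
  rl_r <- run_length_from_hazard(object$P_RA, object$se_RA)
  rt <- reach_probability(object$P_AR, object$L, object$se_AR)
  rb <- reach_probability(object$P_RA, object$L, object$se_RA)
  out <- list(fit = object,
              run_length_antero = as.numeric(rl_a),
              run_length_antero_se = attr(rl_a, "se"),
              run_length_retro = as.numeric(rl_r),
              run_length_retro_se = attr(rl_r, "se"),
              reach_tip = as.numeric(rt), reach_tip_se = attr(rt, "se"),
              reach_base = as.numeric(rb), reach_base_se = attr(rb, "se"),
              L = object$L)
  class(out) <- "summary.ift_turnarounds"
  out
}

#' @export
print.summary.ift_turnarounds <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  run lengths: anterograde %.1f +/- %.1f um, retrograde %.1f +/- %.1f um\n",
              x$run_length_antero, x$run_length_antero_se,
              x$run_length_retro, x$run_length_retro_se))
  cat(sprintf("  reach probabilities over %.0f um: tip %.0f%% +/- %.0f%%, base %.0f%% +/- %.0f%%\n",
              x$L, 100 * x$reach_tip, 100 * x$reach_tip_se,
              100 * x$reach_base, 100 * x$reach_base_se))
  invisible(x)
}

#' Simulate the ensemble distribution implied by fitted hazards
#'
#' Runs the stochastic single-motor simulator ([run_simulation]) with the
#' fitted turnaround probability densities, linking the single-molecule
#' switching statistics to the ensemble motor distribution along the cilium.
#'
#' @param object an `ift_turnarounds` fit.
#' @param nsim number of independent simulator runs.
#' @param seed optional RNG seed.
#' @param ... overrides passed to [sim_config] (e.g. `n_events`).
#' @return an `ift_sim` result, or a list of them when `nsim > 1`.
#' @export
simulate.ift_turnarounds <- function(object, nsim = 1, seed = NULL, ...) {
  set_seed_if(seed)
  cfg <- sim_config(P_AR = object$P_AR, P_RA = object$P_RA,
                    L = object$L * 1000, ...)
  out <- lapply(seq_len(nsim), function(i) run_simulation(cfg))
  if (nsim == 1) out[[1]] else out
}
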