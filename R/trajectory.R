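#' Single-motor trajectory container
#'
#' A trajectory is a time-ordered set of localizations of one motor along the
#' cilium: frame times `t` (s), axial position `x` (nm, 0 at the ciliary base,
#' increasing toward the tip) and lateral offset `y` (nm, perpendicular to the
#' ciliary axis). The frame interval is constant. Ground-truth information
#' from the synthetic generator (noiseless path, event log, behaviour class)
#' travels along as attributes so that analysis results can be compared with
#' the truth in tests.
#'
#' @param t frame times in seconds, strictly increasing, constant spacing.
#' @param x axial positions, nm.
#' @param y lateral offsets, nm.
#' @param id trajectory identifier.
#' @param dt_frame frame interval, s. Defaults to the median time step.
#' @param events optional data.frame with columns `event`, `t_s`, `x_nm`
#'   (events are `turn_AR`, `turn_RA`, `pause_start`, `pause_end`).
#' @return an object of class `ift_trajectory` (a data.frame with columns
#'   `t`, `x`, `y`).
#' @export
ift_trajectory <- function(t, x, y = rep(0, length(t)), id = 1L,
                           dt_frame = NULL, events = NULL) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) >= 2L && any(diff(t) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dt_frame))
    dt_frame <- if (length(t) >= 2L) stats::median(diff(t)) else NA_real_
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "id") <- id
  attr(out, "dt_frame") <- dt_frame
  attr(out, "events") <- events
  class(out) <- c("ift_trajectory", "data.frame")
  out
}

#' @export
print.ift_trajectory <- function(x, ...) {
  cat(sprintf("IFT trajectory #%s: %d frames, dt = %.3f s, x in [%.0f, %.0f] nm\n",
              format(attr(x, "id")), nrow(x), attr(x, "dt_frame"),
              min(x$x), max(x$x)))
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev))
    cat("  events:", paste(ev$event, collapse = ", "), "\n")
  invisible(x)
}

traj_events <- function(traj) {
  ev <- attr(traj, "events")
  if (is.null(ev)) data.frame(event = character(0), t_s = numeric(0),
                              x_nm = numeric(0)) else ev
}

#' Write / read trajectory tables
#'
#' Trajectories are exchanged as plain CSV with columns
#' `id,frame,t_s,x_nm,y_nm`; ground-truth event logs as `id,event,t_s,x_nm`.
#'
#' @param trajectories list of [ift_trajectory] objects.
#' @param path output CSV file.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    data.frame(id = attr(tr, "id"), frame = seq_len(nrow(tr)) - 1L,
               t_s = tr$t, x_nm = tr$x, y_nm = tr$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$id), function(g) {
    g <- g[order(g$frame), ]
    ift_trajectory(g$t_s, g$x_nm, g$y_nm, id = g$id[1])
  })
}

#' @rdname write_trajectories
#' @export
write_event_log <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    ev <- traj_events(tr)
    if (!nrow(ev)) return(NULL)
    data.frame(id = attr(tr, "id"), event = ev$event, t_s = ev$t_s,
               x_nm = ev$x_nm)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), event = character(0),
               t_s = numeric(0), x_nm = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
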