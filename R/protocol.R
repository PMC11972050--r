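#' Multi-sweep acquisition protocol
#'
#' Describes a bidirectional multi-sweep C-arm acquisition: `n_sweeps`
#' rotations of `rotation_time` seconds each, separated by `pause_time`
#' seconds, each acquiring `views_per_sweep` projections over
#' `angular_range` degrees. Odd-indexed sweeps (0-based) rotate backward;
#' their view angles are the reversal of the forward angle list. The first
#' `n_mask_sweeps` sweeps are pre-contrast mask sweeps.
#'
#' The per-view frame times are nonuniform when `accel_fraction > 0`: the
#' gantry accelerates over the first `accel_fraction` of the rotation and
#' decelerates over the last, following a trapezoidal angular-velocity
#' profile with one view per equal angular increment.
#'
#' @param n_sweeps number of rotations (sweeps).
#' @param views_per_sweep projections acquired per sweep (>= 2).
#' @param angular_range angular span of one sweep, degrees.
#' @param rotation_time duration of one sweep, seconds.
#' @param pause_time pause between consecutive sweeps, seconds.
#' @param n_mask_sweeps leading pre-contrast sweeps used as baseline.
#' @param accel_fraction fraction of the rotation spent accelerating (and,
#'   symmetrically, decelerating), in `[0, 0.5)`.
#' @return An object of class `sweep_protocol`.
#' @examples
#' p <- sweep_protocol(n_sweeps = 10, views_per_sweep = 248,
#'                     angular_range = 200, rotation_time = 3.9,
#'                     pause_time = 1.4)
#' p$total_duration  # ~51.6 s
#' @export
sweep_protocol <- function(n_sweeps, views_per_sweep, angular_range,
                           rotation_time, pause_time,
                           n_mask_sweeps = 0L, accel_fraction = 0.15) {
  if (n_sweeps < 1 || views_per_sweep < 2)
    stop("sweep_protocol: n_sweeps must be >= 1 and views_per_sweep >= 2", call. = FALSE)
  if (angular_range <= 0 || rotation_time <= 0 || pause_time < 0)
    stop("sweep_protocol: angular_range and rotation_time must be positive, pause_time nonnegative",
         call. = FALSE)
  if (n_mask_sweeps < 0 || n_mask_sweeps > n_sweeps)
    stop("sweep_protocol: n_mask_sweeps must be in [0, n_sweeps]", call. = FALSE)
  if (accel_fraction < 0 || accel_fraction >= 0.5)
    stop("sweep_protocol: accel_fraction must be in [0, 0.5)", call. = FALSE)
  structure(list(
    n_sweeps = as.integer(n_sweeps),
    n_mask_sweeps = as.integer(n_mask_sweeps),
    views_per_sweep = as.integer(views_per_sweep),
    angular_range = angular_range,
    angular_step = angular_range / (views_per_sweep - 1),
    rotation_time = rotation_time,
    pause_time = pause_time,
    accel_fraction = accel_fraction,
    total_duration = n_sweeps * rotation_time + (n_sweeps - 1) * pause_time
  ), class = "sweep_protocol")
}

#' @export
print.sweep_protocol <- function(x, ...) {
  cat(sprintf(
    "Sweep protocol: %d sweeps (%d mask) x %d views over %.1f deg\n",
    x$n_sweeps, x$n_mask_sweeps, x$views_per_sweep, x$angular_range))
  cat(sprintf("  rotation %.2f s, pause %.2f s, total %.2f s, accel fraction %.2f\n",
              x$rotation_time, x$pause_time, x$total_duration, x$accel_fraction))
  invisible(x)
}

#' Per-view frame times within one sweep
#'
#' Times at which the views of a single sweep are acquired, under a
#' trapezoidal angular-velocity profile: the gantry ramps up linearly over
#' `accel_fraction * rotation_time`, cruises, and ramps down symmetrically.
#' Views are spaced at equal angular increments, so inter-view gaps are
#' longer at the start and end of the sweep than in the middle.
#'
#' @param rotation_time sweep duration, seconds.
#' @param n_views number of views (>= 2).
#' @param accel_fraction fraction of the sweep spent accelerating, `[0, 0.5)`.
#' @return Numeric vector of `n_views` strictly increasing times in
#'   `[0, rotation_time]`, with `times[1] == 0` and
#'   `times[n_views] == rotation_time`.
#' @export
frame_times <- function(rotation_time, n_views, accel_fraction = 0.15) {
  if (n_views < 2) stop("frame_times: n_views must be >= 2", call. = FALSE)
  if (accel_fraction < 0 || accel_fraction >= 0.5)
    stop("frame_times: accel_fraction must be in [0, 0.5)", call. = FALSE)
  u <- seq(0, 1, length.out = n_views)  # cumulative angle fraction per view
  if (accel_fraction == 0) return(u * rotation_time)
  f <- accel_fraction
  # unit-duration profile: v(t) ramps 0->vmax on [0,f], flat on [f,1-f],
  # ramps down on [1-f,1]; total angle 1 => vmax = 1/(1-f)
  vmax <- 1 / (1 - f)
  u_acc <- vmax * f / 2           # angle covered during acceleration
  t <- numeric(n_views)
  lo <- u <= u_acc
  hi <- u >= 1 - u_acc
  mid <- !(lo | hi)
  t[lo] <- sqrt(2 * f * u[lo] / vmax)
  t[mid] <- f + (u[mid] - u_acc) / vmax
  t[hi] <- 1 - sqrt(2 * f * (1 - u[hi]) / vmax)
  t[n_views] <- 1
  t * rotation_time
}

#' Build the full view schedule of a multi-sweep acquisition
#'
#' Expands a [sweep_protocol()] into one record per acquired view: its
#' angle, absolute acquisition time, sweep index, rotation direction, and
#' the index of the angle within the forward angle list (`angle_index`,
#' 1-based; shared between forward and backward sweeps so that views of
#' the same ray geometry can be grouped across sweeps).
#'
#' @param protocol a [sweep_protocol()].
#' @return A `data.frame` of class `view_schedule` with columns
#'   `angle_deg`, `time_s`, `sweep`, `direction`, `angle_index`, plus
#'   attributes `protocol` and `forward_angles`.
#' @export
build_view_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  p <- protocol
  fwd <- seq(0, p$angular_range, length.out = p$views_per_sweep)
  ft <- frame_times(p$rotation_time, p$views_per_sweep, p$accel_fraction)
  rows <- vector("list", p$n_sweeps)
  for (s in seq_len(p$n_sweeps) - 1L) {
    backward <- (s %% 2L) == 1L
    idx <- if (backward) rev(seq_along(fwd)) else seq_along(fwd)
    rows[[s + 1L]] <- data.frame(
      angle_deg = fwd[idx],
      time_s = s * (p$rotation_time + p$pause_time) + ft,
      sweep = s,
      direction = if (backward) "backward" else "forward",
      angle_index = idx,
      stringsAsFactors = FALSE
    )
  }
  sched <- do.call(rbind, rows)
  rownames(sched) <- NULL
  attr(sched, "protocol") <- p
  attr(sched, "forward_angles") <- fwd
  class(sched) <- c("view_schedule", "data.frame")
  sched
}

#' Write a view schedule to CSV
#'
#' @param schedule a [build_view_schedule()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[, c("angle_deg", "time_s", "sweep", "direction")],
                   path, row.names = FALSE)
  invisible(path)
}
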