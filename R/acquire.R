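#' Simulate a multi-sweep projection acquisition
#'
#' Forward projects a dynamic phantom along a view schedule: each view's
#' projection row is the line integral of the phantom frame evaluated at
#' that view's acquisition time and angle. Optional Poisson photon noise
#' is applied afterwards.
#'
#' @param phantom a [build_phantom()] result.
#' @param schedule a [build_view_schedule()] result.
#' @param spec a [projector_spec()] matching the phantom grid.
#' @param noise a [noise_spec()] or `NULL` for a noiseless acquisition.
#' @param A optional precomputed [system_matrix()] over the schedule's
#'   forward angle list.
#' @return An object of class `projection_series`: list with `values`
#'   (`n_bins` x `n_views` line integrals, columns in schedule order),
#'   `schedule`, and `n_bins`.
#' @export
simulate_projections <- function(phantom, schedule, spec, noise = NULL, A = NULL) {
  stopifnot(inherits(phantom, "perfusion_phantom"),
            inherits(schedule, "view_schedule"),
            inherits(spec, "projector_spec"))
  if (phantom$spec$nx != spec$nx || phantom$spec$ny != spec$ny)
    stop("simulate_projections: phantom grid does not match projector grid", call. = FALSE)
  fwd <- attr(schedule, "forward_angles")
  if (is.null(A)) A <- system_matrix(spec, fwd)
  nb <- spec$n_bins
  blocks <- lapply(seq_along(fwd), function(k) A[(k - 1L) * nb + seq_len(nb), , drop = FALSE])
  vals <- matrix(0, nb, nrow(schedule))
  for (v in seq_len(nrow(schedule))) {
    frame <- phantom_frame(phantom, schedule$time_s[v])
    vals[, v] <- as.numeric(blocks[[schedule$angle_index[v]]] %*% as.vector(frame))
  }
  if (!is.null(noise)) vals <- add_poisson_noise(vals, noise)
  structure(list(values = vals, schedule = schedule, n_bins = nb),
            class = "projection_series")
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("Projection series: %d bins x %d views (%d sweeps)\n",
              x$n_bins, ncol(x$values), length(unique(x$schedule$sweep))))
  invisible(x)
}
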