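#' Poisson photon-noise specification
#'
#' Photon noise is applied in the photon-count domain: each detector bin
#' receives `I ~ Poisson(N0 * exp(-p))` counts, where `p` is the noiseless
#' line integral and `N0 = fluence * detector_bin_area` is the
#' unattenuated photon count per bin (the stated fluence is interpreted as
#' the unattenuated flux I0). The noisy line integral is
#' `p' = log(N0 / max(I, 1))`; zero-count bins are floored at one count so
#' the log stays finite.
#'
#' @param fluence photons per mm^2 at the detector, or one of the presets
#'   `"high"` (2.1e5), `"moderate"` (6e5), `"none"` (noise disabled).
#' @param detector_bin_area detector bin area, mm^2 (default 0.16 x 0.16).
#' @param seed integer RNG seed.
#' @param enabled set `FALSE` to pass projections through unchanged.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(fluence = "moderate", detector_bin_area = 0.16 * 0.16,
                       seed = 1L, enabled = TRUE) {
  if (is.character(fluence)) {
    fluence <- switch(match.arg(fluence, c("high", "moderate", "none")),
                      high = 2.1e5, moderate = 6e5, none = { enabled <- FALSE; 6e5 })
  }
  if (fluence <= 0 || detector_bin_area <= 0)
    stop("noise_spec: fluence and detector_bin_area must be positive", call. = FALSE)
  if (fluence * detector_bin_area < 1)
    stop("noise_spec: fewer than one photon per bin (N0 < 1)", call. = FALSE)
  structure(list(fluence = fluence, detector_bin_area = detector_bin_area,
                 N0 = fluence * detector_bin_area,
                 seed = as.integer(seed), enabled = isTRUE(enabled)),
            class = "noise_spec")
}

#' Add Poisson photon noise to line integrals
#'
#' @param projections numeric vector/matrix of noiseless line integrals
#'   (finite; small negatives are clamped to zero with a warning).
#' @param spec a [noise_spec()].
#' @return Noisy line integrals with the same shape; deterministic for a
#'   fixed `spec$seed`. With `spec$enabled = FALSE` the input is returned
#'   unchanged.
#' @export
add_poisson_noise <- function(projections, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!all(is.finite(projections)))
    stop("add_poisson_noise: projections must be finite", call. = FALSE)
  if (!spec$enabled) return(projections)
  p <- projections
  if (any(p < 0)) {
    warning("add_poisson_noise: clamping ", sum(p < 0), " negative line integrals to 0")
    p[p < 0] <- 0
  }
  counts <- with_local_seed(spec$seed,
                            stats::rpois(length(p), spec$N0 * exp(-as.vector(p))))
  out <- log(spec$N0 / pmax(counts, 1))
  if (is.matrix(projections)) out <- matrix(out, nrow = nrow(projections))
  out
}
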