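#' Akima spline interpolation of a time series
#'
#' Resamples irregularly or regularly sampled values onto new time points
#' with Akima's (1970) locally fitted cubic interpolant. Unlike a natural
#' cubic spline, the Akima interpolant does not overshoot between samples
#' of step-like data, which is why it is the resampling method of choice
#' for time attenuation curves. No extrapolation is performed.
#'
#' @param times strictly increasing sample times (>= 5 points).
#' @param values sample values: a vector, or a matrix with one column per
#'   series (rows = `times`).
#' @param new_times query times; must lie within `range(times)`.
#' @return Interpolated values: a vector, or a matrix of dimension
#'   `length(new_times)` x `ncol(values)`.
#' @export
resample_time_series <- function(values, times, new_times) {
  n <- length(times)
  if (n < 5) stop("resample_time_series: Akima interpolation needs >= 5 samples", call. = FALSE)
  if (any(diff(times) <= 0)) stop("resample_time_series: times must be strictly increasing", call. = FALSE)
  if (any(new_times < times[1] - 1e-12) || any(new_times > times[n] + 1e-12))
    stop("resample_time_series: new_times outside the sampled span (no extrapolation); crop or exclude instead",
         call. = FALSE)
  new_times <- pmin(pmax(new_times, times[1]), times[n])
  vec <- is.null(dim(values))
  v <- if (vec) matrix(values, ncol = 1) else values
  if (nrow(v) != n) stop("resample_time_series: values/times length mismatch", call. = FALSE)
  out <- apply(v, 2, akima_interp_1d, x = times, xi = new_times)
  if (vec) as.numeric(out) else matrix(out, nrow = length(new_times))
}

# Akima (1970) univariate interpolant. x strictly increasing, length >= 5.
akima_interp_1d <- function(y, x, xi) {
  n <- length(x)
  m <- diff(y) / diff(x)                       # segment slopes, length n-1
  # quadratic-trend extension of slopes (Akima's end conditions)
  me <- c(3 * m[1] - 2 * m[2], 2 * m[1] - m[2], m,
          2 * m[n - 1] - m[n - 2], 3 * m[n - 1] - 2 * m[n - 2])
  # node derivative: weighted mean of adjacent slopes; for node i the
  # surrounding extended slopes are me[i..i+3]
  w1 <- abs(me[4:(n + 3)] - me[3:(n + 2)])     # |m_{i+1}-m_i|
  w2 <- abs(me[2:(n + 1)] - me[1:n])           # |m_{i-1}-m_{i-2}|
  den <- w1 + w2
  tder <- ifelse(den > 0,
                 (w1 * me[2:(n + 1)] + w2 * me[3:(n + 2)]) / ifelse(den > 0, den, 1),
                 (me[2:(n + 1)] + me[3:(n + 2)]) / 2)
  k <- findInterval(xi, x, rightmost.closed = TRUE)
  k[k < 1] <- 1L; k[k >= n] <- n - 1L
  h <- x[k + 1] - x[k]
  s <- (xi - x[k]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[k] + h10 * h * tder[k] + h01 * y[k + 1] + h11 * h * tder[k + 1]
}
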