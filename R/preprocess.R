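# Zero-phase low-pass filtering and numerical differentiation.

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero phase lag; the effective attenuation order is doubled by the two
#' passes). The series is extended by odd reflection about both endpoints
#' before filtering to suppress edge transients; the pad length is three
#' times the filter's characteristic length.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param cutoff cutoff frequency, Hz. Must be below the Nyquist rate.
#' @param rate sampling rate, Hz.
#' @param order filter order per pass (default 2).
#' @return filtered series, same shape as `x`.
#' @export
butter_zero_phase <- function(x, cutoff, rate, order = 2) {
  if (is.matrix(x)) {
    return(apply(x, 2, butter_zero_phase, cutoff = cutoff, rate = rate,
                 order = order))
  }
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop("cutoff must lie in (0, rate/2)")
  }
  n <- length(x)
  pad <- max(3 * (order + 1), ceiling(3 * rate / cutoff))
  if (n <= pad) stop("series too short for the filter padding (need > ",
                     pad, " samples)")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # odd reflection keeps the extension continuous in value and slope
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Filter all marker trajectories of a session
#'
#' @param session a [gait_session()].
#' @param cutoff cutoff frequency in Hz (default 12).
#' @param order Butterworth order per pass (default 2).
#' @return the session with filtered marker matrices.
#' @export
filter_session <- function(session, cutoff = 12, order = 2) {
  session$markers <- lapply(session$markers, butter_zero_phase,
                            cutoff = cutoff, rate = session$rate_markers,
                            order = order)
  session
}

#' Numerical time derivative
#'
#' Central differences in the interior, one-sided differences at the ends;
#' length is preserved.
#'
#' @param x numeric vector.
#' @param rate sampling rate, Hz.
#' @return derivative series, units of `x` per second.
#' @export
differentiate <- function(x, rate) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}
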