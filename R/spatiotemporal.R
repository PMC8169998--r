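# Spatiotemporal step parameters and their variability.

#' Per-step spatiotemporal parameters
#'
#' For each touchdown after the first: step time (time since the previous,
#' contralateral, touchdown), step length (AP distance between the leading
#' and trailing hallux at the leading-foot touchdown), step width (absolute
#' ML hallux distance at touchdown) and double-support time (overlap of the
#' stance intervals bounding the step, i.e. time from this touchdown to the
#' trailing foot's toe-off).
#'
#' @param session a [gait_session()].
#' @param events a [gait_events()] object with alternating touchdowns.
#' @return data frame of `StepRecord`s: `time`, `side`, `step_time`,
#'   `step_length`, `step_width`, `double_support_time` (NA when the
#'   bounding toe-off is missing).
#' @export
step_parameters <- function(session, events) {
  td <- events$touchdowns
  if (nrow(td) < 3) stop("need at least 3 touchdowns")
  if (any(td$side[-1] == td$side[-nrow(td)])) {
    stop("touchdowns must alternate sides; reconcile events first")
  }
  to <- events$toeoffs
  hal <- function(side) session$markers[[paste0(side, "HLX")]]
  rows <- lapply(2:nrow(td), function(k) {
    t_k <- td$time[k]
    lead <- td$side[k]; trail <- td$side[k - 1]
    lead_xy <- apply(hal(lead)[, 1:2], 2, function(v) {
      approx(session$time, v, xout = t_k)$y
    })
    trail_xy <- apply(hal(trail)[, 1:2], 2, function(v) {
      approx(session$time, v, xout = t_k)$y
    })
    trail_to <- to$time[to$side == trail & to$time > td$time[k - 1]]
    ds <- if (length(trail_to) > 0) max(0, trail_to[1] - t_k) else NA_real_
    data.frame(time = t_k, side = lead,
               step_time = t_k - td$time[k - 1],
               step_length = lead_xy[1] - trail_xy[1],
               step_width = abs(lead_xy[2] - trail_xy[2]),
               double_support_time = ds)
  })
  do.call(rbind, rows)
}

#' Coefficient of variation
#'
#' `100 * sample SD / mean` (n-1 denominator), in percent.
#'
#' @param values numeric vector, length at least 2, non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  100 * sd(values) / m
}

#' Trial-level step-parameter summary
#'
#' Means and coefficients of variation of step length, width, time and
#' double-support time.
#'
#' @param steps data frame from [step_parameters()].
#' @return data frame: `parameter`, `mean`, `cv` (percent).
#' @export
summarize_steps <- function(steps) {
  pars <- c("step_length", "step_width", "step_time", "double_support_time")
  do.call(rbind, lapply(pars, function(p) {
    v <- steps[[p]]
    v <- v[!is.na(v)]
    data.frame(parameter = p, mean = mean(v),
               cv = coefficient_of_variation(v))
  }))
}
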