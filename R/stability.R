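# Extrapolated centre of mass, margin of stability, and the
# stability-normalised walking speed.

#' Reduced-model centre-of-mass proxy
#'
#' Weighted mean of the sacrum, the trochanter midpoint and C7. The default
#' weights (0.5, 0.3, 0.2) put most mass at pelvis level.
#'
#' @param session a [gait_session()] (typically filtered).
#' @param weights numeric length-3 vector (sacrum, mid-trochanter, C7);
#'   must sum to 1.
#' @return n-by-3 matrix of proxy positions.
#' @export
com_proxy <- function(session, weights = c(0.5, 0.3, 0.2)) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  mid_tro <- (session$markers$LTRO + session$markers$RTRO) / 2
  weights[1] * session$markers$SACR + weights[2] * mid_tro +
    weights[3] * session$markers$C7
}

#' Pendulum length from the marker geometry
#'
#' Mean vertical distance from the CoM proxy to the lowest hallux sample of
#' the trial; used as the inverted-pendulum length l in
#' omega0 = sqrt(g / l).
#'
#' @param com n-by-3 CoM proxy matrix.
#' @param session the session the proxy came from.
#' @return length in m.
#' @export
pendulum_length <- function(com, session) {
  zmin <- min(session$markers$LHLX[, 3], session$markers$RHLX[, 3])
  l <- mean(com[, 3]) - zmin
  if (l <= 0) stop("non-positive pendulum length")
  l
}

#' Extrapolated centre of mass (anteroposterior)
#'
#' `XCoM(t) = x(t) + v(t) / omega0` with `omega0 = sqrt(g / l)`: the CoM
#' position extended by its velocity scaled with the inverted-pendulum
#' eigenfrequency.
#'
#' @param position_ap AP CoM position series, m.
#' @param velocity_ap AP CoM velocity series, m/s (belt-relative for
#'   treadmill use).
#' @param l pendulum length, m.
#' @param g gravitational acceleration, m/s^2.
#' @return XCoM series, m.
#' @export
xcom <- function(position_ap, velocity_ap, l, g = 9.81) {
  if (l <= 0) stop("pendulum length must be positive")
  position_ap + velocity_ap / sqrt(g / l)
}

#' Anteroposterior margin of stability at each touchdown
#'
#' MoS = (AP position of the leading-foot hallux) - XCoM at the touchdown
#' instant. Positive values mean the extrapolated CoM lies behind the
#' anterior boundary of the base of support (mechanically stable).
#'
#' @param xcom_series XCoM series on the session's marker grid.
#' @param session the (filtered) session.
#' @param events a [gait_events()] object.
#' @return object of class `"mos_series"`: data frame with
#'   `touchdown_time`, `side`, `mos_ap`.
#' @export
mos_at_touchdowns <- function(xcom_series, session, events) {
  td <- events$touchdowns
  if (nrow(td) == 0) stop("no touchdown events")
  rng <- range(session$time)
  if (any(td$time < rng[1] | td$time > rng[2])) {
    stop("touchdown outside the sampled time range")
  }
  mos <- vapply(seq_len(nrow(td)), function(i) {
    hal <- session$markers[[paste0(td$side[i], "HLX")]][, 1]
    h <- approx(session$time, hal, xout = td$time[i])$y
    x <- approx(session$time, xcom_series, xout = td$time[i])$y
    h - x
  }, numeric(1))
  structure(data.frame(touchdown_time = td$time, side = td$side,
                       mos_ap = mos),
            class = c("mos_series", "data.frame"),
            trial_label = session$trial_label)
}

#' Full MoS pipeline for one session
#'
#' Filters the markers, detects (or accepts) gait events, builds the CoM
#' proxy and its belt-relative AP velocity, and returns the per-touchdown
#' anteroposterior MoS.
#'
#' @param session a [gait_session()] (raw; filtering happens here).
#' @param events optional [gait_events()]; when `NULL`, force-based
#'   detection with marker fallback and alternation reconciliation is used.
#' @param cutoff low-pass cutoff for the markers, Hz.
#' @param weights CoM proxy weights, see [com_proxy()].
#' @param l pendulum length override, m; default estimates it from the
#'   marker geometry via [pendulum_length()].
#' @param belt_relative add the stance-side belt speed to the lab-frame CoM
#'   velocity (the base of support translates with the belt). Default TRUE.
#' @param anterior_sign +1 if +x is anterior (the package convention), -1
#'   to analyse data recorded with the opposite sign.
#' @return a `mos_series` data frame.
#' @export
compute_mos <- function(session, events = NULL, cutoff = 12,
                        weights = c(0.5, 0.3, 0.2), l = NULL,
                        belt_relative = TRUE, anterior_sign = 1) {
  if (anterior_sign == -1) {
    session$markers <- lapply(session$markers, function(m) {
      m[, 1] <- -m[, 1]; m
    })
  }
  fses <- filter_session(session, cutoff = cutoff)
  if (is.null(events)) {
    fev <- if (!is.null(session$forces)) {
      detect_events_force(session$forces)
    }
    mev <- tryCatch(detect_events_marker(fses), error = function(e) NULL)
    events <- reconcile_events(fev, mev)
  }
  com <- com_proxy(fses, weights)
  if (is.null(l)) l <- pendulum_length(com, fses)
  vel_lab <- differentiate(com[, 1], session$rate_markers)
  # The belt-relative XCoM jumps at touchdown (the reference belt
  # switches), so it is evaluated per event with the touchdown side's own
  # belt speed rather than by interpolating a stance-side series across
  # the discontinuity; this keeps MoS robust to frame-level event error.
  td <- events$touchdowns
  if (nrow(td) == 0) stop("no touchdown events")
  belt <- list(L = session$belt_left, R = session$belt_right)
  at <- function(series, t) approx(session$time, series, xout = t)$y
  mos <- vapply(seq_len(nrow(td)), function(i) {
    t_i <- td$time[i]
    side <- td$side[i]
    v <- at(vel_lab, t_i) +
      if (belt_relative) at(belt[[side]], t_i) else 0
    h <- at(fses$markers[[paste0(side, "HLX")]][, 1], t_i)
    h - xcom(at(com[, 1], t_i), v, l)
  }, numeric(1))
  structure(data.frame(touchdown_time = td$time, side = td$side,
                       mos_ap = mos),
            class = c("mos_series", "data.frame"),
            trial_label = session$trial_label)
}

#' Mean MoS over the final steps of a trial
#'
#' @param mos a `mos_series` (or any data frame with `mos_ap`).
#' @param n_steps number of final steps to average (default 10).
#' @return mean MoS, m.
#' @export
mean_mos_final_steps <- function(mos, n_steps = 10) {
  v <- mos$mos_ap
  if (length(v) < n_steps) {
    stop("need at least ", n_steps, " steps, have ", length(v))
  }
  mean(tail(v, n_steps))
}

# ---- stability-normalised walking speed ------------------------------------

#' Fit the MoS-vs-speed curve and solve the stability-normalised speed
#'
#' Fits `mean_mos = f(speed)` by least squares (second-order polynomial,
#' with a linear fallback) and solves `f(speed) = target_mos` on the
#' decreasing branch. The stability-normalised walking speed is the speed
#' at which a participant's mean MoS over the final ten steps equals the
#' target (0.05 m by default), used to equate baseline stability across
#' participants before perturbation trials.
#'
#' @param speeds trial speeds, m/s (at least 3, strictly increasing).
#' @param mean_mos mean final-steps MoS per trial, m.
#' @param target_mos target MoS, m.
#' @param degree polynomial degree (2, with automatic linear fallback).
#' @return object of class `"stability_curve"` with the fitted
#'   coefficients, `normalized_speed` (reported to 0.01 m/s), and flags
#'   `extrapolated` / `linear_fallback`.
#' @export
fit_stability_curve <- function(speeds, mean_mos, target_mos = 0.05,
                                degree = 2) {
  if (length(speeds) < 3) stop("need at least 3 speed points")
  if (any(diff(speeds) <= 0)) stop("speeds must be strictly increasing")
  if (length(unique(mean_mos)) == 1) stop("mean_mos is constant; no curve")
  df <- data.frame(speed = speeds, mos = mean_mos)
  fit2 <- lm(mos ~ poly(speed, degree, raw = TRUE), data = df)
  cf <- coef(fit2)                      # (a0, a1, a2)
  rng <- range(speeds)
  sol <- solve_target_speed(cf, target_mos, rng)
  linear_fallback <- FALSE
  fit <- fit2
  if (is.null(sol)) {
    fit1 <- lm(mos ~ speed, data = df)
    c1 <- coef(fit1)
    if (c1[2] >= 0) {
      stop("no in-range decreasing root and the linear trend is ",
           "non-decreasing; cannot solve the normalised speed")
    }
    v <- unname((target_mos - c1[1]) / c1[2])
    sol <- list(speed = v, extrapolated = v < rng[1] || v > rng[2])
    linear_fallback <- TRUE
    fit <- fit1
    cf <- c(c1, 0)
  }
  structure(list(speeds = speeds, mean_mos = mean_mos,
                 fit_coeffs = unname(cf), target_mos = target_mos,
                 normalized_speed = round(sol$speed, 2),
                 normalized_speed_raw = sol$speed,
                 extrapolated = sol$extrapolated,
                 linear_fallback = linear_fallback, fit = fit),
            class = "stability_curve")
}

# Root of a0 + a1 v + a2 v^2 = target on the decreasing branch. Returns
# NULL when no usable quadratic root exists; in-range roots are preferred,
# otherwise the decreasing root closest to the range is flagged
# extrapolated. Near-degenerate quadratics fall back to the linear term.
solve_target_speed <- function(cf, target, rng) {
  cf <- unname(cf)
  a0 <- cf[1] - target; a1 <- cf[2]; a2 <- if (length(cf) > 2) cf[3] else 0
  scale <- max(abs(cf), 1e-12)
  if (abs(a2) < 1e-9 * scale) {
    if (a1 >= 0) return(NULL)
    v <- -a0 / a1
    return(list(speed = v, extrapolated = v < rng[1] || v > rng[2]))
  }
  disc <- a1^2 - 4 * a2 * a0
  if (disc < 0) return(NULL)
  roots <- (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  decreasing <- a1 + 2 * a2 * roots < 0
  roots <- roots[decreasing]
  if (length(roots) == 0) return(NULL)
  in_range <- roots >= rng[1] & roots <= rng[2]
  if (any(in_range)) {
    return(list(speed = roots[in_range][1], extrapolated = FALSE))
  }
  NULL
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("Stability-normalised walking speed\n")
  cat(sprintf("  fitted over %d speeds (%.1f-%.1f m/s), %s fit\n",
              length(x$speeds), min(x$speeds), max(x$speeds),
              if (x$linear_fallback) "linear" else "quadratic"))
  cat(sprintf("  target MoS: %.3f m\n", x$target_mos))
  cat(sprintf("  normalised speed: %.2f m/s%s\n", x$normalized_speed,
              if (x$extrapolated) " (extrapolated beyond measured range)"
              else ""))
  invisible(x)
}

#' @export
summary.stability_curve <- function(object, ...) {
  print(object)
  cat("\nCoefficients (mos = a0 + a1*v + a2*v^2):\n")
  print(setNames(object$fit_coeffs[1:3], c("a0", "a1", "a2")))
  cat("\nResiduals (m):\n")
  print(summary(residuals(object)))
  invisible(object)
}

#' @export
coef.stability_curve <- function(object, ...) {
  setNames(object$fit_coeffs[1:3], c("a0", "a1", "a2"))
}

#' @export
predict.stability_curve <- function(object, speeds = object$speeds, ...) {
  polyval_asc(object$fit_coeffs, speeds)
}

#' @export
residuals.stability_curve <- function(object, ...) {
  object$mean_mos - predict(object)
}

#' @export
plot.stability_curve <- function(x, ...) {
  vs <- seq(min(x$speeds), max(x$speeds), length.out = 100)
  plot(x$speeds, x$mean_mos, xlab = "walking speed (m/s)",
       ylab = "mean AP MoS, final 10 steps (m)",
       main = "Stability-normalised walking speed", ...)
  lines(vs, predict(x, vs))
  abline(h = x$target_mos, lty = 2)
  abline(v = x$normalized_speed, lty = 3)
  invisible(x)
}

#' Stability-normalised speed from a set of trials
#'
#' Convenience wrapper: computes the mean final-steps MoS of each trial via
#' the full pipeline and fits the stability-speed curve.
#'
#' @param sessions list of [gait_session()]s at increasing speeds.
#' @param speeds the trial speeds, m/s.
#' @param target_mos target MoS, m.
#' @param n_steps number of final steps averaged per trial.
#' @param ... passed to [compute_mos()].
#' @return a `stability_curve`.
#' @export
stability_normalized_speed <- function(sessions, speeds, target_mos = 0.05,
                                       n_steps = 10, ...) {
  mm <- vapply(sessions, function(s) {
    mean_mos_final_steps(compute_mos(s, ...), n_steps)
  }, numeric(1))
  fit_stability_curve(speeds, mm, target_mos)
}
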