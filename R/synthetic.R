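# Synthetic treadmill gait generator with ground truth.
#
# The kinematic model is deliberately reduced: feet are advected backward at
# belt speed during stance and transported forward by a minimum-jerk profile
# during swing; the trunk/pelvis markers ride on a common CoM-proxy
# trajectory that is inverse-designed so that the margin of stability the
# analysis pipeline computes at each touchdown equals a prescribed truth
# value exactly. All event times are snapped to the 100 Hz marker grid so
# that linear interpolation of marker series at event instants is exact.

MARKER_DT <- 0.01   # 100 Hz marker grid
FORCE_DT <- 0.001   # 1000 Hz force grid

snap_grid <- function(t, dt = MARKER_DT) round(t / dt) * dt

# lognormal draws with exact mean m and coefficient of variation cv
rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# minimum-jerk blend: s(0)=0, s(1)=1, zero velocity/acceleration at ends
minjerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# Landing skid: after touchdown the hallux blends smoothly (C2) from zero
# velocity into full belt advection over SKID_W seconds, as a real foot
# plants rather than instantly matching the belt. Returns the forward
# offset relative to pure advection from the touchdown position;
# lag(dt) = v * integral_0^dt (1 - minjerk(u/w)) du, saturating at v*w/2.
SKID_W <- 0.05
stance_lag <- function(dt, v, w = SKID_W) {
  dtc <- pmin(dt, w)
  tau <- dtc / w
  v * (dtc - w * (2.5 * tau^4 - 3 * tau^5 + tau^6))
}

#' Gait model parameters for the synthetic generator
#'
#' Defaults describe an older adult walking at 1.3 m/s: step time 0.55 s
#' (CV 3%), step width 0.10 m, one double-support episode lasting 10% of a
#' stride, pendulum length 1.05 m. `step_length_mean = NULL` derives the
#' step length from belt consistency (`speed * step_time_mean`), which is
#' what treadmill walking enforces on average.
#'
#' @param walking_speed nominal belt speed, m/s.
#' @param step_time_mean,step_time_cv step time mean (s) and coefficient of
#'   variation (fraction).
#' @param step_length_mean,step_length_cv step length mean (m; `NULL` =
#'   belt-consistent) and CV.
#' @param step_width_mean,step_width_cv step width mean (m) and CV.
#' @param double_support_fraction duration of one double-support episode as
#'   a fraction of stride time; must lie in (0, 0.5).
#' @param leg_length inverted-pendulum length l (m); the extrapolated CoM
#'   uses omega0 = sqrt(g / l).
#' @param body_mass kg; scales the vertical ground reaction force.
#' @param mos_speed_coeffs coefficients (a0, a1, a2) of the true mean
#'   MoS-vs-speed relationship a0 + a1 v + a2 v^2, which must be monotone
#'   decreasing over 0.4-1.8 m/s.
#' @param mos_sd step-to-step SD of the true MoS about the speed curve, m.
#' @param marker_noise_sd additive Gaussian marker noise SD, m (default
#'   1 mm).
#' @param osc_amplitude amplitude of the intra-step CoM oscillation, m.
#' @param seed default RNG seed used by the simulators.
#' @return object of class `"gait_params"` (a validated list).
#' @export
gait_params <- function(walking_speed = 1.3,
                        step_time_mean = 0.55, step_time_cv = 0.03,
                        step_length_mean = NULL, step_length_cv = 0.04,
                        step_width_mean = 0.10, step_width_cv = 0.08,
                        double_support_fraction = 0.10,
                        leg_length = 1.05, body_mass = 75,
                        mos_speed_coeffs = c(0.22, -0.12, 0.005),
                        mos_sd = 0.004, marker_noise_sd = 0.001,
                        osc_amplitude = 0.008, seed = 1L) {
  if (step_time_mean <= 0) stop("step_time_mean must be positive")
  if (double_support_fraction <= 0 || double_support_fraction >= 0.5) {
    stop("double_support_fraction must lie in (0, 0.5)")
  }
  if (any(c(step_time_cv, step_length_cv, step_width_cv) < 0)) {
    stop("coefficients of variation must be non-negative")
  }
  if (leg_length <= 0) stop("leg_length must be positive")
  vs <- seq(0.4, 1.8, by = 0.2)
  mos <- polyval_asc(mos_speed_coeffs, vs)
  if (any(diff(mos) >= 0)) {
    stop("mos_speed_coeffs must be monotone decreasing over 0.4-1.8 m/s")
  }
  structure(list(walking_speed = walking_speed,
                 step_time_mean = step_time_mean, step_time_cv = step_time_cv,
                 step_length_mean = step_length_mean,
                 step_length_cv = step_length_cv,
                 step_width_mean = step_width_mean,
                 step_width_cv = step_width_cv,
                 double_support_fraction = double_support_fraction,
                 leg_length = leg_length, body_mass = body_mass,
                 mos_speed_coeffs = mos_speed_coeffs, mos_sd = mos_sd,
                 marker_noise_sd = marker_noise_sd,
                 osc_amplitude = osc_amplitude, seed = seed),
            class = "gait_params")
}

# ascending-power polynomial evaluation: a0 + a1 x + a2 x^2 + ...
polyval_asc <- function(coeffs, x) {
  y <- 0
  for (i in seq_along(coeffs)) y <- y + coeffs[i] * x^(i - 1)
  y
}

#' Perturbation-response parameters
#'
#' Describes how the true per-step MoS deviates from baseline after a belt
#' acceleration: the first post-perturbation step deviates by
#' `initial_mos_deviation` (scaled by `(1 - adaptation_rate)^(k-1)` for the
#' k-th perturbation of the session), the deviation is held for
#' `delay_steps` further steps and then decays geometrically with ratio
#' `recovery_rate` per step; Gaussian noise of SD `response_sd` is added to
#' each of the first eight recovery steps.
#'
#' Defaults (deviation -0.15 m, recovery rate 0.8, no adaptation) give
#' recovery-step counts around 5-6 under the 0.05 m band criterion, the
#' order of magnitude reported for novel belt perturbations in older
#' adults.
#'
#' @param initial_mos_deviation signed Post1 deviation from baseline, m.
#' @param recovery_rate per-step geometric decay ratio, in (0, 1).
#' @param adaptation_rate multiplicative reduction of the deviation per
#'   perturbation repetition, in \[0, 1\].
#' @param response_sd step-to-step noise of the recovery curve, m.
#' @param delay_steps number of steps the full deviation is held before the
#'   decay begins.
#' @return object of class `"perturbation_response"`.
#' @export
perturbation_response <- function(initial_mos_deviation = -0.15,
                                  recovery_rate = 0.8,
                                  adaptation_rate = 0,
                                  response_sd = 0.01,
                                  delay_steps = 0L) {
  if (recovery_rate <= 0 || recovery_rate >= 1) {
    stop("recovery_rate must lie in (0, 1)")
  }
  if (adaptation_rate < 0 || adaptation_rate > 1) {
    stop("adaptation_rate must lie in [0, 1]")
  }
  if (response_sd < 0) stop("response_sd must be non-negative")
  if (delay_steps < 0) stop("delay_steps must be non-negative")
  structure(list(initial_mos_deviation = initial_mos_deviation,
                 recovery_rate = recovery_rate,
                 adaptation_rate = adaptation_rate,
                 response_sd = response_sd,
                 delay_steps = as.integer(delay_steps)),
            class = "perturbation_response")
}

# deterministic part of the truth deviation at post-step p (1-based) of
# perturbation k
response_deviation <- function(resp, k, p) {
  scale <- resp$initial_mos_deviation * (1 - resp$adaptation_rate)^(k - 1)
  scale * resp$recovery_rate^pmax(0, p - 1 - resp$delay_steps)
}

#' Perturbation schedule
#'
#' The protocol applies ten unannounced unilateral belt accelerations with
#' 30-90 s of unperturbed walking between them; the first and last perturb
#' the right leg, the second to ninth the left.
#'
#' @param n number of perturbations (default 10).
#' @param sides character vector of perturbed sides; default
#'   `R, L x 8, R`.
#' @param gap_range range (s) from which inter-perturbation walking gaps
#'   are drawn uniformly.
#' @param warmup unperturbed walking time before the first perturbation, s.
#' @return data frame with columns `index`, `side`, `gap`.
#' @export
perturbation_schedule <- function(n = 10,
                                  sides = c("R", rep("L", 8), "R"),
                                  gap_range = c(30, 88), warmup = 180) {
  if (length(sides) != n) stop("schedule/side mismatch: need ", n, " sides")
  if (!all(sides %in% c("L", "R"))) stop("sides must be 'L' or 'R'")
  data.frame(index = seq_len(n), side = sides,
             gap = c(warmup, runif(n - 1, gap_range[1], gap_range[2])))
}

# ---- internal planning ------------------------------------------------------

# Sample the step plan: touchdown times (grid-snapped), sides, target step
# lengths/widths and toe-off times, covering [t_start, t_end].
plan_steps <- function(params, speed, t_start, t_end) {
  L0 <- if (is.null(params$step_length_mean)) speed * params$step_time_mean
        else params$step_length_mean
  n_guess <- ceiling((t_end - t_start) / params$step_time_mean) + 4
  tt <- rlnorm_cv(n_guess, params$step_time_mean, params$step_time_cv)
  td <- snap_grid(t_start + cumsum(tt))
  while (td[length(td)] < t_end) {
    t2 <- rlnorm_cv(8, params$step_time_mean, params$step_time_cv)
    td <- c(td, snap_grid(td[length(td)] + cumsum(t2)))
  }
  td <- td[td <= t_end + 2 * params$step_time_mean]
  n <- length(td)
  side <- rep(c("L", "R"), length.out = n)
  S <- rlnorm_cv(n, L0, params$step_length_cv)
  W <- rlnorm_cv(n, params$step_width_mean, params$step_width_cv)
  # toe-off of the foot that lands at step k: one double-support episode
  # (fraction of stride) after the contralateral touchdown k+1
  stride <- c(diff(td, lag = 2), rep(2 * params$step_time_mean, 2))
  ds <- params$double_support_fraction * stride
  to <- c(snap_grid(td[-1] + ds[-n]), NA)
  list(td = td, side = side, S = S, W = W, to = to, n = n)
}

# trapezoidal belt-speed bump and its displacement integral (analytic);
# if toe-off arrives before the cap, deceleration starts from the speed
# actually reached
bump_speed <- function(t, t0, t_to, vpd, a) {
  vpd <- min(vpd, a * (t_to - t0))
  pmax(0, pmin(a * (t - t0), vpd, vpd - a * (t - t_to)))
}

bump_disp <- function(t, t0, t_to, vpd, a) {
  vpd <- min(vpd, a * (t_to - t0))
  tr <- vpd / a
  t1 <- t0 + tr          # cap reached
  t2 <- t_to + tr        # back to base speed
  out <- numeric(length(t))
  ph1 <- t > t0 & t <= t1
  out[ph1] <- a * (t[ph1] - t0)^2 / 2
  ph2 <- t > t1 & t <= t_to
  out[ph2] <- a * tr^2 / 2 + vpd * (t[ph2] - t1)
  ph3 <- t > t_to & t <= t2
  out[ph3] <- a * tr^2 / 2 + vpd * (t_to - t1) + vpd * (t[ph3] - t_to) -
    a * (t[ph3] - t_to)^2 / 2
  ph4 <- t > t2
  out[ph4] <- a * tr^2 / 2 + vpd * (t_to - t1) + vpd * tr - a * tr^2 / 2
  out
}

# belt speed / displacement for one side given base speed and bump list
belt_speed_fun <- function(t, v0, bumps) {
  v <- rep(v0, length(t))
  for (b in bumps) v <- v + bump_speed(t, b$t0, b$t_to, b$vpd, b$a)
  v
}

belt_disp_fun <- function(t, v0, bumps) {
  d <- v0 * t
  for (b in bumps) d <- d + bump_disp(t, b$t0, b$t_to, b$vpd, b$a)
  d
}

# ---- trajectory assembly ----------------------------------------------------

# Build per-side hallux trajectories on the grid from the step plan and
# touchdown positions. Returns list L/R of n x 3 matrices.
build_feet <- function(time, plan, x_td, y_td, belt_bumps, v_base,
                       z0 = 0.02, swing_h = 0.06) {
  feet <- list()
  for (s in c("L", "R")) {
    idx <- which(plan$side == s)
    x <- rep(NA_real_, length(time)); y <- x; z <- x
    for (j in seq_along(idx)) {
      k <- idx[j]
      t_td <- plan$td[k]
      t_to <- plan$to[k]
      t_next <- if (j < length(idx)) plan$td[idx[j + 1]] else NA
      # stance: advected backward by this side's belt
      t_end_st <- if (is.na(t_to)) time[length(time)] + 1 else t_to
      v_land <- belt_speed_fun(t_td, v_base, belt_bumps[[s]])
      in_st <- time >= t_td & time < t_end_st
      if (any(in_st)) {
        disp <- belt_disp_fun(time[in_st], v_base, belt_bumps[[s]]) -
          belt_disp_fun(t_td, v_base, belt_bumps[[s]])
        x[in_st] <- x_td[k] - disp + stance_lag(time[in_st] - t_td, v_land)
        y[in_st] <- y_td[k]
        z[in_st] <- z0
      }
      # swing: minimum-jerk transport to the next touchdown position
      if (!is.na(t_to) && !is.na(t_next) && t_next > t_to) {
        in_sw <- time >= t_to & time < t_next
        if (any(in_sw)) {
          tau <- (time[in_sw] - t_to) / (t_next - t_to)
          x_to <- x_td[k] - (belt_disp_fun(t_to, v_base, belt_bumps[[s]]) -
                               belt_disp_fun(t_td, v_base, belt_bumps[[s]])) +
            stance_lag(t_to - t_td, v_land)
          kn <- idx[j + 1]
          x[in_sw] <- x_to + (x_td[kn] - x_to) * minjerk(tau)
          y[in_sw] <- y_td[k] + (y_td[kn] - y_td[k]) * minjerk(tau)
          z[in_sw] <- z0 + swing_h * sin(pi * tau)^2
        }
      }
    }
    # frames before the side's first touchdown: hold the first stance pose
    first_na <- is.na(x)
    if (any(first_na)) {
      k1 <- idx[1]
      x[first_na] <- x_td[k1]; y[first_na] <- y_td[k1]; z[first_na] <- z0
    }
    feet[[s]] <- cbind(x = x, y = y, z = z)
  }
  feet
}

# CoM-proxy AP trajectory: piecewise quintic Hermite through knots
# (p_k, w_k) at the touchdown instants with zero acceleration at knots,
# plus an intra-step oscillation that vanishes to second order there.
# Prescribing the knot velocity lets the belt-speed term of the XCoM be
# absorbed by CoM velocity rather than position, which keeps the
# trajectory's curvature physiological even during belt perturbations.
build_com_ap <- function(time, td, p, w, side, osc_amp) {
  x <- rep(p[1], length(time))
  for (k in seq_len(length(td) - 1)) {
    in_seg <- time >= td[k] & time < td[k + 1]
    if (!any(in_seg)) next
    h <- td[k + 1] - td[k]
    tau <- (time[in_seg] - td[k]) / h
    H0 <- 1 - 10 * tau^3 + 15 * tau^4 - 6 * tau^5
    H1 <- tau - 6 * tau^3 + 8 * tau^4 - 3 * tau^5
    H3 <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    H4 <- -4 * tau^3 + 7 * tau^4 - 3 * tau^5
    sgn <- if (side[k] == "L") 1 else -1
    x[in_seg] <- p[k] * H0 + h * w[k] * H1 + p[k + 1] * H3 +
      h * w[k + 1] * H4 + sgn * osc_amp * sin(pi * tau)^3
  }
  x[time >= td[length(td)]] <- p[length(td)]
  x
}

# vertical GRF for one side: trapezoid per stance scaled to body weight
build_forces <- function(ftime, plan, side, body_mass, rise_cap = 0.10) {
  bw <- body_mass * 9.81
  f <- numeric(length(ftime))
  idx <- which(plan$side == side)
  for (k in idx) {
    t_td <- plan$td[k]
    t_to <- plan$to[k]
    if (is.na(t_to)) t_to <- ftime[length(ftime)] + 1
    rt <- min(rise_cap, (t_to - t_td) / 3)
    sel <- ftime >= t_td & ftime <= t_to
    if (!any(sel)) next
    t <- ftime[sel]
    f[sel] <- f[sel] + bw * pmax(0, pmin(1, (t - t_td) / rt, (t_to - t) / rt))
  }
  f
}

# ---- simulators -------------------------------------------------------------

# shared core: builds a session from a step plan, belt bumps and truth MoS
assemble_session <- function(params, v_base, duration, plan, x_td, y_td,
                             belt_bumps, mos_truth, pert_times, pert_table,
                             trial_label) {
  time <- seq(0, duration, by = MARKER_DT)
  l <- params$leg_length
  omega0 <- sqrt(9.81 / l)

  # knot constraints for the inverse-designed CoM: at each touchdown the
  # pipeline's XCoM, p_k + (w_k + v_belt_k) / omega0, must equal
  # hallux - MoS. The knot velocity absorbs the belt term
  # (w_k = v_base - v_belt_k), so knot positions stay smooth
  v_at_td <- vapply(seq_len(plan$n), function(k) {
    belt_speed_fun(plan$td[k], v_base, belt_bumps[[plan$side[k]]])
  }, numeric(1))
  X_knot <- x_td - mos_truth
  w_knot <- v_base - v_at_td
  p_knot <- X_knot - v_base / omega0
  com_ap <- build_com_ap(time, plan$td, p_knot, w_knot, plan$side,
                         params$osc_amplitude)

  feet <- build_feet(time, plan, x_td, y_td, belt_bumps, v_base)

  # trunk/pelvis markers ride on the CoM proxy; heights are chosen so the
  # default proxy weights (0.5, 0.3, 0.2) put the proxy exactly leg_length
  # above the stance hallux height
  sway <- 0.015 * sin(2 * pi * time / (2 * params$step_time_mean))
  bob <- 0.01 * sin(4 * pi * time / (2 * params$step_time_mean))
  z_sacr <- l - 0.11; z_tro <- l - 0.13; z_c7 <- l + 0.47
  mk <- list(
    C7 = cbind(com_ap, sway, z_c7 + 0.02 + bob),
    SACR = cbind(com_ap, sway, z_sacr + 0.02 + bob),
    LTRO = cbind(com_ap, sway + 0.10, z_tro + 0.02 + bob),
    RTRO = cbind(com_ap, sway - 0.10, z_tro + 0.02 + bob),
    LHLX = feet$L, RHLX = feet$R)
  if (params$marker_noise_sd > 0) {
    mk <- lapply(mk, function(m) {
      m + matrix(rnorm(length(m), 0, params$marker_noise_sd), nrow = nrow(m))
    })
  }
  mk <- lapply(mk, function(m) { colnames(m) <- c("x", "y", "z"); m })

  belt_l <- belt_speed_fun(time, v_base, belt_bumps$L)
  belt_r <- belt_speed_fun(time, v_base, belt_bumps$R)

  ftime <- seq(0, duration, by = FORCE_DT)
  forces <- list(time = ftime,
                 left = build_forces(ftime, plan, "L", params$body_mass),
                 right = build_forces(ftime, plan, "R", params$body_mass))

  keep <- plan$td >= 0 & plan$td <= duration
  tds <- data.frame(time = plan$td[keep], side = plan$side[keep])
  keep_to <- !is.na(plan$to) & plan$to >= 0 & plan$to <= duration
  tos <- data.frame(time = plan$to[keep_to], side = plan$side[keep_to])
  tos <- tos[order(tos$time), , drop = FALSE]

  ses <- gait_session(time, mk, belt_l, belt_r, forces = forces,
                      trial_label = trial_label)
  ses$truth <- list(
    events = gait_events(tds, tos),
    mos = data.frame(touchdown_time = plan$td[keep], side = plan$side[keep],
                     mos_ap = mos_truth[keep]),
    step_length = plan$S[keep], step_width = plan$W[keep],
    pert_times = pert_times, pert_table = pert_table,
    group = NA_character_)
  class(ses) <- c("synthetic_session", class(ses))
  ses
}

#' Simulate an unperturbed treadmill walking trial
#'
#' Generates markers (100 Hz), dual-belt vertical forces (1000 Hz), belt
#' speed series and full ground truth (events, per-step MoS) for steady
#' walking at `speed`.
#'
#' @param params a [gait_params()] object.
#' @param speed belt speed, m/s, in \[0.2, 2.5\].
#' @param duration trial duration, s (at least 10).
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a `synthetic_session` (subclass of [gait_session()]) with a
#'   `truth` element.
#' @export
simulate_gait_trial <- function(params, speed = params$walking_speed,
                                duration = 60, seed = params$seed) {
  if (speed < 0.2 || speed > 2.5) stop("speed must lie in [0.2, 2.5] m/s")
  if (duration < 10) stop("duration must be at least 10 s")
  set.seed(seed)
  plan <- plan_steps(params, speed, t_start = -2, t_end = duration + 1.5)
  mos_truth <- polyval_asc(params$mos_speed_coeffs, speed) +
    rnorm(plan$n, 0, params$mos_sd)
  # touchdown positions: previous foot advected + target step length
  x_td <- numeric(plan$n)
  x_td[1] <- 0.1
  for (k in 2:plan$n) {
    dt_k <- plan$td[k] - plan$td[k - 1]
    trail <- x_td[k - 1] - speed * dt_k + stance_lag(dt_k, speed)
    x_td[k] <- trail + plan$S[k]
  }
  y_td <- ifelse(plan$side == "L", 1, -1) * plan$W / 2
  bumps <- list(L = list(), R = list())
  assemble_session(params, speed, duration, plan, x_td, y_td, bumps,
                   mos_truth, pert_times = numeric(0), pert_table = NULL,
                   trial_label = sprintf("synthetic_%.1fms", speed))
}

#' Simulate a full belt-acceleration perturbation session
#'
#' Walks at the base speed and applies the scheduled unilateral belt
#' accelerations. Each perturbation is triggered at the instant the
#' to-be-perturbed hallux passes the contralateral hallux in the sagittal
#' plane (mid-swing); the perturbed belt then accelerates at
#' `accel` m/s^2 to `speed_factor` times the base speed and decelerates
#' symmetrically at the perturbed foot's subsequent toe-off. True
#' post-perturbation MoS deviations follow the [perturbation_response()]
#' model, with across-perturbation adaptation.
#'
#' @param params a [gait_params()] object.
#' @param resp a [perturbation_response()] object.
#' @param schedule a [perturbation_schedule()] data frame (`index`, `side`,
#'   `gap`); gaps are consumed as trigger-to-trigger walking times.
#' @param speed base belt speed, m/s.
#' @param accel belt acceleration, m/s^2 (protocol value 3).
#' @param speed_factor peak speed as a multiple of base speed (protocol
#'   value 1.8).
#' @param tail unperturbed walking after the last perturbation, s.
#' @param seed RNG seed.
#' @return a `synthetic_session` whose `truth` element includes
#'   `pert_times` (trigger instants) and `pert_table` (index, side, onset).
#' @export
simulate_perturbation_session <- function(params, resp,
                                          schedule = NULL,
                                          speed = params$walking_speed,
                                          accel = 3, speed_factor = 1.8,
                                          tail = 15, seed = params$seed) {
  set.seed(seed)
  if (is.null(schedule)) schedule <- perturbation_schedule()
  if (!all(c("index", "side", "gap") %in% names(schedule))) {
    stop("schedule must have columns index, side, gap")
  }
  if (!all(schedule$side %in% c("L", "R"))) {
    stop("schedule sides must be 'L' or 'R'")
  }
  if (accel <= 0 || speed_factor <= 1) {
    stop("need accel > 0 and speed_factor > 1")
  }
  n_pert <- nrow(schedule)
  duration <- sum(schedule$gap) + 10 * 2 * params$step_time_mean + tail
  plan <- plan_steps(params, speed, t_start = -2, t_end = duration + 1.5)
  n <- plan$n
  base_mos <- polyval_asc(params$mos_speed_coeffs, speed) +
    rnorm(n, 0, params$mos_sd)
  resp_noise <- matrix(rnorm(n_pert * 8, 0, resp$response_sd), nrow = n_pert)

  bumps <- list(L = list(), R = list())
  x_td <- numeric(n); x_td[1] <- 0.1
  y_td <- ifelse(plan$side == "L", 1, -1) * plan$W / 2
  mos_truth <- base_mos
  vpd_cap <- (speed_factor - 1) * speed

  trigger <- rep(NA_real_, n_pert)
  onset_step <- rep(NA_integer_, n_pert)
  next_pert <- 1L
  next_due <- schedule$gap[1]
  bonus <- numeric(n)  # forward re-centring added to step-length targets

  for (k in 2:n) {
    s <- plan$side[k]; s_opp <- plan$side[k - 1]
    v_land_opp <- belt_speed_fun(plan$td[k - 1], speed, bumps[[s_opp]])
    trail <- x_td[k - 1] -
      (belt_disp_fun(plan$td[k], speed, bumps[[s_opp]]) -
         belt_disp_fun(plan$td[k - 1], speed, bumps[[s_opp]])) +
      stance_lag(plan$td[k] - plan$td[k - 1], v_land_opp)
    x_td[k] <- trail + plan$S[k] + bonus[k]

    # does this step's swing host the next scheduled perturbation?
    same_prev <- if (k > 2) k - 2 else NA
    if (next_pert <= n_pert && !is.na(same_prev) &&
        s == schedule$side[next_pert] && !is.na(plan$to[same_prev]) &&
        plan$to[same_prev] >= next_due) {
      t_sw0 <- plan$to[same_prev]
      v_land_same <- belt_speed_fun(plan$td[same_prev], speed, bumps[[s]])
      x_sw0 <- x_td[same_prev] -
        (belt_disp_fun(t_sw0, speed, bumps[[s]]) -
           belt_disp_fun(plan$td[same_prev], speed, bumps[[s]])) +
        stance_lag(t_sw0 - plan$td[same_prev], v_land_same)
      tg <- seq(t_sw0, plan$td[k], by = MARKER_DT)
      tau <- (tg - t_sw0) / (plan$td[k] - t_sw0)
      x_swing <- x_sw0 + (x_td[k] - x_sw0) * minjerk(tau)
      x_opp <- x_td[k - 1] -
        (belt_disp_fun(tg, speed, bumps[[s_opp]]) -
           belt_disp_fun(plan$td[k - 1], speed, bumps[[s_opp]])) +
        stance_lag(tg - plan$td[k - 1], v_land_opp)
      cross <- which(x_swing >= x_opp & tg >= plan$td[k - 1])
      if (length(cross) > 0) {
        t0 <- snap_grid(tg[cross[1]])
        t_to <- plan$to[k]  # toe-off of the perturbed foot's stance
        if (is.na(t_to)) t_to <- plan$td[k] + 2 * params$step_time_mean
        bump <- list(t0 = t0, t_to = t_to, vpd = vpd_cap, a = accel)
        bumps[[s]] <- c(bumps[[s]], list(bump))
        trigger[next_pert] <- t0
        onset_step[next_pert] <- k
        # spread the extra belt displacement over the next 6 steps so the
        # subject re-centres on the treadmill
        extra <- bump_disp(t_to + vpd_cap / accel + 1, t0, t_to, vpd_cap,
                           accel)
        ahead <- (k + 1):min(n, k + 6)
        bonus[ahead] <- bonus[ahead] + extra / length(ahead)
        if (next_pert < n_pert) next_due <- t0 + schedule$gap[next_pert + 1]
        next_pert <- next_pert + 1L
      }
    }
  }

  # truth MoS deviations after each onset
  for (j in seq_len(n_pert)) {
    if (is.na(trigger[j])) next
    post_idx <- which(plan$td >= trigger[j])
    if (j < n_pert && !is.na(trigger[j + 1])) {
      post_idx <- post_idx[plan$td[post_idx] < trigger[j + 1]]
    }
    p <- seq_along(post_idx)
    dev <- response_deviation(resp, schedule$index[j], p)
    noise <- ifelse(p <= 8, resp_noise[j, pmin(p, 8)], 0)
    mos_truth[post_idx] <- mos_truth[post_idx] + dev + noise
  }

  done <- !is.na(trigger)
  pert_table <- data.frame(index = schedule$index[done],
                           side = schedule$side[done],
                           onset = trigger[done])
  ses <- assemble_session(params, speed, duration, plan, x_td, y_td, bumps,
                          mos_truth, pert_times = trigger[done],
                          pert_table = pert_table,
                          trial_label = "synthetic_perturbation")
  if (any(!done)) {
    warning(sum(!done), " scheduled perturbation(s) could not be placed")
  }
  ses
}

# ---- truth-level cohort generator ------------------------------------------

#' Simulate a labelled-step cohort at the response-model level
#'
#' Draws the Base/Pre/Post1-8 MoS table that the group-comparison statistics
#' consume directly from the perturbation-response model, without kinematic
#' synthesis: per participant, per perturbation, each of the ten step cells
#' is baseline (participant effect + noise) plus, for post steps, the
#' deterministic response deviation. Noise is homoscedastic across cells and
#' the participant effect induces compound symmetry, so the uncorrected
#' mixed-ANOVA F is exactly calibrated under a group null.
#'
#' @param n participants.
#' @param resp a [perturbation_response()].
#' @param n_pert perturbations per participant (default 10, sides R, L x 8,
#'   R).
#' @param base_mos group-level baseline MoS, m (0.05 at the
#'   stability-normalised speed).
#' @param between_sd SD of the participant baseline effect, m.
#' @param noise_sd within-participant step noise, m.
#' @param group group label stored in the output.
#' @param participant_prefix prefix for participant ids.
#' @return long data frame: `participant`, `group`, `pert`, `step` (factor
#'   Base, Pre, Post1..Post8), `mos`.
#' @export
simulate_recovery_cohort <- function(n, resp, n_pert = 10, base_mos = 0.05,
                                     between_sd = 0.01, noise_sd = 0.01,
                                     group = "G", participant_prefix = "P") {
  steps <- c("Base", "Pre", paste0("Post", 1:8))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    b_i <- base_mos + rnorm(1, 0, between_sd)
    rows <- vector("list", n_pert)
    for (j in seq_len(n_pert)) {
      dev <- c(0, 0, response_deviation(resp, j, 1:8))
      rows[[j]] <- data.frame(
        participant = paste0(participant_prefix, i), group = group,
        pert = j, step = steps,
        mos = b_i + dev + rnorm(10, 0, noise_sd))
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res$step <- factor(res$step, levels = steps)
  res
}

#' Recovery-step counts from a labelled-step cohort
#'
#' Applies the backward band-scan recovery criterion to each participant x
#' perturbation cell of a [simulate_recovery_cohort()] table.
#'
#' @param cohort long data frame from [simulate_recovery_cohort()].
#' @param tolerance recovery band half-width, m (default 0.05).
#' @return data frame: `participant`, `group`, `pert`, `recovery_steps`.
#' @export
cohort_recovery_steps <- function(cohort, tolerance = 0.05) {
  cells <- unique(cohort[, c("participant", "group", "pert")])
  cells$recovery_steps <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    sub <- cohort[cohort$participant == cells$participant[i] &
                    cohort$pert == cells$pert[i], ]
    lp <- labeled_perturbation(
      onset_time = cells$pert[i],
      base_mos = sub$mos[sub$step == "Base"],
      pre_mos = sub$mos[sub$step == "Pre"],
      post_mos = sub$mos[match(paste0("Post", 1:8), sub$step)])
    cells$recovery_steps[i] <- count_recovery_steps(lp, tolerance)
  }
  rownames(cells) <- NULL
  cells
}
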