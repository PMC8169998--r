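# Perturbation triggering, belt profiles, step labelling and recovery
# counting.

#' Perturbation specification
#'
#' @param acceleration belt acceleration, m/s^2 (protocol value 3).
#' @param speed_factor peak speed as a multiple of the base speed (protocol
#'   value 1.8).
#' @param side perturbed side, "L" or "R".
#' @param index position in the session's schedule (1-10).
#' @return object of class `"perturbation_spec"`.
#' @export
perturbation_spec <- function(acceleration = 3, speed_factor = 1.8,
                              side = "R", index = 1L) {
  if (acceleration <= 0) stop("acceleration must be positive")
  if (speed_factor <= 1) stop("speed_factor must exceed 1")
  if (!side %in% c("L", "R")) stop("side must be 'L' or 'R'")
  structure(list(acceleration = acceleration, speed_factor = speed_factor,
                 side = side, index = as.integer(index)),
            class = "perturbation_spec")
}

#' Perturbation trigger instant from hallux kinematics
#'
#' The belt acceleration is triggered when the hallux of the to-be-perturbed
#' limb passes the hallux of the opposite foot in the sagittal plane: the
#' first instant in the search window at which the AP hallux difference
#' (perturbed minus opposite) crosses zero from negative to positive.
#'
#' @param session a [gait_session()].
#' @param side perturbed side, "L" or "R".
#' @param search_window numeric length-2, seconds.
#' @return trigger time, s.
#' @export
trigger_time <- function(session, side, search_window) {
  if (search_window[1] < min(session$time) ||
      search_window[2] > max(session$time)) {
    stop("search window outside the session")
  }
  opp <- if (side == "L") "R" else "L"
  d <- session$markers[[paste0(side, "HLX")]][, 1] -
    session$markers[[paste0(opp, "HLX")]][, 1]
  sel <- session$time >= search_window[1] & session$time <= search_window[2]
  t <- session$time[sel]; dd <- d[sel]
  up <- which(dd[-1] >= 0 & dd[-length(dd)] < 0)
  if (length(up) == 0) {
    stop("perturbed-side hallux never passes the opposite hallux in the ",
         "search window")
  }
  t[up[1] + 1]
}

#' Belt speed profile of one perturbation
#'
#' Ramp from the base speed at the configured acceleration, capped at
#' `speed_factor` times the base speed, held until the perturbed limb's
#' toe-off, then a symmetric deceleration back to the base speed.
#'
#' @param spec a [perturbation_spec()].
#' @param v0 base belt speed, m/s.
#' @param t_trigger,t_toeoff trigger and toe-off instants, s.
#' @param time evaluation time grid, s.
#' @return belt speed series over `time`, m/s.
#' @export
belt_profile <- function(spec, v0, t_trigger, t_toeoff, time) {
  if (v0 <= 0) stop("base speed must be positive")
  if (t_toeoff <= t_trigger) stop("toe-off must follow the trigger")
  vpd <- (spec$speed_factor - 1) * v0
  v0 + bump_speed(time, t_trigger, t_toeoff, vpd, spec$acceleration)
}

#' Labelled steps around one perturbation
#'
#' Steps are indexed by touchdown time relative to the onset: Base is the
#' mean MoS of the eleventh-to-second-last steps before the perturbation
#' (10 steps), Pre is the final step before it, and Post1-8 are the first
#' eight recovery steps. A touchdown exactly at the onset counts as Post1.
#'
#' @param mos a `mos_series` (see [compute_mos()]), or any data frame with
#'   `touchdown_time` and `mos_ap`.
#' @param onset_time perturbation onset, s.
#' @return object of class `"labeled_perturbation"`.
#' @export
label_steps <- function(mos, onset_time) {
  pre_idx <- which(mos$touchdown_time < onset_time)
  post_idx <- which(mos$touchdown_time >= onset_time)
  if (length(pre_idx) < 11 || length(post_idx) < 8) {
    stop("insufficient steps around the onset: need 11 before and 8 ",
         "after, have ", length(pre_idx), " and ", length(post_idx))
  }
  pre_vals <- mos$mos_ap[pre_idx]
  n <- length(pre_vals)
  base <- mean(pre_vals[(n - 10):(n - 1)])   # steps -11 .. -2
  pre <- pre_vals[n]                         # step -1
  post <- mos$mos_ap[post_idx[1:8]]
  labeled_perturbation(onset_time, base, pre, post,
                       post_times = mos$touchdown_time[post_idx[1:8]])
}

#' Construct a labelled perturbation record
#'
#' @param onset_time perturbation onset, s.
#' @param base_mos baseline MoS (mean of steps -11..-2), m.
#' @param pre_mos MoS of the final pre-perturbation step, m.
#' @param post_mos numeric length-8, MoS of Post1-8, m.
#' @param post_times optional touchdown times of the post steps.
#' @return object of class `"labeled_perturbation"`.
#' @export
labeled_perturbation <- function(onset_time, base_mos, pre_mos, post_mos,
                                 post_times = NULL) {
  if (length(post_mos) != 8 || anyNA(post_mos)) {
    stop("post_mos must hold 8 non-missing values")
  }
  structure(list(onset_time = onset_time, base_mos = base_mos,
                 pre_mos = pre_mos, post_mos = post_mos,
                 post_times = post_times),
            class = "labeled_perturbation")
}

#' @export
print.labeled_perturbation <- function(x, ...) {
  cat(sprintf("<labeled_perturbation> onset %.2f s\n", x$onset_time))
  cat(sprintf("  Base %.3f m | Pre %.3f m\n", x$base_mos, x$pre_mos))
  cat("  Post1-8:", paste(sprintf("%.3f", x$post_mos), collapse = " "), "\n")
  invisible(x)
}

#' Count recovery steps by the backward band scan
#'
#' Let k be the number of consecutive post-perturbation steps, counting
#' backward from the eighth recovery step, whose MoS lies within
#' `tolerance` of the Base value. The recovery-step count is `8 - k`; if
#' Post8 itself is out of band the count is 8 regardless of earlier steps
#' (an in-band run interrupted by a later out-of-band step does not count
#' as recovered).
#'
#' @param labeled a [labeled_perturbation()].
#' @param tolerance band half-width around Base, m (protocol value 0.05).
#' @return integer in 0..8.
#' @export
count_recovery_steps <- function(labeled, tolerance = 0.05) {
  in_band <- abs(labeled$post_mos - labeled$base_mos) <= tolerance
  k <- 0L
  for (i in 8:1) {
    if (!in_band[i]) break
    k <- k + 1L
  }
  8L - k
}

#' Label and count every perturbation of a session
#'
#' @param mos a `mos_series` for the whole session.
#' @param onsets perturbation onset times, s (e.g. the session's
#'   `truth$pert_times` or detected triggers).
#' @param tolerance recovery band half-width, m.
#' @return data frame: `index`, `onset`, `base`, `pre`, `post1`..`post8`,
#'   `recovery_steps`.
#' @export
analyze_perturbations <- function(mos, onsets, tolerance = 0.05) {
  rows <- lapply(seq_along(onsets), function(j) {
    lab <- label_steps(mos, onsets[j])
    out <- data.frame(index = j, onset = onsets[j], base = lab$base_mos,
                      pre = lab$pre_mos)
    for (p in 1:8) out[[paste0("post", p)]] <- lab$post_mos[p]
    out$recovery_steps <- count_recovery_steps(lab, tolerance)
    out
  })
  do.call(rbind, rows)
}
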