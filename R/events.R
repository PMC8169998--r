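# Gait event detection: force-plate thresholding with a marker fallback.

#' Construct a gait event set
#'
#' @param touchdowns,toeoffs data frames with columns `time` (s) and `side`
#'   ("L"/"R"), times strictly increasing within each table.
#' @return object of class `"gait_events"`.
#' @export
gait_events <- function(touchdowns, toeoffs) {
  for (tb in list(touchdowns, toeoffs)) {
    if (nrow(tb) > 1 && any(diff(tb$time) <= 0)) {
      stop("event times must be strictly increasing")
    }
    if (nrow(tb) > 0 && !all(tb$side %in% c("L", "R"))) {
      stop("side must be 'L' or 'R'")
    }
  }
  structure(list(touchdowns = touchdowns, toeoffs = toeoffs),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events>", nrow(x$touchdowns), "touchdowns,",
      nrow(x$toeoffs), "toe-offs\n")
  invisible(x)
}

# threshold crossings of one belt's vertical force
crossings_one_belt <- function(force, time, threshold, min_sustain,
                               debounce) {
  above <- force > threshold
  d <- diff(as.integer(above))
  up <- which(d == 1) + 1     # first sample above
  down <- which(d == -1) + 1  # first sample below
  dt <- time[2] - time[1]
  sustain_n <- max(1L, round(min_sustain / dt))
  keep_sustained <- function(idx, state) {
    ok <- vapply(idx, function(i) {
      j <- min(length(above), i + sustain_n - 1L)
      all(above[i:j] == state)
    }, logical(1))
    idx[ok]
  }
  up <- keep_sustained(up, TRUE)
  down <- keep_sustained(down, FALSE)
  merge_close <- function(idx) {
    if (length(idx) < 2) return(idx)
    keep <- c(TRUE, diff(time[idx]) > debounce)
    idx[keep]
  }
  list(td = time[merge_close(up)], to = time[merge_close(down)])
}

#' Detect gait events from dual-belt vertical forces
#'
#' Touchdown is an upward crossing of `threshold` sustained for at least
#' `min_sustain` seconds; toe-off is the corresponding sustained downward
#' crossing. Crossings closer than `debounce` seconds are merged.
#'
#' @param forces list with `time`, `left`, `right` (N).
#' @param threshold force threshold in N (default 50, a conventional
#'   treadmill contact threshold).
#' @param min_sustain minimum time the signal must stay on the new side of
#'   the threshold, s.
#' @param debounce minimum separation of same-type events, s.
#' @return a [gait_events()] object. If no belt ever crosses the threshold
#'   an empty event set is returned with a warning.
#' @export
detect_events_force <- function(forces, threshold = 50, min_sustain = 0.02,
                                debounce = 0.05) {
  if (threshold <= 0) stop("threshold must be positive")
  l <- crossings_one_belt(forces$left, forces$time, threshold, min_sustain,
                          debounce)
  r <- crossings_one_belt(forces$right, forces$time, threshold, min_sustain,
                          debounce)
  td <- rbind(data.frame(time = l$td, side = rep("L", length(l$td))),
              data.frame(time = r$td, side = rep("R", length(r$td))))
  to <- rbind(data.frame(time = l$to, side = rep("L", length(l$to))),
              data.frame(time = r$to, side = rep("R", length(r$to))))
  if (nrow(td) == 0) warning("no force threshold crossings; empty event set")
  gait_events(td[order(td$time), , drop = FALSE],
              to[order(to$time), , drop = FALSE])
}

# indices of strict local maxima separated by >= min_sep samples
local_maxima <- function(x, min_sep) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1
  if (length(cand) == 0) return(integer(0))
  # greedy thinning: keep the larger of any pair closer than min_sep
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) > 0 && i - keep[length(keep)] < min_sep) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  keep
}

#' Detect gait events from hallux kinematics
#'
#' On a treadmill the hallux moves backward with the belt during stance and
#' forward during swing, so its anteroposterior position peaks at touchdown
#' and troughs at toe-off. Events are local extrema of each side's
#' (low-pass filtered) hallux AP trajectory.
#'
#' @param session a [gait_session()] (filter first, see [filter_session()]).
#' @param min_step_time minimum credible step time in s; extrema closer
#'   together are treated as noise.
#' @return a [gait_events()] object.
#' @export
detect_events_marker <- function(session, min_step_time = 0.3) {
  rate <- session$rate_markers
  sep <- round(min_step_time * 2 * rate * 0.7)  # ~stride spacing per side
  td <- NULL; to <- NULL
  for (side in c("L", "R")) {
    ap <- session$markers[[paste0(side, "HLX")]][, 1]
    imax <- local_maxima(ap, sep)
    imin <- local_maxima(-ap, sep)
    td <- rbind(td, data.frame(time = session$time[imax],
                               side = rep(side, length(imax))))
    to <- rbind(to, data.frame(time = session$time[imin],
                               side = rep(side, length(imin))))
  }
  if (nrow(td) < 4) stop("fewer than two gait cycles detected from markers")
  gait_events(td[order(td$time), , drop = FALSE],
              to[order(to$time), , drop = FALSE])
}

#' Reconcile force- and marker-based events
#'
#' Force-derived events are authoritative; where the merged touchdown
#' stream violates left/right alternation the later event of the offending
#' same-side pair is dropped (with a warning).
#'
#' @param force_events,marker_events [gait_events()] objects; either may be
#'   `NULL`.
#' @return a [gait_events()] object with alternating touchdown sides.
#' @export
reconcile_events <- function(force_events, marker_events = NULL) {
  ev <- if (!is.null(force_events) && nrow(force_events$touchdowns) > 0) {
    force_events
  } else {
    marker_events
  }
  if (is.null(ev)) stop("no events to reconcile")
  td <- ev$touchdowns
  if (nrow(td) > 1) {
    bad <- which(td$side[-1] == td$side[-nrow(td)]) + 1
    if (length(bad) > 0) {
      warning(length(bad), " touchdown(s) dropped to restore alternation")
      td <- td[-bad, , drop = FALSE]
    }
  }
  gait_events(td, ev$toeoffs)
}
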