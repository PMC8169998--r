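# Session container and marker/force I/O.

REQUIRED_MARKERS <- c("C7", "SACR", "LTRO", "RTRO", "LHLX", "RHLX")

#' Construct a gait session
#'
#' Bundles the six-marker trajectories, belt-speed commands and (optionally)
#' the dual-belt vertical ground reaction forces for one treadmill trial.
#' All marker series share the 100 Hz time grid `time`; forces live on their
#' own 1000 Hz grid.
#'
#' @param time numeric vector, seconds, regular grid (markers).
#' @param markers named list of n-by-3 matrices (columns x = anterior,
#'   y = left, z = up, metres). Must contain `C7, SACR, LTRO, RTRO, LHLX,
#'   RHLX`.
#' @param belt_left,belt_right belt speed series (m/s) on the marker grid.
#' @param forces optional list with elements `time`, `left`, `right`:
#'   vertical force (N) per belt at `rate_forces`.
#' @param trial_label free-text label.
#' @param rate_markers,rate_forces sampling rates in Hz.
#' @return An object of class `"gait_session"`.
#' @export
gait_session <- function(time, markers, belt_left, belt_right, forces = NULL,
                         trial_label = "", rate_markers = 100,
                         rate_forces = 1000) {
  stopifnot(is.numeric(time), length(time) > 1)
  missing_m <- setdiff(REQUIRED_MARKERS, names(markers))
  if (length(missing_m) > 0) {
    stop("missing required marker(s): ", paste(missing_m, collapse = ", "))
  }
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6)) stop("irregular marker time base")
  n <- length(time)
  for (m in REQUIRED_MARKERS) {
    xyz <- markers[[m]]
    if (!is.matrix(xyz) || nrow(xyz) != n || ncol(xyz) != 3) {
      stop("marker ", m, " must be a ", n, "-by-3 matrix")
    }
  }
  if (length(belt_left) != n || length(belt_right) != n) {
    stop("belt speed series must match the marker grid")
  }
  structure(
    list(time = time, markers = markers[REQUIRED_MARKERS],
         belt_left = as.numeric(belt_left),
         belt_right = as.numeric(belt_right),
         forces = forces, trial_label = trial_label,
         rate_markers = rate_markers, rate_forces = rate_forces),
    class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  cat("<gait_session>", if (nzchar(x$trial_label)) x$trial_label else "",
      "\n  duration:", sprintf("%.2f s", diff(range(x$time))),
      "(", length(x$time), "frames @", x$rate_markers, "Hz )\n")
  cat("  belt speed:", sprintf("%.2f-%.2f m/s",
                               min(x$belt_left, x$belt_right),
                               max(x$belt_left, x$belt_right)), "\n")
  cat("  forces:", if (is.null(x$forces)) "absent" else
    paste0(length(x$forces$time), " samples @ ", x$rate_forces, " Hz"), "\n")
  invisible(x)
}

#' Belt speed of the stance side at each marker frame
#'
#' The stance side at time t is the side of the most recent touchdown at or
#' before t (before the first touchdown, the first event's side is used).
#'
#' @param session a [gait_session()].
#' @param touchdowns data frame with columns `time`, `side` ("L"/"R").
#' @return numeric vector on the marker grid.
#' @keywords internal
stance_belt_speed <- function(session, touchdowns) {
  idx <- findInterval(session$time, touchdowns$time)
  idx[idx < 1] <- 1
  side <- as.character(touchdowns$side)[idx]
  ifelse(side == "L", session$belt_left, session$belt_right)
}

# ---- CSV dialect -----------------------------------------------------------
# markers file: time, C7_x, C7_y, C7_z, ..., RHLX_z, belt_left, belt_right
# forces file:  time, force_left, force_right

#' Write a session to CSV files
#'
#' Writes `<prefix>_markers.csv` (and `<prefix>_forces.csv` if forces are
#' present). Synthetic sessions additionally get a `<prefix>_truth.json`
#' sidecar with the generator's ground truth.
#'
#' @param session a [gait_session()].
#' @param prefix path prefix (directory must exist).
#' @return `prefix`, invisibly.
#' @export
write_session <- function(session, prefix) {
  df <- data.frame(time = session$time)
  for (m in REQUIRED_MARKERS) {
    xyz <- session$markers[[m]]
    df[[paste0(m, "_x")]] <- xyz[, 1]
    df[[paste0(m, "_y")]] <- xyz[, 2]
    df[[paste0(m, "_z")]] <- xyz[, 3]
  }
  df$belt_left <- session$belt_left
  df$belt_right <- session$belt_right
  write.csv(df, paste0(prefix, "_markers.csv"), row.names = FALSE)
  if (!is.null(session$forces)) {
    fdf <- data.frame(time = session$forces$time,
                      force_left = session$forces$left,
                      force_right = session$forces$right)
    write.csv(fdf, paste0(prefix, "_forces.csv"), row.names = FALSE)
  }
  if (!is.null(session$truth)) {
    truth <- session$truth
    out <- list(
      touchdowns = truth$events$touchdowns,
      toeoffs = truth$events$toeoffs,
      mos = truth$mos,
      pert_times = truth$pert_times,
      group = truth$group)
    jsonlite::write_json(out, paste0(prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(prefix)
}

#' Read a session from CSV files
#'
#' Reads the CSV dialect written by [write_session()]. Marker gaps (`NA`
#' runs) of at most `max_gap` frames are linearly interpolated; longer gaps
#' are an error. Column names can be remapped through `alias` (a named
#' character vector, `c(SACR = "sacrum")` means the file calls SACR
#' "sacrum").
#'
#' @param prefix path prefix used at write time.
#' @param alias optional named character vector of label aliases.
#' @param max_gap maximum interpolatable gap length, frames.
#' @return A [gait_session()]; if a truth sidecar exists it is attached.
#' @export
read_session <- function(prefix, alias = NULL, max_gap = 10) {
  mpath <- paste0(prefix, "_markers.csv")
  if (!file.exists(mpath)) stop("no markers file at ", mpath)
  df <- read.csv(mpath, check.names = FALSE)
  name_of <- function(marker) {
    if (!is.null(alias) && marker %in% names(alias)) alias[[marker]] else marker
  }
  markers <- list()
  absent <- character(0)
  for (m in REQUIRED_MARKERS) {
    cols <- paste0(name_of(m), "_", c("x", "y", "z"))
    if (!all(cols %in% names(df))) {
      absent <- c(absent, m)
      next
    }
    xyz <- as.matrix(df[, cols])
    colnames(xyz) <- c("x", "y", "z")
    markers[[m]] <- apply(xyz, 2, fill_gaps, max_gap = max_gap)
  }
  if (length(absent) > 0) {
    stop("missing required marker(s): ", paste(absent, collapse = ", "))
  }
  forces <- NULL
  fpath <- paste0(prefix, "_forces.csv")
  if (file.exists(fpath)) {
    fdf <- read.csv(fpath)
    forces <- list(time = fdf$time, left = fdf$force_left,
                   right = fdf$force_right)
  }
  rate <- 1 / median(diff(df$time))
  frate <- if (is.null(forces)) 1000 else 1 / median(diff(forces$time))
  ses <- gait_session(df$time, markers, df$belt_left, df$belt_right,
                      forces = forces, trial_label = basename(prefix),
                      rate_markers = round(rate), rate_forces = round(frate))
  tpath <- paste0(prefix, "_truth.json")
  if (file.exists(tpath)) {
    tr <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    ses$truth <- list(
      events = gait_events(tr$touchdowns, tr$toeoffs),
      mos = tr$mos, pert_times = tr$pert_times, group = tr$group)
    class(ses) <- c("synthetic_session", class(ses))
  }
  ses
}

# Linear interpolation of interior NA runs up to max_gap frames.
fill_gaps <- function(x, max_gap = 10) {
  if (!anyNA(x)) return(x)
  na <- is.na(x)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gaps <- which(r$values)
  if (any(starts[gaps] == 1 | ends[gaps] == length(x))) {
    stop("marker gap touches the series boundary; cannot interpolate")
  }
  if (any(r$lengths[gaps] > max_gap)) {
    stop("marker gap of ", max(r$lengths[gaps]),
         " frames exceeds the interpolation limit (", max_gap, ")")
  }
  idx <- which(!na)
  approx(idx, x[idx], xout = seq_along(x))$y
}

# ---- participants ----------------------------------------------------------

#' Build a participant record table
#'
#' @param id character ids.
#' @param sex "M"/"F".
#' @param age years.
#' @param height cm.
#' @param weight kg.
#' @param falls_last_year non-negative integer count of falls in the past
#'   12 months.
#' @return data frame with a `group` column: `"Falls"` for one or more
#'   falls, `"NoFalls"` otherwise.
#' @export
participant_records <- function(id, sex, age, height, weight,
                                falls_last_year) {
  if (any(falls_last_year < 0)) stop("falls_last_year must be non-negative")
  data.frame(id = as.character(id), sex = sex, age = age, height = height,
             weight = weight, falls_last_year = falls_last_year,
             group = ifelse(falls_last_year >= 1, "Falls", "NoFalls"),
             stringsAsFactors = FALSE)
}

#' Partition participants by falls history
#'
#' Splits a record table into the falls-history group (one or more reported
#' falls in the past year) and the no-falls group; the partition is
#' exhaustive and disjoint.
#'
#' @param records data frame as from [participant_records()], or any data
#'   frame with a `falls_last_year` column.
#' @return list with elements `falls` and `no_falls` (data frames).
#' @export
assign_groups <- function(records) {
  counts <- records$falls_last_year
  if (is.null(counts)) stop("records must have a falls_last_year column")
  if (any(counts < 0)) stop("falls_last_year must be non-negative")
  list(falls = records[counts >= 1, , drop = FALSE],
       no_falls = records[counts < 1, , drop = FALSE])
}
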