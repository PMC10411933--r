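#' Radial and tangential speed of a cursor path
#'
#' Differentiates a cursor path by central finite differences. Two speeds are
#' kept: the *radial* speed, the signed rate of change of distance from the
#' movement start (used for movement-onset detection and the peak-speed
#' metric), and the *tangential* (path) speed (used for the primary-movement
#' end rule). An optional centred moving average smooths the speeds only,
#' never the positions.
#'
#' @param path Data frame with columns `t_ms`, `x`, `y`, timestamps strictly
#'   increasing, at least 3 samples.
#' @param start Length-2 numeric, movement start position.
#' @param window Odd width (samples) of the centred moving average applied to
#'   the speeds; 1 disables smoothing.
#' @return A tibble over the interior samples (differentiation trims one
#'   sample at each end): `t_ms`, `radial_speed` (au/s, signed),
#'   `tangential_speed` (au/s, non-negative), `smoothed`.
#' @export
compute_speed <- function(path, start = c(0, 0), window = 3) {
  if (nrow(path) < 3) abort("need at least 3 samples to differentiate")
  if (is.unsorted(path$t_ms, strictly = TRUE)) {
    abort("timestamps must be strictly increasing")
  }
  if (window %% 2 != 1 || window < 1) abort("window must be odd and >= 1")
  n <- nrow(path)
  i <- 2:(n - 1)
  dt_s <- (path$t_ms[i + 1] - path$t_ms[i - 1]) / 1000
  r <- sqrt((path$x - start[1])^2 + (path$y - start[2])^2)
  radial <- (r[i + 1] - r[i - 1]) / dt_s
  tangential <- sqrt((path$x[i + 1] - path$x[i - 1])^2 +
                       (path$y[i + 1] - path$y[i - 1])^2) / dt_s
  if (window > 1) {
    radial <- moving_average(radial, window)
    tangential <- moving_average(tangential, window)
  }
  tibble(t_ms = path$t_ms[i], radial_speed = radial,
         tangential_speed = tangential, smoothed = window > 1)
}

# centred moving average with shrinking windows at the edges
moving_average <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Detect movement onset from the radial speed
#'
#' Movement onset is the first sample after the target is shown whose radial
#' speed exceeds the threshold (0.5 au/s); reaction time is onset minus
#' target-shown time. A profile that never crosses the threshold is flagged
#' as no movement (the trial is then excluded from movement metrics).
#'
#' @param speed A [compute_speed()] tibble.
#' @param target_shown_t Target-shown time, ms.
#' @param threshold Onset threshold, au/s.
#' @return A list with `onset_t` (ms or `NA`), `reaction` (ms or `NA`) and
#'   `no_movement` (logical).
#' @export
detect_onset <- function(speed, target_shown_t = 0, threshold = 0.5) {
  idx <- which(speed$t_ms > target_shown_t & speed$radial_speed > threshold)
  if (length(idx) == 0) {
    return(list(onset_t = NA_real_, reaction = NA_real_, no_movement = TRUE))
  }
  onset_t <- speed$t_ms[idx[1]]
  list(onset_t = onset_t, reaction = onset_t - target_shown_t,
       no_movement = FALSE)
}

#' Detect the end of the primary movement
#'
#' Finds the speed-profile discontinuity that terminates the initial,
#' largely feedforward movement: after the tangential-speed peak (post
#' onset), the primary movement ends at the earliest sample that is either
#' (a) a local minimum of tangential speed below `min_frac` of the peak, or
#' (b) below the onset threshold — whichever occurs first. If neither occurs
#' before the click, the primary end is the click time.
#'
#' @param speed A [compute_speed()] tibble.
#' @param onset_t Movement onset, ms.
#' @param click_t Click time, ms (upper bound of the search).
#' @param threshold Onset threshold, au/s.
#' @param min_frac Local-minimum criterion as a fraction of peak speed.
#' @return `primary_end_t`, ms.
#' @export
detect_primary_end <- function(speed, onset_t, click_t = Inf,
                               threshold = 0.5, min_frac = 0.5) {
  win <- speed |> filter(.data$t_ms >= onset_t, .data$t_ms <= click_t)
  if (nrow(win) == 0) return(min(click_t, max(speed$t_ms)))
  v <- win$tangential_speed
  peak_i <- which.max(v)
  peak <- v[peak_i]
  if (peak_i >= length(v)) return(min(click_t, win$t_ms[length(v)]))
  for (j in (peak_i + 1):length(v)) {
    if (v[j] < threshold) return(win$t_ms[j])
    is_local_min <- j > 1 && j < length(v) &&
      v[j] <= v[j - 1] && v[j] <= v[j + 1] && v[j] < min_frac * peak
    if (is_local_min) return(win$t_ms[j])
  }
  min(click_t, win$t_ms[length(v)])
}

#' Target entry and exit intervals of a cursor path
#'
#' Intervals during which the cursor centre is within the target circle
#' (boundary inclusive). An interval still open at the end of the path has
#' `exit_t = NA`.
#'
#' @param path Data frame with `t_ms`, `x`, `y`.
#' @param target Length-2 numeric target centre.
#' @param target_radius Target radius, au.
#' @return A tibble with `entry_t`, `exit_t` (ms), one row per entry.
#' @export
target_entries <- function(path, target, target_radius = 0.1) {
  inside <- sqrt((path$x - target[1])^2 + (path$y - target[2])^2) <=
    target_radius
  d <- diff(c(FALSE, inside))
  entry_i <- which(d == 1)
  exit_i <- which(d == -1)
  if (length(entry_i) == 0) return(tibble(entry_t = numeric(),
                                          exit_t = numeric()))
  exits <- path$t_ms[exit_i]
  if (length(exits) < length(entry_i)) exits <- c(exits, NA_real_)
  tibble(entry_t = path$t_ms[entry_i], exit_t = exits)
}

#' Segment one trial into movement phases
#'
#' Splits a trial's acquire time (target shown to successful click) into the
#' four phases of the movement: reaction (target shown to onset), primary
#' movement (onset to the speed-profile discontinuity), correction (primary
#' end to the last target entry) and click dwell (last entry to the click).
#' If the cursor enters the target before the primary movement ends, the
#' correction phase is clamped to zero and the dwell runs from the later of
#' the two boundaries, preserving the exact identity
#' `reaction + primary_mt + correction + dwell = acquire`.
#'
#' @param samples Trial samples: `t_ms`, `x`, `y`.
#' @param events Trial events: `t_ms`, `event` (must contain `target_shown`;
#'   a successful trial has a `click`).
#' @param target Length-2 numeric target centre.
#' @param target_radius Target radius, au.
#' @param start Length-2 numeric, movement start position.
#' @param threshold Onset threshold, au/s.
#' @param min_frac Primary-end local-minimum fraction.
#' @param window Speed-smoothing window, samples.
#' @param success Whether the trial was successful. A successful trial whose
#'   click lies outside every target-entry interval is inconsistent data and
#'   raises an error; an unsuccessful one yields a partial segmentation.
#' @return A one-row tibble: boundary times `onset_t`, `primary_end_t`,
#'   `last_entry_t`, `click_t` and durations `reaction`, `primary_mt`,
#'   `correction`, `dwell`, `acquire` (ms), plus a `no_movement` flag.
#'   Boundaries that cannot be measured (no movement, unsuccessful trial)
#'   are `NA`.
#' @export
segment_trial <- function(samples, events, target, target_radius = 0.1,
                          start = c(0, 0), threshold = 0.5, min_frac = 0.5,
                          window = 3, success = TRUE) {
  shown_t <- events$t_ms[events$event == "target_shown"][1]
  if (is.na(shown_t)) abort("events must contain target_shown")
  click_ts <- events$t_ms[events$event == "click"]
  click_t <- if (length(click_ts)) max(click_ts) else NA_real_

  speed <- compute_speed(samples, start = start, window = window)
  on <- detect_onset(speed, shown_t, threshold)
  empty <- tibble(
    onset_t = on$onset_t, primary_end_t = NA_real_,
    last_entry_t = NA_real_, click_t = click_t,
    reaction = on$reaction, primary_mt = NA_real_, correction = NA_real_,
    dwell = NA_real_, acquire = NA_real_, no_movement = on$no_movement
  )
  if (on$no_movement || is.na(click_t)) return(empty)

  pe_t <- detect_primary_end(speed, on$onset_t, click_t, threshold, min_frac)
  entries <- target_entries(samples, target, target_radius)
  entries <- filter(entries, .data$entry_t <= click_t)
  if (nrow(entries) == 0) {
    if (success) {
      abort("click outside any target-entry interval: inconsistent trial data")
    }
    return(mutate(empty, primary_end_t = pe_t,
                  primary_mt = pe_t - on$onset_t))
  }
  le_t <- max(entries$entry_t)

  reaction <- on$onset_t - shown_t
  primary_mt <- pe_t - on$onset_t
  correction <- max(0, le_t - pe_t)
  dwell <- click_t - max(le_t, pe_t)
  tibble(
    onset_t = on$onset_t, primary_end_t = pe_t, last_entry_t = le_t,
    click_t = click_t, reaction = reaction, primary_mt = primary_mt,
    correction = correction, dwell = dwell,
    acquire = click_t - shown_t, no_movement = FALSE
  )
}

#' Segment every trial of a session
#'
#' Applies [segment_trial()] to each trial of a simulated or loaded session.
#' Unsuccessful trials whose click missed the target yield partial
#' segmentations (durations `NA`) rather than errors.
#'
#' @param session An `aimkin_session`.
#' @param ... Passed to [segment_trial()] (thresholds, smoothing window).
#' @return A tibble with one row per trial: the trial id and the
#'   [segment_trial()] columns.
#' @export
segment_session <- function(session, ...) {
  samples_by <- split(session$samples, session$samples$trial)
  events_by <- split(session$events, session$events$trial)
  purrr::map(seq_len(nrow(session$trials)), function(i) {
    tr <- session$trials[i, ]
    id <- as.character(tr$trial)
    seg <- tryCatch(
      segment_trial(samples_by[[id]], events_by[[id]],
                    target = c(tr$target_x, tr$target_y),
                    start = c(tr$start_x, tr$start_y),
                    success = isTRUE(tr$success), ...),
      error = function(e) {
        tibble(onset_t = NA_real_, primary_end_t = NA_real_,
               last_entry_t = NA_real_, click_t = NA_real_,
               reaction = NA_real_, primary_mt = NA_real_,
               correction = NA_real_, dwell = NA_real_, acquire = NA_real_,
               no_movement = NA)
      }
    )
    mutate(seg, trial = tr$trial, .before = 1)
  }) |> bind_rows()
}
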