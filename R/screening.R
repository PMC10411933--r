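#' Frame-rate data-quality check
#'
#' Kinematic analysis degrades at low display rates, and frame-rate changes
#' confound comparisons, so sessions are screened on their per-trial frame
#' rates. For the two-context experiment the check fails when the mean frame
#' rate in either context is below `min_fps` or the contexts differ by more
#' than `max_diff` fps; for the multi-round experiment it fails when the
#' overall mean is below `min_fps` or the rate drops by more than `max_diff`
#' fps between the first and last round. Comparisons are strict.
#'
#' @param trials A session trial table with an `fps` column and either a
#'   `context` or a `round` column.
#' @param experiment `"exp1"` (per-context rule) or `"exp2"` (per-round
#'   rule).
#' @param min_fps Minimum acceptable mean frame rate.
#' @param max_diff Maximum acceptable context difference / first-to-last
#'   round drop, fps.
#' @return A one-row tibble: `pass`, `reason` (NA when passing) and the
#'   values used.
#' @export
frame_rate_check <- function(trials, experiment = c("exp1", "exp2"),
                             min_fps = 30, max_diff = 10) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    by_ctx <- trials |>
      group_by(.data$context) |>
      summarise(fps = mean(.data$fps), .groups = "drop")
    low <- any(by_ctx$fps < min_fps)
    diff_fps <- if (nrow(by_ctx) > 1) max(by_ctx$fps) - min(by_ctx$fps) else 0
    pass <- !low && !(diff_fps > max_diff)
    reason <- if (low) {
      sprintf("mean frame rate below %g fps", min_fps)
    } else if (diff_fps > max_diff) {
      sprintf("context frame rates differ by more than %g fps", max_diff)
    } else NA_character_
    tibble(pass = pass, reason = reason,
           fps_min = min(by_ctx$fps), fps_diff = diff_fps)
  } else {
    by_round <- trials |>
      group_by(.data$round) |>
      summarise(fps = mean(.data$fps), .groups = "drop") |>
      arrange(.data$round)
    mean_fps <- mean(trials$fps)
    drop <- by_round$fps[1] - by_round$fps[nrow(by_round)]
    pass <- !(mean_fps < min_fps) && !(drop > max_diff)
    reason <- if (mean_fps < min_fps) {
      sprintf("mean frame rate below %g fps", min_fps)
    } else if (drop > max_diff) {
      sprintf("frame rate dropped more than %g fps across rounds", max_diff)
    } else NA_character_
    tibble(pass = pass, reason = reason, fps_min = mean_fps, fps_diff = drop)
  }
}

#' Staircase stabilisation check
#'
#' By the end of a staircased block the one-up/one-down procedure should hold
#' success near 50%. The check fails when the success rate over the late
#' window (last `last_n` trials of each staircase, pooled per context) is
#' more than `tol` away from 0.5 in either context — strictly more, so a
#' rate of exactly 0.60 passes.
#'
#' @param trials A trial table with `context`, `trial`, `staircase`,
#'   `success`.
#' @param last_n Late-window size per staircase.
#' @param tol Allowed deviation from 0.5.
#' @param window Late-window mode, see [asymptotic_time_limit()].
#' @return A one-row tibble: `pass`, `reason` and the per-context rates.
#' @export
stabilization_check <- function(trials, last_n = 40, tol = 0.10,
                                window = c("per_staircase", "combined")) {
  window <- match.arg(window)
  rates <- split(trials, trials$context) |>
    purrr::imap(function(tr, ctx) {
      pool <- asymptotic_pool(tr, last_n, window)
      tibble(context = ctx, success_rate = mean(pool$success))
    }) |>
    bind_rows()
  bad <- abs(rates$success_rate - 0.5) > tol
  tibble(
    pass = !any(bad),
    reason = if (any(bad)) {
      sprintf("late-window success rate not stabilised in: %s",
              paste(rates$context[bad], collapse = ", "))
    } else NA_character_,
    rates = list(rates)
  )
}

#' Robust MAD outlier mask
#'
#' Flags values more than `k` scaled median absolute deviations from the
#' median, with the consistency constant `c = 1.4826` making the MAD a
#' robust estimator of the SD. When the scaled MAD is zero (over half the
#' values identical) any value differing from the median is flagged, the
#' limit of the robust z-score rule.
#'
#' @param values Numeric vector (>= 2 values).
#' @param k Threshold in scaled MADs.
#' @param constant Consistency constant.
#' @return Logical mask, `TRUE` for outliers.
#' @examples
#' mad_outliers(c(10, 12, 11, 13, 50))
#' @export
mad_outliers <- function(values, k = 3, constant = 1.4826) {
  if (length(values) < 2) abort("need at least 2 values")
  med <- median(values)
  smad <- constant * median(abs(values - med))
  if (smad == 0) {
    return(values != med)
  }
  abs(values - med) > k * smad
}

#' Screen a session for inclusion
#'
#' Runs the applicable data-quality checks for a session (frame rate, and
#' staircase stabilisation for the staircased experiment) and reports a
#' conjunction verdict. Screening never mutates the data; the report is a
#' pure annotation. Group-level MAD screening of between-context differences
#' is done across participants with [mad_outliers()].
#'
#' @param session An `aimkin_session`.
#' @param ... Passed to the individual checks.
#' @return A one-row tibble with `frame_rate_pass`, `stabilization_pass`
#'   (NA when not applicable), `pass` and the reasons.
#' @export
screen_session <- function(session, ...) {
  exp <- session$header$experiment
  fr <- frame_rate_check(session$trials, exp)
  if (exp == "exp1") {
    st <- stabilization_check(session$trials, ...)
    tibble(frame_rate_pass = fr$pass, stabilization_pass = st$pass,
           pass = fr$pass && st$pass,
           frame_rate_reason = fr$reason, stabilization_reason = st$reason)
  } else {
    tibble(frame_rate_pass = fr$pass, stabilization_pass = NA,
           pass = fr$pass, frame_rate_reason = fr$reason,
           stabilization_reason = NA_character_)
  }
}
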