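#' Per-trial spatial and temporal metrics
#'
#' Joins a session's trials with their segmentations and computes the
#' per-trial measures: the phase durations; the radial extent and signed
#' hand angle at the primary-movement end (cursor direction minus target
#' direction, counterclockwise positive); the peak radial speed between
#' onset and click; and the endpoint in the target-aligned frame, obtained
#' by rotating each movement as if directed to a target straight up (target
#' direction mapped to +y), so that the aligned y coordinate is the on-axis
#' (extent) component and x the off-axis (direction) component.
#'
#' @param session An `aimkin_session`.
#' @param segmentation Output of [segment_session()]; computed if missing.
#' @param window Speed-smoothing window passed through to the speed
#'   computation.
#' @return A tibble, one row per trial: trial descriptors, durations,
#'   `extent_at_pe` (au), `angle_at_pe` (deg, in (-180, 180]), `peak_speed`
#'   (au/s), `aligned_x`, `aligned_y` (au).
#' @export
trial_metrics <- function(session, segmentation = NULL, window = 3) {
  seg <- segmentation %||% segment_session(session, window = window)
  samples_by <- split(session$samples, session$samples$trial)
  rows <- purrr::map(seq_len(nrow(session$trials)), function(i) {
    tr <- session$trials[i, ]
    sg <- seg[seg$trial == tr$trial, ]
    sm <- samples_by[[as.character(tr$trial)]]
    start <- c(tr$start_x, tr$start_y)
    out <- tibble(extent_at_pe = NA_real_, angle_at_pe = NA_real_,
                  peak_speed = NA_real_, aligned_x = NA_real_,
                  aligned_y = NA_real_)
    if (nrow(sg) == 1 && !is.na(sg$primary_end_t)) {
      # cursor position at (the sample closest to) the primary-movement end
      k <- which.min(abs(sm$t_ms - sg$primary_end_t))
      ep <- c(sm$x[k], sm$y[k]) - start
      out$extent_at_pe <- sqrt(sum(ep^2))
      if (out$extent_at_pe > 0) {
        out$angle_at_pe <- wrap_angle(rad2deg(atan2(ep[2], ep[1])) -
                                        tr$target_angle)
      }
      al <- rotate_xy(ep[1], ep[2], 90 - tr$target_angle)
      out$aligned_x <- al[1]
      out$aligned_y <- al[2]
      if (!is.na(sg$onset_t) && !is.na(sg$click_t)) {
        sp <- compute_speed(sm, start = start, window = window)
        inwin <- sp$t_ms >= sg$onset_t & sp$t_ms <= sg$click_t
        if (any(inwin)) out$peak_speed <- max(sp$radial_speed[inwin])
      }
    }
    bind_cols(
      tr[, intersect(c("trial", "context", "round", "cycle", "staircase",
                       "time_limit", "target_distance", "target_angle",
                       "success"), names(tr))],
      sg[, c("reaction", "primary_mt", "correction", "dwell", "acquire",
             "no_movement")],
      out
    )
  })
  bind_rows(rows)
}

# rotate (x, y) counterclockwise by `deg` degrees
rotate_xy <- function(x, y, deg) {
  a <- deg2rad(deg)
  c(cos(a) * x - sin(a) * y, sin(a) * x + cos(a) * y)
}

#' Linearity index of a movement path
#'
#' Maximum perpendicular deviation of the path from the straight
#' start-to-target segment, divided by the straight-line distance. 0 for a
#' perfectly straight movement; a semicircular arc gives 0.5. An alternative
#' definition, the path-length ratio minus one, is available via `method`.
#'
#' @param path Data frame with `x`, `y` (>= 2 samples).
#' @param start,target Length-2 numerics.
#' @param method `"max_deviation"` (default) or `"path_ratio"`.
#' @return Dimensionless index.
#' @export
linearity_index <- function(path, start, target,
                            method = c("max_deviation", "path_ratio")) {
  method <- match.arg(method)
  v <- target - start
  L <- sqrt(sum(v^2))
  if (L == 0) abort("start and target coincide")
  if (nrow(path) < 2) abort("path needs at least 2 samples")
  if (method == "max_deviation") {
    # perpendicular distance via the 2D cross product
    dev <- abs((path$x - start[1]) * v[2] - (path$y - start[2]) * v[1]) / L
    max(dev) / L
  } else {
    steps <- sqrt(diff(path$x)^2 + diff(path$y)^2)
    sum(steps) / L - 1
  }
}

#' Confidence error ellipse of an endpoint cloud
#'
#' Fits a coverage-level error ellipse to 2D endpoints by
#' eigendecomposition of the sample covariance: semi-axis k is
#' `sqrt(q * lambda_k)` with `q` the chi-square(2) quantile at `coverage`.
#' The aspect ratio `sqrt(lambda_major / lambda_minor)` exceeds 1 when
#' variability is extent-dominated (for target-aligned endpoints, elongated
#' along the movement axis).
#'
#' @param endpoints Data frame with `x`, `y` (>= 3 rows), typically
#'   target-aligned endpoints.
#' @param coverage Coverage probability.
#' @return A list of class `aimkin_ellipse`: `center`, `semi_axes` (major,
#'   minor, au), `orientation` (deg, major axis, counterclockwise from +x),
#'   `aspect_ratio`, `coverage`, `n`.
#' @export
error_ellipse <- function(endpoints, coverage = 0.95) {
  xy <- cbind(endpoints$x, endpoints$y)
  xy <- xy[complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 3) abort("need at least 3 endpoints")
  S <- stats::cov(xy)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 0) {
    abort(sprintf("degenerate endpoint covariance (rank %d)",
                  sum(e$values > 1e-12)))
  }
  q <- qchisq(coverage, df = 2)
  structure(
    list(center = colMeans(xy),
         semi_axes = sqrt(q * e$values),
         orientation = rad2deg(atan2(e$vectors[2, 1], e$vectors[1, 1])),
         aspect_ratio = sqrt(e$values[1] / e$values[2]),
         coverage = coverage, n = nrow(xy)),
    class = "aimkin_ellipse"
  )
}

#' @export
print.aimkin_ellipse <- function(x, ...) {
  cat(sprintf(
    "<aimkin_ellipse> %d%% ellipse of %d endpoints: semi-axes %.3f x %.3f au, aspect ratio %.2f\n",
    round(100 * x$coverage), x$n, x$semi_axes[1], x$semi_axes[2],
    x$aspect_ratio
  ))
  invisible(x)
}

#' Per-direction directional bias
#'
#' Systematic signed aiming error per target direction: the median
#' `angle_at_pe` per angle within each participant, then the mean across
#' participants.
#'
#' @param metrics A [trial_metrics()] tibble (optionally with a
#'   `participant` column; a single participant is assumed otherwise).
#' @return A tibble with `target_angle`, `bias` (deg) and `n_participants`.
#' @export
directional_bias <- function(metrics) {
  if (!"participant" %in% names(metrics)) metrics$participant <- 1L
  metrics |>
    filter(!is.na(.data$angle_at_pe)) |>
    group_by(.data$participant, .data$target_angle) |>
    summarise(bias = median(.data$angle_at_pe), .groups = "drop") |>
    group_by(.data$target_angle) |>
    summarise(bias = mean(.data$bias), n_participants = n(),
              .groups = "drop")
}

#' Effective index of difficulty
#'
#' Fitts-law difficulty computed from realised movements rather than nominal
#' target geometry: the effective width is `W_e = 4.133 * SD` of the signed
#' on-axis endpoint coordinate, and `ID_e = log2(D_e / W_e + 1)` with `D_e`
#' the mean movement extent of the cell (Shannon formulation).
#'
#' @param extent Numeric vector of movement extents (au) for one cell, or a
#'   single precomputed mean.
#' @param on_axis Numeric vector of signed on-axis endpoint coordinates (au).
#' @return A list with `D_e`, `W_e` and `id_e` (bits); `id_e` is `NA` with a
#'   warning if the endpoint SD is zero.
#' @examples
#' effective_id(0.8, c(-0.05, 0.05))  # W_e ~ 0.2 -> ID_e ~ log2(5)
#' @export
effective_id <- function(extent, on_axis) {
  if (length(on_axis) < 2) abort("need >= 2 endpoints per cell")
  D_e <- mean(extent, na.rm = TRUE)
  W_e <- 4.133 * sd(on_axis, na.rm = TRUE)
  if (!is.finite(W_e) || W_e == 0) {
    warn("zero endpoint spread: effective ID undefined")
    return(list(D_e = D_e, W_e = W_e, id_e = NA_real_))
  }
  list(D_e = D_e, W_e = W_e, id_e = log2(D_e / W_e + 1))
}

#' Fitts-law fit of movement time on effective difficulty
#'
#' Ordinary least squares of movement time (ms) on the effective index of
#' difficulty (bits); the slope (ms/bit) is the inverse throughput.
#'
#' @param points Data frame with columns `id_e` (bits) and `mt` (ms), one
#'   row per cell (or participant-by-cell).
#' @return An object of class `aimkin_fitts` wrapping the `lm` fit, with
#'   `intercept` (ms) and `slope` (ms/bit). Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' pts <- tibble::tibble(id_e = 1:4, mt = 35 + 243 * (1:4))
#' fitts_fit(pts)$slope
#' @export
fitts_fit <- function(points) {
  if (length(unique(points$id_e)) < 2) {
    abort("need at least 2 distinct ID values")
  }
  fit <- lm(mt ~ id_e, data = points)
  structure(
    list(fit = fit, intercept = unname(coef(fit)[1]),
         slope = unname(coef(fit)[2]), data = as_tibble(points)),
    class = "aimkin_fitts"
  )
}

#' @export
print.aimkin_fitts <- function(x, ...) {
  cat(sprintf("<aimkin_fitts> MT = %.1f + %.1f * ID_e  (n = %d)\n",
              x$intercept, x$slope, nrow(x$data)))
  invisible(x)
}

#' Participant-level summary of a session
#'
#' Summarises per-trial metrics the way the staircased experiment is
#' analysed: only successful trials from the selection window (the last
#' `last_n` trials of each staircase, per context) enter; temporal measures
#' are summarised by medians and spatial measures by means/SDs, alongside
#' the asymptotic time limit.
#'
#' @param session An `aimkin_session` (experiment 1 layout, with `staircase`
#'   and `time_limit` columns).
#' @param metrics A [trial_metrics()] tibble; computed if missing.
#' @param last_n Late-window size per staircase.
#' @param window Late-window mode, see [asymptotic_time_limit()].
#' @return A tibble with one row per context: `asymptotic_limit`,
#'   `n_selected`, `n_successful`, medians of the phase durations, mean/SD
#'   of `extent_at_pe`, mean `peak_speed`, SD of `angle_at_pe`.
#' @export
participant_summary <- function(session, metrics = NULL, last_n = 40,
                                window = c("per_staircase", "combined")) {
  window <- match.arg(window)
  metrics <- metrics %||% trial_metrics(session)
  split(metrics, metrics$context) |>
    purrr::imap(function(mx, ctx) {
      sel <- asymptotic_pool(mx, last_n, window)
      succ <- filter(sel, .data$success)
      tibble(
        context = ctx,
        asymptotic_limit = median(sel$time_limit),
        n_selected = nrow(sel),
        n_successful = nrow(succ),
        acquire = median(succ$acquire, na.rm = TRUE),
        reaction = median(succ$reaction, na.rm = TRUE),
        primary_mt = median(succ$primary_mt, na.rm = TRUE),
        correction = median(succ$correction, na.rm = TRUE),
        dwell = median(succ$dwell, na.rm = TRUE),
        extent_mean = mean(succ$extent_at_pe, na.rm = TRUE),
        extent_sd = sd(succ$extent_at_pe, na.rm = TRUE),
        peak_speed = mean(succ$peak_speed, na.rm = TRUE),
        angle_sd = sd(succ$angle_at_pe, na.rm = TRUE)
      )
    }) |>
    bind_rows()
}

#' Per-round summary of an aim-trainer session
#'
#' Learning-curve view of a practice session: per-round medians of the phase
#' durations and means/SDs of the spatial measures, over successful trials.
#'
#' @param metrics A [trial_metrics()] tibble with a `round` column.
#' @return A tibble with one row per round.
#' @export
round_summary <- function(metrics) {
  metrics |>
    filter(.data$success) |>
    group_by(.data$round) |>
    summarise(
      n = n(),
      acquire = median(.data$acquire, na.rm = TRUE),
      reaction = median(.data$reaction, na.rm = TRUE),
      primary_mt = median(.data$primary_mt, na.rm = TRUE),
      correction = median(.data$correction, na.rm = TRUE),
      dwell = median(.data$dwell, na.rm = TRUE),
      peak_speed = mean(.data$peak_speed, na.rm = TRUE),
      extent_mean = mean(.data$extent_at_pe, na.rm = TRUE),
      extent_sd = sd(.data$extent_at_pe, na.rm = TRUE),
      angle_sd = sd(.data$angle_at_pe, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Per-cell (distance) summary with effective difficulty
#'
#' Summarises an aim-trainer session per movement distance: median movement
#' time (onset to click), mean extent, endpoint spread and the effective
#' index of difficulty per cell — the inputs to [fitts_fit()].
#'
#' @param metrics A [trial_metrics()] tibble with `aligned_y` endpoints.
#' @return A tibble with one row per `target_distance`: `n`, `mt`,
#'   `D_e`, `W_e`, `id_e`.
#' @export
distance_summary <- function(metrics) {
  metrics |>
    filter(.data$success, !is.na(.data$aligned_y)) |>
    group_by(.data$target_distance) |>
    summarise(
      n = n(),
      mt = median(.data$acquire - .data$reaction, na.rm = TRUE),
      D_e = mean(.data$extent_at_pe, na.rm = TRUE),
      W_e = 4.133 * sd(.data$aligned_y, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(id_e = log2(.data$D_e / .data$W_e + 1))
}
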