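#' Generative parameters of the synthetic performer
#'
#' The synthetic performer produces mouse traces with the statistical
#' structure typical of time-pressured centre-out aiming: a straight,
#' target-directed primary movement with a minimum-jerk speed profile whose
#' duration grows linearly with distance; signal-dependent extent noise
#' (SD proportional to movement distance) and smaller directional noise, so
#' endpoint clouds are elongated along the movement axis; shifted-lognormal
#' reaction times and lognormal click dwell; iterative corrective
#' submovements each covering a fixed fraction of the remaining error after a
#' latency; small additive Look-context penalties on reaction and correction
#' latency; and dual-rate (fast-then-slow) improvement across practice
#' rounds. It is a validation instrument for the analysis pipeline, not a
#' model of participants' true generative process.
#'
#' @param rt_shift,rt_location,rt_scale Shifted-lognormal reaction time:
#'   `rt_shift + rlnorm(rt_location, rt_scale)` ms.
#' @param mt_intercept,mt_slope Primary-movement duration `T = a + b * D` ms,
#'   with `D` the submovement amplitude in au.
#' @param extent_cv Coefficient of variation of primary-movement extent
#'   (signal-dependent: SD = `extent_cv * D`).
#' @param angle_sd Direction noise at the primary-movement end, degrees.
#' @param undershoot_frac Mean primary extent as a fraction of target
#'   distance (primary movements slightly undershoot).
#' @param corr_latency Pause before each corrective submovement, ms.
#' @param corr_gain Fraction of the remaining vector error covered by each
#'   correction (0 < gain <= 1).
#' @param dwell_location,dwell_scale Lognormal click dwell, ms.
#' @param look_rt_penalty,look_corr_penalty Additive Look-context penalties
#'   on reaction time and correction latency, ms.
#' @param learn_fast,learn_slow Decay rates (per round) of the fast and slow
#'   learning processes.
#' @param amp_fast,amp_slow Initial fractional elevations of the fast and
#'   slow processes; the round-r multiplier is
#'   `1 + amp_fast * exp(-learn_fast * (r-1)) + amp_slow * exp(-learn_slow * (r-1))`,
#'   applied to latency and noise parameters (movement-time parameters
#'   improve only through the slow process).
#' @param frame_rate Display/sampling rate, Hz (>= 30).
#' @param max_submovements Cap on submovements per trial; a trial still
#'   outside the target after the cap clicks and fails.
#' @param bias_table Optional tibble (`angle`, `bias_deg`) of per-direction
#'   aiming biases added to the primary movement direction; default none, so
#'   the group-mean directional bias is zero at every angle.
#' @return A list of class `performer_params`.
#' @export
performer_params <- function(rt_shift = 150, rt_location = log(130),
                             rt_scale = 0.25,
                             mt_intercept = 120, mt_slope = 380,
                             extent_cv = 0.08, angle_sd = 2,
                             undershoot_frac = 0.92,
                             corr_latency = 120, corr_gain = 0.75,
                             dwell_location = log(160), dwell_scale = 0.3,
                             look_rt_penalty = 25, look_corr_penalty = 24,
                             learn_fast = 0.4, learn_slow = 0.05,
                             amp_fast = 0.45, amp_slow = 0.25,
                             frame_rate = 60, max_submovements = 10,
                             bias_table = NULL) {
  p <- list(
    rt_shift = rt_shift, rt_location = rt_location, rt_scale = rt_scale,
    mt_intercept = mt_intercept, mt_slope = mt_slope,
    extent_cv = extent_cv, angle_sd = angle_sd,
    undershoot_frac = undershoot_frac,
    corr_latency = corr_latency, corr_gain = corr_gain,
    dwell_location = dwell_location, dwell_scale = dwell_scale,
    look_rt_penalty = look_rt_penalty, look_corr_penalty = look_corr_penalty,
    learn_fast = learn_fast, learn_slow = learn_slow,
    amp_fast = amp_fast, amp_slow = amp_slow,
    frame_rate = frame_rate, max_submovements = max_submovements,
    bias_table = bias_table
  )
  if (p$corr_gain <= 0 || p$corr_gain > 1) abort("corr_gain must be in (0, 1]")
  if (p$frame_rate < 30) abort("frame_rate must be >= 30 Hz")
  # endpoint clouds must elongate along the movement axis: the radial SD
  # (extent_cv * D) has to dominate the tangential SD (~ D * angle_sd in rad)
  if (p$extent_cv > 0 && p$extent_cv <= deg2rad(p$angle_sd)) {
    abort("extent_cv must exceed the tangential SD implied by angle_sd")
  }
  structure(p, class = "performer_params")
}

# minimum-jerk position and velocity shape functions on tau in [0, 1]
mj_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_v <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4

#' Minimum-jerk displacement and speed profile
#'
#' Samples the rest-to-rest minimum-jerk trajectory of amplitude `D` and
#' duration `T`: `s(tau) = D (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = t / T`. Peak speed is `1.875 D / T` at `tau = 0.5`.
#'
#' @param D Movement amplitude, au.
#' @param T_ms Movement duration, ms.
#' @param dt_ms Sample period, ms.
#' @return A tibble with `t_ms`, `s` (au) and `v` (au/s).
#' @examples
#' pr <- min_jerk_profile(1, 500, 1000 / 60)
#' max(pr$v)  # ~ 1.875 * 1 / 0.5
#' @export
min_jerk_profile <- function(D, T_ms, dt_ms) {
  if (D <= 0 || T_ms <= 0 || dt_ms <= 0) abort("D, T_ms, dt_ms must be positive")
  t <- seq(0, T_ms, by = dt_ms)
  if (t[length(t)] < T_ms) t <- c(t, T_ms)
  tau <- t / T_ms
  tibble(t_ms = t, s = D * mj_s(tau), v = D * mj_v(tau) / T_ms * 1000)
}

# time (ms since submovement start) at which the min-jerk speed of amplitude
# L (au) and duration T (ms) crosses `thr` (au/s); side "up" (rising limb) or
# "down" (falling limb). NA if the peak never reaches thr.
mj_speed_crossing <- function(L, T_ms, thr, side = c("up", "down")) {
  side <- match.arg(side)
  peak <- 1.875 * L / T_ms * 1000
  if (peak <= thr) return(NA_real_)
  f <- function(tau) L * mj_v(tau) / T_ms * 1000 - thr
  iv <- if (side == "up") c(1e-12, 0.5) else c(0.5, 1 - 1e-12)
  T_ms * uniroot(f, iv, tol = 1e-12)$root
}

# times (ms since submovement start) at which a straight min-jerk submovement
# from p0 to p1 crosses distance r from `center`; returns a tibble with
# t (ms) and entering (logical), ordered in time
mj_circle_crossings <- function(p0, p1, T_ms, center, r) {
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) return(tibble(t = numeric(), entering = logical()))
  u <- (p1 - p0) / L
  a <- p0 - center
  # squared distance along the path: d2(s) = s^2 + 2 (a.u) s + |a|^2
  b <- sum(a * u)
  cc <- sum(a * a) - r^2
  disc <- b^2 - cc
  if (disc <= 0) return(tibble(t = numeric(), entering = logical()))
  roots <- c(-b - sqrt(disc), -b + sqrt(disc))
  roots <- roots[roots > 0 & roots < L]
  if (length(roots) == 0) return(tibble(t = numeric(), entering = logical()))
  t <- vapply(roots, function(s_star) {
    tau <- uniroot(function(tau) mj_s(tau) - s_star / L,
                   c(0, 1), tol = 1e-12)$root
    T_ms * tau
  }, numeric(1))
  entering <- vapply(roots, function(s_star) (s_star + b) < 0, logical(1))
  tibble(t = t, entering = entering) |> arrange(t)
}

# multiplier applied to latency/noise parameters on practice round r
learning_multiplier <- function(params, round, process = c("both", "slow")) {
  process <- match.arg(process)
  fast <- params$amp_fast * exp(-params$learn_fast * (round - 1))
  slow <- params$amp_slow * exp(-params$learn_slow * (round - 1))
  if (process == "slow") 1 + slow else 1 + fast + slow
}

# params with round-r learning applied; round 1 = naive
scale_params <- function(params, round = 1) {
  m <- learning_multiplier(params, round, "both")
  ms <- learning_multiplier(params, round, "slow")
  params$rt_location <- params$rt_location + log(m)
  params$dwell_location <- params$dwell_location + log(m)
  params$corr_latency <- params$corr_latency * m
  params$angle_sd <- params$angle_sd * m
  params$extent_cv <- params$extent_cv * m
  params$mt_intercept <- params$mt_intercept * ms
  params$mt_slope <- params$mt_slope * ms
  params
}

# per-angle aiming bias (deg) from the optional bias table
angle_bias <- function(params, angle) {
  bt <- params$bias_table
  if (is.null(bt)) return(0)
  hit <- which(bt$angle == angle)
  if (length(hit) == 0) 0 else bt$bias_deg[hit[1]]
}

#' Simulate one shot attempt
#'
#' Draws a reaction time, executes a straight minimum-jerk primary movement
#' toward a noisy aimpoint (extent mean `undershoot_frac * D`, SD
#' `extent_cv * D`; direction SD `angle_sd`), then corrective submovements
#' (each after `corr_latency`, covering `corr_gain` of the remaining vector
#' error with proportional noise) until the cursor is inside the target, then
#' a dwell and a click. The trial succeeds iff the click lands inside the
#' target and, when a time limit is given, at or before the limit. The trace
#' is sampled at the frame rate with deltas consistent with the path.
#'
#' @param params A [performer_params()].
#' @param target_distance,target_angle Target displacement from the movement
#'   start, au / degrees.
#' @param context `"point"` or `"look"`.
#' @param time_limit Time limit, ms, or `NULL` for none.
#' @param target_radius Target radius, au.
#' @param start Length-2 numeric, movement start in workspace coordinates.
#' @return A list of class `aimkin_trial` with `samples` (`t_ms`, `dx`, `dy`,
#'   `x`, `y`), `events` (`t_ms`, `event`), `success`, `n_submovements`,
#'   `click_t`, and `ground_truth` — the analytic phase boundaries
#'   (`true_onset`, `true_primary_end`, `true_last_entry`, `true_click`, ms)
#'   computed from the closed-form kinematics, for validating trajectory
#'   segmentation. Onset and primary end are the analytic 0.5 au/s crossings
#'   of the minimum-jerk speed profile; with an undershooting noiseless
#'   aimpoint the last target entry can precede the primary-movement end, in
#'   which case the correction phase is empty by definition.
#' @export
simulate_trial <- function(params, target_distance = 1, target_angle = 0,
                           context = c("point", "look"), time_limit = NULL,
                           target_radius = 0.1, start = c(0, 0)) {
  context <- match.arg(tolower(context), c("point", "look"))
  look <- context == "look"
  D <- target_distance
  target <- start + D * c(cos(deg2rad(target_angle)), sin(deg2rad(target_angle)))

  rt <- params$rt_shift + rlnorm(1, params$rt_location, params$rt_scale) +
    if (look) params$look_rt_penalty else 0

  # submovements: start time, p0, p1, duration
  subs <- list()
  p <- start
  t_cur <- rt
  for (k in seq_len(params$max_submovements)) {
    if (k == 1) {
      intended <- params$undershoot_frac * D
      extent <- max(1e-6, intended + rnorm(1, 0, params$extent_cv * D))
      ang <- target_angle + angle_bias(params, target_angle) +
        rnorm(1, 0, params$angle_sd)
      aim <- start + extent * c(cos(deg2rad(ang)), sin(deg2rad(ang)))
    } else {
      err <- target - p
      err_len <- sqrt(sum(err^2))
      intended <- params$corr_gain * err_len
      extent <- max(1e-6, intended + rnorm(1, 0, params$extent_cv * err_len))
      ang <- rad2deg(atan2(err[2], err[1])) + rnorm(1, 0, params$angle_sd)
      aim <- p + extent * c(cos(deg2rad(ang)), sin(deg2rad(ang)))
      t_cur <- t_cur + params$corr_latency +
        if (look) params$look_corr_penalty else 0
    }
    # duration is programmed for the intended amplitude; extent noise is
    # realised in execution, so peak speed inherits signal-dependent spread
    T_k <- params$mt_intercept + params$mt_slope * intended
    subs[[k]] <- list(t0 = t_cur, p0 = p, p1 = aim, T_ms = T_k)
    t_cur <- t_cur + T_k
    p <- aim
    if (sqrt(sum((p - target)^2)) <= target_radius) break
  }
  inside <- sqrt(sum((p - target)^2)) <= target_radius
  move_end <- t_cur

  # entry/exit events from the analytic path
  crossings <- purrr::map(subs, function(sm) {
    cr <- mj_circle_crossings(sm$p0, sm$p1, sm$T_ms, target, target_radius)
    mutate(cr, t = t + sm$t0)
  }) |> bind_rows()
  last_entry <- if (nrow(crossings) && any(crossings$entering)) {
    max(crossings$t[crossings$entering])
  } else NA_real_

  dwell <- rlnorm(1, params$dwell_location, params$dwell_scale)
  click_t <- max(move_end, last_entry, na.rm = TRUE) + dwell
  success <- inside && (is.null(time_limit) || click_t <= time_limit)

  # ground truth from the first (primary) submovement's closed form
  s1 <- subs[[1]]
  L1 <- sqrt(sum((s1$p1 - s1$p0)^2))
  up <- mj_speed_crossing(L1, s1$T_ms, 0.5, "up")
  down <- mj_speed_crossing(L1, s1$T_ms, 0.5, "down")
  gt <- tibble(
    true_onset = s1$t0 + up,
    true_primary_end = s1$t0 + down,
    true_last_entry = last_entry,
    true_click = click_t
  )

  # sample the analytic path at the frame rate
  dt <- 1000 / params$frame_rate
  t_samp <- seq(0, click_t + 2 * dt, by = dt)
  x <- rep(start[1], length(t_samp))
  y <- rep(start[2], length(t_samp))
  for (sm in subs) {
    after <- t_samp >= sm$t0 + sm$T_ms
    x[after] <- sm$p1[1]; y[after] <- sm$p1[2]
    during <- t_samp >= sm$t0 & t_samp < sm$t0 + sm$T_ms
    if (any(during)) {
      sh <- mj_s((t_samp[during] - sm$t0) / sm$T_ms)
      x[during] <- sm$p0[1] + (sm$p1[1] - sm$p0[1]) * sh
      y[during] <- sm$p0[2] + (sm$p1[2] - sm$p0[2]) * sh
    }
  }
  samples <- tibble(
    t_ms = t_samp,
    dx = c(0, diff(x)), dy = c(0, diff(y)),
    x = x, y = y
  )

  events <- bind_rows(
    tibble(t_ms = 0, event = "target_shown"),
    if (nrow(crossings)) {
      tibble(t_ms = crossings$t,
             event = ifelse(crossings$entering, "target_enter", "target_exit"))
    },
    tibble(t_ms = click_t, event = "click"),
    tibble(t_ms = click_t, event = if (success) "success" else "fail")
  ) |> arrange(t_ms)

  structure(
    list(samples = samples, events = events, success = success,
         n_submovements = length(subs), click_t = click_t,
         ground_truth = gt),
    class = "aimkin_trial"
  )
}

# assemble per-trial simulation results into a session object
build_session <- function(experiment, trials, sims, params, seed,
                          cfg = scene_config()) {
  samples <- purrr::imap(sims, function(s, i) {
    mutate(s$samples, trial = trials$trial[i], .before = 1)
  }) |> bind_rows()
  events <- purrr::imap(sims, function(s, i) {
    mutate(s$events, trial = trials$trial[i], .before = 1)
  }) |> bind_rows()
  ground_truth <- purrr::imap(sims, function(s, i) {
    mutate(s$ground_truth, trial = trials$trial[i], .before = 1)
  }) |> bind_rows()
  trials$success <- vapply(sims, function(s) s$success, logical(1))
  trials$n_submovements <- vapply(sims, function(s) s$n_submovements,
                                  integer(1))
  trials$fps <- params$frame_rate
  structure(
    list(
      header = list(format_version = 1L, experiment = experiment,
                    device = "mouse", seed = seed,
                    frame_rate = params$frame_rate, scene = unclass(cfg)),
      trials = as_tibble(trials), samples = samples, events = events,
      ground_truth = ground_truth
    ),
    class = "aimkin_session"
  )
}

#' @export
print.aimkin_session <- function(x, ...) {
  cat(sprintf(
    "<aimkin_session> %s: %d trials, %d samples, %d events\n",
    x$header$experiment, nrow(x$trials), nrow(x$samples), nrow(x$events)
  ))
  invisible(x)
}

#' Simulate the staircased two-context experiment
#'
#' Runs the synthetic performer through a full session of the staircased
#' shooting task: one 320-trial block per context (eight target angles at
#' 1 au, 40 cycles), with two interleaved one-up/one-down staircases per
#' block (starts 300 and 1,500 ms, step 30 ms) updated from each trial's
#' outcome.
#'
#' @param params A [performer_params()].
#' @param seed Optional integer seed.
#' @param contexts Contexts to run, in order.
#' @param n_cycles Cycles per block (40 in the task).
#' @return An `aimkin_session` whose `trials` table carries the staircase
#'   bookkeeping (`staircase`, `time_limit`).
#' @export
simulate_experiment1 <- function(params = performer_params(), seed = NULL,
                                 contexts = c("point", "look"),
                                 n_cycles = 40) {
  if (!is.null(seed)) set.seed(seed)
  all_trials <- list(); all_sims <- list()
  offset <- 0L
  for (ctx in contexts) {
    block <- exp1_block(ctx, n_cycles = n_cycles)
    sc <- list(low = staircase_new(300, 30, "low"),
               high = staircase_new(1500, 30, "high"))
    limits <- numeric(nrow(block))
    sims <- vector("list", nrow(block))
    for (i in seq_len(nrow(block))) {
      id <- block$staircase[i]
      limits[i] <- sc[[id]]$limit
      sims[[i]] <- simulate_trial(
        params, block$target_distance[i], block$target_angle[i],
        context = ctx, time_limit = limits[i]
      )
      sc[[id]] <- staircase_update(sc[[id]], sims[[i]]$success)
    }
    block$time_limit <- limits
    block$trial <- block$trial + offset
    block$start_x <- 0; block$start_y <- 0
    offset <- offset + nrow(block)
    all_trials[[ctx]] <- block
    all_sims[[ctx]] <- sims
  }
  build_session("exp1", bind_rows(all_trials),
                do.call(c, unname(all_sims)), params, seed)
}

#' Simulate the aim-trainer practice experiment
#'
#' Runs the synthetic performer through rounds of 48 chained targets in the
#' Look context (three distances x eight directions, two cycles per round, no
#' time limit). Practice improves the performer's latency and noise
#' parameters with a dual-rate (fast-then-slow) schedule across rounds; each
#' movement starts at the previous target's position and is analysed as a
#' centre-out movement from that start.
#'
#' @param params A [performer_params()].
#' @param seed Optional integer seed.
#' @param n_rounds Number of rounds (20 in the task).
#' @return An `aimkin_session` whose `trials` table has `round`, `start_x`,
#'   `start_y` and absolute target coordinates.
#' @export
simulate_experiment2 <- function(params = performer_params(), seed = NULL,
                                 n_rounds = 20) {
  if (!is.null(seed)) set.seed(seed)
  targets <- exp2_session(n_rounds)
  trials <- targets |>
    group_by(.data$round) |>
    mutate(start_x = lag(.data$x, default = 0),
           start_y = lag(.data$y, default = 0)) |>
    ungroup() |>
    mutate(trial = row_number(), context = "look",
           target_distance = .data$distance, target_angle = .data$angle,
           target_x = .data$x, target_y = .data$y) |>
    select("trial", "round", "cycle", "context", "target_distance",
           "target_angle", "start_x", "start_y", "target_x", "target_y")
  sims <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    p_r <- scale_params(params, trials$round[i])
    sims[[i]] <- simulate_trial(
      p_r, trials$target_distance[i], trials$target_angle[i],
      context = "look", time_limit = NULL,
      start = c(trials$start_x[i], trials$start_y[i])
    )
  }
  trials$time_limit <- NA_real_
  build_session("exp2", trials, sims, params, seed)
}
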