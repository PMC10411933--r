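#' Create a one-up/one-down staircase
#'
#' The task imposes personalised time pressure with a one-up/one-down
#' staircase on the trial time limit: after a successful trial the limit is
#' reduced by one step, after a failure it is increased by one step, so the
#' limit converges to roughly 50% success. Two staircases per block are
#' interleaved, one starting at 300 ms and one at 1,500 ms, with a 30 ms step.
#'
#' @param limit Starting time limit, ms.
#' @param step Step size, ms (constant 30 in the task).
#' @param id Optional staircase label (e.g. `"low"`, `"high"`).
#' @return A list of class `staircase` with fields `limit`, `step`, `id`,
#'   `clamped` and a `history` tibble (one row per update: tested limit,
#'   outcome, resulting limit).
#' @seealso [staircase_update()], [asymptotic_time_limit()]
#' @export
staircase_new <- function(limit, step = 30, id = NULL) {
  if (limit <= 0 || step <= 0) abort("limit and step must be positive")
  structure(
    list(limit = limit, step = step, id = id, clamped = FALSE,
         history = tibble(limit = numeric(), success = logical(),
                          next_limit = numeric())),
    class = "staircase"
  )
}

#' Update a staircase after one trial
#'
#' Success reduces the time limit by one step; failure increases it. A limit
#' that would fall to zero or below is clamped at one step and flagged
#' (`clamped = TRUE`); this cannot occur in the task's parameter range but
#' keeps pathological simulations physical.
#'
#' @param state A [staircase_new()] object.
#' @param success Logical, whether the trial was successful.
#' @return The updated `staircase`.
#' @examples
#' s <- staircase_new(300)
#' staircase_update(s, FALSE)$limit  # 330
#' @export
staircase_update <- function(state, success) {
  stopifnot(inherits(state, "staircase"), is.logical(success), length(success) == 1)
  new_limit <- state$limit + if (success) -state$step else state$step
  if (new_limit <= 0) {
    new_limit <- state$step
    state$clamped <- TRUE
  }
  state$history <- bind_rows(
    state$history,
    tibble(limit = state$limit, success = success, next_limit = new_limit)
  )
  state$limit <- new_limit
  state
}

#' Interleaving schedule for two staircases
#'
#' Assigns each trial of a block to one of the two staircases so that trial
#' counts are balanced and the staircase switches after most trials: trials
#' are taken in consecutive pairs and each pair contains one trial from each
#' staircase in random order, so no staircase runs more than twice in a row.
#'
#' @param n_trials Even number of trials (320 in the task).
#' @param ids Length-2 character vector of staircase labels.
#' @return Character vector of length `n_trials`.
#' @export
interleave_schedule <- function(n_trials = 320, ids = c("low", "high")) {
  if (n_trials %% 2 != 0) abort("n_trials must be even")
  pairs <- replicate(n_trials / 2, sample(ids), simplify = FALSE)
  unlist(pairs)
}

#' Trial schedule for one staircased block
#'
#' A block is 320 trials arranged into 40 cycles of eight; within each cycle
#' every target angle (0-315 deg in 45 deg steps, radius 1 au) is tested once
#' in random order. Staircase assignment comes from [interleave_schedule()].
#'
#' @param context `"point"` or `"look"`.
#' @param n_cycles Number of eight-trial cycles (40 in the task).
#' @param target_distance Target eccentricity, au.
#' @param angles Target angles, degrees.
#' @return A tibble with one row per trial: `trial`, `context`, `cycle`,
#'   `staircase`, `target_angle`, `target_distance`, `target_x`, `target_y`.
#' @export
exp1_block <- function(context = c("point", "look"), n_cycles = 40,
                       target_distance = 1, angles = seq(0, 315, by = 45)) {
  context <- match.arg(tolower(context), c("point", "look"))
  n_trials <- n_cycles * length(angles)
  angle_seq <- unlist(lapply(seq_len(n_cycles), function(i) sample(angles)))
  tibble(
    trial = seq_len(n_trials),
    context = context,
    cycle = rep(seq_len(n_cycles), each = length(angles)),
    staircase = interleave_schedule(n_trials),
    target_angle = angle_seq,
    target_distance = target_distance,
    target_x = target_distance * cos(deg2rad(angle_seq)),
    target_y = target_distance * sin(deg2rad(angle_seq))
  )
}

#' Run a staircased block against a success-generating performer
#'
#' Drives the two interleaved staircases through a block, asking `success_fn`
#' whether each trial succeeded at its current time limit. `success_fn` may
#' be deterministic (a threshold performer) or stochastic (e.g. a logistic
#' psychometric function); it receives the limit in ms and must return a
#' single logical.
#'
#' @param success_fn Function `limit -> logical`.
#' @param n_trials Trials in the block.
#' @param start_low,start_high Starting limits, ms.
#' @param step Staircase step, ms.
#' @return A tibble with `trial`, `staircase`, `limit` (limit in force on the
#'   trial) and `success`.
#' @examples
#' blk <- run_staircase_block(function(limit) limit >= 750)
#' asymptotic_time_limit(blk)
#' @export
run_staircase_block <- function(success_fn, n_trials = 320,
                                start_low = 300, start_high = 1500,
                                step = 30) {
  sc <- list(low = staircase_new(start_low, step, "low"),
             high = staircase_new(start_high, step, "high"))
  sched <- interleave_schedule(n_trials)
  limit <- numeric(n_trials)
  success <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    id <- sched[i]
    limit[i] <- sc[[id]]$limit
    success[i] <- isTRUE(success_fn(limit[i]))
    sc[[id]] <- staircase_update(sc[[id]], success[i])
  }
  tibble(trial = seq_len(n_trials), staircase = sched,
         limit = limit, success = success)
}

#' Asymptotic time limit of a staircased block
#'
#' The skill measure of the staircased experiment: the median time limit over
#' the late, stabilised portion of a block. By default the last 40 trials of
#' *each* staircase are pooled (80 values); `window = "combined"` instead
#' pools the last 40 trials of the block regardless of staircase.
#'
#' @param block A tibble with columns `trial`, `staircase`, `limit` (as
#'   returned by [run_staircase_block()] or extracted from a session's trial
#'   table).
#' @param last_n Number of late trials per staircase (40 in the task).
#' @param window `"per_staircase"` (default; `last_n` per staircase, pooled)
#'   or `"combined"` (`last_n` trials of the whole block).
#' @return The asymptotic time limit, ms.
#' @export
asymptotic_time_limit <- function(block, last_n = 40,
                                  window = c("per_staircase", "combined")) {
  window <- match.arg(window)
  pool <- asymptotic_pool(block, last_n, window)
  median(pool$limit)
}

# late-window trials used for the asymptotic limit and all last-40 selections
asymptotic_pool <- function(block, last_n = 40,
                            window = c("per_staircase", "combined")) {
  window <- match.arg(window)
  if (window == "combined") {
    if (nrow(block) < last_n) abort("fewer trials than the analysis window")
    return(arrange(block, .data$trial) |> slice_tail(n = last_n))
  }
  counts <- dplyr::count(block, .data$staircase)
  if (any(counts$n < last_n)) {
    abort(sprintf("each staircase needs >= %d trials", last_n))
  }
  block |>
    arrange(.data$trial) |>
    group_by(.data$staircase) |>
    slice_tail(n = last_n) |>
    ungroup()
}

#' Generate one aim-trainer round of chained targets
#'
#' A round is 48 back-to-back targets forming two uninterrupted cycles; each
#' cycle contains every combination of three movement distances (0.4, 0.6,
#' 0.8 au) and eight directions (0-315 deg in 45 deg steps) exactly once, and
#' each target lies at exactly its labelled (distance, angle) displacement
#' from the previous target (the first from the plane centre). No target may
#' lie more than `max_radius` from the workspace centre; sequences are
#' rejection-sampled (reshuffling a cycle until it satisfies the constraint).
#' Because the 24 displacement vectors of a cycle sum to zero, each cycle is
#' a closed loop returning to the centre.
#'
#' @param distances Movement distances, au.
#' @param angles Movement directions, degrees.
#' @param n_cycles Cycles per round (2 in the task).
#' @param max_radius Workspace cap, au.
#' @param max_attempts Shuffle attempts per cycle before giving up.
#' @return A tibble with one row per target: `target`, `cycle`, `distance`,
#'   `angle` (the movement that produced it), `x`, `y`.
#' @examples
#' set.seed(1)
#' rd <- exp2_round()
#' max(sqrt(rd$x^2 + rd$y^2))
#' @export
exp2_round <- function(distances = c(0.4, 0.6, 0.8),
                       angles = seq(0, 315, by = 45),
                       n_cycles = 2, max_radius = 1, max_attempts = 100000) {
  if (max_attempts < 1) abort("max_attempts must be >= 1")
  combos <- tidyr::expand_grid(distance = distances, angle = angles)
  vx <- combos$distance * cos(deg2rad(combos$angle))
  vy <- combos$distance * sin(deg2rad(combos$angle))
  n <- nrow(combos)
  cycles <- vector("list", n_cycles)
  for (cy in seq_len(n_cycles)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      ord <- sample(n)
      px <- cumsum(vx[ord])
      py <- cumsum(vy[ord])
      if (all(px^2 + py^2 <= max_radius^2 + 1e-12)) {
        cycles[[cy]] <- tibble(
          cycle = cy, distance = combos$distance[ord],
          angle = combos$angle[ord], x = px, y = py
        )
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("max_attempts exhausted while generating a round")
  }
  bind_rows(cycles) |>
    mutate(target = row_number(), .before = 1)
}

#' Generate a full aim-trainer session of rounds
#'
#' @param n_rounds Number of rounds (20 in the task).
#' @param ... Passed to [exp2_round()].
#' @return A tibble of `n_rounds * 48` targets with a `round` column.
#' @export
exp2_session <- function(n_rounds = 20, ...) {
  purrr::map(seq_len(n_rounds), function(r) {
    mutate(exp2_round(...), round = r, .before = 1)
  }) |> bind_rows()
}
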