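test_that("extent and hand angle at the primary end follow the sign convention", {
  # aim 10 degrees counterclockwise of... a 45-degree target, reaching 0.8 au:
  # extent 0.8, hand angle -35 degrees (cursor direction minus target
  # direction, counterclockwise positive)
  p <- noiseless_params(undershoot_frac = 0.8,
                        bias_table = tibble::tibble(angle = 45,
                                                    bias_deg = -35))
  set.seed(31)
  tr <- simulate_trial(p, 1, 45, "point")
  ses <- list(
    header = list(experiment = "exp1", scene = unclass(scene_config())),
    trials = tibble::tibble(
      trial = 1L, context = "point", time_limit = NA_real_,
      target_distance = 1, target_angle = 45,
      target_x = cos(pi / 4), target_y = sin(pi / 4),
      start_x = 0, start_y = 0, success = tr$success, fps = 60
    ),
    samples = dplyr::mutate(tr$samples, trial = 1L, .before = 1),
    events = dplyr::mutate(tr$events, trial = 1L, .before = 1)
  )
  class(ses) <- "aimkin_session"
  mx <- trial_metrics(ses)
  expect_equal(mx$extent_at_pe, 0.8, tolerance = 0.02)
  expect_equal(mx$angle_at_pe, -35, tolerance = 1)
  # aligned frame: target direction maps to +y
  expect_equal(mx$aligned_y, 0.8 * cos(35 * pi / 180), tolerance = 0.02)
  expect_equal(mx$aligned_x, 0.8 * sin(35 * pi / 180), tolerance = 0.02)
})

test_that("an on-axis noiseless movement has a centred aligned endpoint", {
  set.seed(32)
  p <- noiseless_params()
  ses <- simulate_experiment2(p, n_rounds = 1)
  mx <- trial_metrics(ses)
  expect_true(all(abs(mx$aligned_x) < 1e-6))
  expect_equal(mx$extent_at_pe,
               p$undershoot_frac * mx$target_distance, tolerance = 0.01)
  expect_true(all(abs(mx$angle_at_pe) < 0.1))
})

test_that("linearity index is zero for straight paths and 0.5 for a semicircle", {
  straight <- tibble::tibble(x = seq(0, 1, length.out = 20), y = 0)
  expect_equal(linearity_index(straight, c(0, 0), c(1, 0)), 0)

  th <- seq(pi, 0, length.out = 2001)
  arc <- tibble::tibble(x = 0.5 + 0.5 * cos(th), y = 0.5 * sin(th))
  expect_equal(linearity_index(arc, c(0, 0), c(1, 0)), 0.5,
               tolerance = 1e-6)

  # rotation invariance of the whole scene
  rot <- function(df, a) tibble::tibble(
    x = cos(a) * df$x - sin(a) * df$y,
    y = sin(a) * df$x + cos(a) * df$y
  )
  a <- 1.1
  expect_equal(
    linearity_index(rot(arc, a), c(0, 0), c(cos(a), sin(a))),
    linearity_index(arc, c(0, 0), c(1, 0)),
    tolerance = 1e-9
  )
  expect_error(linearity_index(straight, c(0, 0), c(0, 0)), "coincide")
})

test_that("error ellipse axes come from the chi-square quantile", {
  # four points with exact sample variance 1 on both axes and zero
  # covariance: 95% semi-axes are sqrt(5.991) ~ 2.448 (chi-square table)
  a <- sqrt(3) / 2
  iso <- tibble::tibble(x = c(a, -a, a, -a), y = c(a, a, -a, -a))
  ell <- error_ellipse(iso, coverage = 0.95)
  expect_equal(ell$aspect_ratio, 1, tolerance = 1e-9)
  expect_equal(unname(ell$semi_axes), c(2.448, 2.448), tolerance = 1e-3)

  # covariance diag(4, 1): aspect ratio exactly 2
  anis <- tibble::tibble(x = c(2, -2, 0, 0) * sqrt(3) / 2,
                         y = c(0, 0, 1, -1) * sqrt(3) / 2)
  ell2 <- error_ellipse(anis)
  expect_equal(ell2$aspect_ratio, 2, tolerance = 1e-9)

  degen <- tibble::tibble(x = c(0, 1, 2), y = c(0, 1, 2))
  expect_error(error_ellipse(degen), "degenerate")
})

test_that("aspect ratio recovers a known axis-SD ratio at n = 500", {
  set.seed(41)
  r <- 2.5
  pts <- tibble::tibble(x = rnorm(500, 0, 1), y = rnorm(500, 0, r))
  ell <- error_ellipse(pts)
  expect_lt(abs(ell$aspect_ratio - r) / r, 0.05)
})

test_that("directional bias recovers injected per-angle errors", {
  # function-level recovery on constructed metrics
  set.seed(43)
  angles <- seq(0, 315, by = 45)
  mx <- tidyr::expand_grid(participant = 1:20, target_angle = angles,
                           rep = 1:11) |>
    dplyr::mutate(angle_at_pe = rnorm(dplyr::n(), 0, 2) +
                    ifelse(target_angle == 90, 3, 0))
  bias <- directional_bias(mx)
  expect_equal(nrow(bias), 8)
  expect_equal(bias$bias[bias$target_angle == 90], 3, tolerance = 0.8)
  expect_lt(max(abs(bias$bias[bias$target_angle != 90])), 0.8)

  # single trial per angle: the bias is that trial's error
  one <- tibble::tibble(target_angle = c(0, 90), angle_at_pe = c(-2, 4))
  b1 <- directional_bias(one)
  expect_equal(b1$bias, c(-2, 4))
})

test_that("effective ID follows the Shannon formulation with W_e = 4.133 SD", {
  on_axis <- c(-1, 1) * 0.0484 / sqrt(2)  # SD exactly 0.0484
  res <- effective_id(0.8, on_axis)
  expect_equal(res$W_e, 0.2, tolerance = 1e-3)
  expect_equal(res$id_e, log2(5), tolerance = 2e-2)
  # scale invariance: doubling D_e and W_e leaves ID unchanged
  res2 <- effective_id(1.6, 2 * on_axis)
  expect_equal(res2$id_e, res$id_e, tolerance = 1e-12)
  # monotonicity: more spread, less difficulty
  res3 <- effective_id(0.8, 3 * on_axis)
  expect_lt(res3$id_e, res$id_e)
  expect_warning(eid0 <- effective_id(0.8, c(0.1, 0.1)), "zero")
  expect_true(is.na(eid0$id_e))
})

test_that("the Fitts fit recovers an exactly linear law to machine precision", {
  pts <- tibble::tibble(id_e = c(1.2, 1.8, 2.4, 3.1),
                        mt = 35 + 243 * c(1.2, 1.8, 2.4, 3.1))
  fit <- fitts_fit(pts)
  expect_equal(fit$intercept, 35, tolerance = 1e-9)
  expect_equal(fit$slope, 243, tolerance = 1e-9)

  flat <- tibble::tibble(id_e = 1:4, mt = 500)
  expect_equal(fitts_fit(flat)$slope, 0, tolerance = 1e-12)

  # OLS residuals orthogonal to the predictor
  noisy <- tibble::tibble(id_e = runif(20, 1, 3))
  noisy$mt <- 50 + 200 * noisy$id_e + rnorm(20, 0, 30)
  fit2 <- fitts_fit(noisy)
  expect_lt(abs(sum(stats::residuals(fit2$fit) * noisy$id_e)), 1e-8)
  expect_error(fitts_fit(flat[1, ]), "distinct")
})

test_that("Fitts confidence intervals cover known parameters", {
  set.seed(47)
  a <- 35; b <- 243
  hits <- replicate(100, {
    id <- rep(c(1.2, 1.8, 2.4), each = 8)
    mt <- a + b * id + rnorm(length(id), 0, 60)
    ci <- stats::confint(fitts_fit(tibble::tibble(id_e = id, mt = mt))$fit)
    ci[1, 1] <= a && a <= ci[1, 2] && ci[2, 1] <= b && b <= ci[2, 2]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("broom-style accessors expose the Fitts fit", {
  pts <- tibble::tibble(id_e = c(1, 2, 3, 4), mt = 30 + 250 * c(1, 2, 3, 4) +
                          c(1, -1, 1, -1))
  fit <- fitts_fit(pts)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("(Intercept)", "id_e"))
  gl <- generics::glance(fit)
  expect_equal(gl$throughput, 1000 / gl$slope)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  ell <- error_ellipse(tibble::tibble(x = rnorm(30), y = rnorm(30, 0, 2)))
  expect_s3_class(generics::tidy(ell), "tbl_df")
  expect_s3_class(ggplot2::autoplot(ell), "ggplot")
})

test_that("participant summaries use the late successful-trial window", {
  ses <- small_exp1(seed = 51, n_cycles = 8)  # 64 trials/context
  ps <- participant_summary(ses, last_n = 20)
  expect_equal(nrow(ps), 2)
  expect_true(all(ps$n_selected == 40))  # 20 per staircase, pooled
  expect_true(all(ps$n_successful <= ps$n_selected))
  expect_true(all(is.finite(ps$asymptotic_limit)))
})

test_that("movement time and endpoint spread grow with target distance", {
  set.seed(52)
  ses <- simulate_experiment2(n_rounds = 2)
  mx <- trial_metrics(ses)
  ds <- distance_summary(mx)
  expect_equal(ds$target_distance, c(0.4, 0.6, 0.8))
  expect_true(all(diff(ds$mt) > 0))
  expect_true(all(diff(ds$W_e) > 0))
  # with purely multiplicative endpoint noise W_e scales with distance, so
  # the effective ID is near-constant across the three distances (a
  # documented property of the generator, not of human data)
  expect_true(all(is.finite(ds$id_e) & ds$id_e > 0))
  expect_lt(diff(range(ds$id_e)) / mean(ds$id_e), 0.25)
})

test_that("metrics are invariant under global workspace rotation", {
  p <- noiseless_params(undershoot_frac = 0.85)
  set.seed(53)
  m_by_angle <- lapply(c(0, 90, 225), function(ang) {
    tr <- simulate_trial(p, 0.8, ang, "point")
    seg <- segment_trial(tr$samples, tr$events,
                         target = 0.8 * c(cos(ang * pi / 180),
                                          sin(ang * pi / 180)))
    ses <- list(
      header = list(experiment = "exp1"),
      trials = tibble::tibble(trial = 1L, context = "point",
                              time_limit = NA_real_, target_distance = 0.8,
                              target_angle = ang,
                              target_x = 0.8 * cos(ang * pi / 180),
                              target_y = 0.8 * sin(ang * pi / 180),
                              start_x = 0, start_y = 0,
                              success = tr$success, fps = 60),
      samples = dplyr::mutate(tr$samples, trial = 1L, .before = 1),
      events = dplyr::mutate(tr$events, trial = 1L, .before = 1)
    )
    class(ses) <- "aimkin_session"
    trial_metrics(ses)
  })
  for (col in c("extent_at_pe", "angle_at_pe", "aligned_x", "aligned_y")) {
    vals <- vapply(m_by_angle, function(m) m[[col]], numeric(1))
    expect_lt(diff(range(vals)), 1e-6)
  }
})
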