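test_that("speed computation handles trivial motions", {
  t <- seq(0, 1000, length.out = 61)
  still <- tibble::tibble(t_ms = t, x = 0.3, y = -0.2)
  sp <- compute_speed(still)
  expect_true(all(sp$radial_speed == 0))
  expect_true(all(sp$tangential_speed == 0))

  uniform <- tibble::tibble(t_ms = t, x = t / 1000, y = 0)
  spu <- compute_speed(uniform)
  expect_equal(spu$tangential_speed, rep(1, nrow(spu)), tolerance = 1e-9)
  expect_equal(spu$radial_speed, rep(1, nrow(spu)), tolerance = 1e-9)

  expect_error(compute_speed(uniform[1:2, ]), "3 samples")
})

test_that("numeric peak speed matches the analytic minimum-jerk value", {
  pr <- min_jerk_profile(D = 1, T_ms = 500, dt_ms = 1000 / 60)
  path <- tibble::tibble(t_ms = pr$t_ms, x = pr$s, y = 0)
  sp <- compute_speed(path)
  expect_lt(abs(max(sp$tangential_speed) - 1.875 * 1 / 0.5),
            0.02 * 1.875 / 0.5)
})

test_that("onset is the first sample above threshold after target onset", {
  sp <- tibble::tibble(t_ms = c(10, 20, 30, 40),
                       radial_speed = c(0, 0.2, 0.6, 1.4),
                       tangential_speed = c(0, 0.2, 0.6, 1.4),
                       smoothed = FALSE)
  on <- detect_onset(sp, target_shown_t = 0)
  expect_equal(on$onset_t, 30)
  expect_equal(on$reaction, 30)
  expect_false(on$no_movement)

  quiet <- dplyr::mutate(sp, radial_speed = 0)
  expect_true(detect_onset(quiet, 0)$no_movement)
})

test_that("onset detection is monotone in the threshold", {
  set.seed(19)
  for (i in 1:50) {
    v <- abs(cumsum(rnorm(50, 0.05, 0.2)))
    sp <- tibble::tibble(t_ms = seq_along(v) * 10, radial_speed = v,
                         tangential_speed = v, smoothed = FALSE)
    ths <- sort(runif(3, 0, max(v)))
    ons <- vapply(ths, function(th) {
      o <- detect_onset(sp, 0, th)
      if (o$no_movement) Inf else o$onset_t
    }, numeric(1))
    expect_true(all(diff(ons) >= 0))
  }
})

test_that("primary end follows the local-minimum-or-threshold rule", {
  # single-peak profile decaying to rest: rule branch (b), first sample
  # below the onset threshold after the peak
  pr <- min_jerk_profile(1, 500, 1000 / 60)
  sp <- tibble::tibble(t_ms = pr$t_ms, radial_speed = pr$v,
                       tangential_speed = pr$v, smoothed = FALSE)
  pe <- detect_primary_end(sp, onset_t = 0, click_t = 1000)
  below <- sp$t_ms[sp$tangential_speed < 0.5 & sp$t_ms > 250]
  expect_equal(pe, below[1])

  # constructed two-bump profile: peak 2.0 at sample 10, local minimum 0.8
  # at sample 18 (< 50% of peak), second bump to 1.2: end at sample 18
  v <- c(seq(0.1, 2, length.out = 10), seq(1.9, 0.8, length.out = 8),
         seq(0.9, 1.2, length.out = 5), seq(1.1, 0.1, length.out = 7))
  sp2 <- tibble::tibble(t_ms = seq_along(v) * 10, radial_speed = v,
                        tangential_speed = v, smoothed = FALSE)
  expect_equal(detect_primary_end(sp2, onset_t = 0, click_t = 1000), 180)
})

test_that("target entries report boundary-inclusive intervals", {
  t <- seq(0, 100, by = 10)
  far <- tibble::tibble(t_ms = t, x = seq(0, 1, length.out = 11), y = 0.5)
  expect_equal(nrow(target_entries(far, c(0.5, 0))), 0)

  through <- tibble::tibble(t_ms = t, x = seq(0, 1, length.out = 11), y = 0)
  ent <- target_entries(through, c(0.5, 0))
  expect_equal(nrow(ent), 1)

  # pass through, leave, re-enter: two entries, last entry is the second
  x <- c(0, 0.25, 0.5, 0.75, 1.0, 0.75, 0.5, 0.5, 0.5)
  re <- tibble::tibble(t_ms = seq_along(x) * 10, x = x, y = 0)
  ent2 <- target_entries(re, c(0.5, 0))
  expect_equal(nrow(ent2), 2)
  expect_true(is.na(ent2$exit_t[2]))
  expect_gt(ent2$entry_t[2], ent2$entry_t[1])
})

test_that("noiseless trials are segmented within one frame of ground truth", {
  set.seed(23)
  p <- noiseless_params()
  for (D in c(0.4, 0.6, 0.8, 1)) {
    for (i in 1:5) {
      ang <- sample(seq(0, 315, 45), 1)
      tr <- simulate_trial(p, D, ang, "point")
      seg <- segment_trial(tr$samples, tr$events,
                           target = D * c(cos(ang * pi / 180),
                                          sin(ang * pi / 180)))
      gt <- tr$ground_truth
      expect_lt(abs(seg$onset_t - gt$true_onset), frame_ms(p))
      expect_lt(abs(seg$primary_end_t - gt$true_primary_end), frame_ms(p))
      expect_lt(abs(seg$last_entry_t - gt$true_last_entry), frame_ms(p))
      expect_equal(seg$click_t, gt$true_click)
    }
  }
})

test_that("phase durations sum exactly to the acquire time", {
  set.seed(24)
  p <- performer_params()
  n_checked <- 0
  for (i in 1:25) {
    D <- sample(c(0.4, 0.8, 1), 1)
    tr <- simulate_trial(p, D, 90, "look")
    if (!tr$success) next
    seg <- segment_trial(tr$samples, tr$events, target = c(0, D))
    n_checked <- n_checked + 1
    expect_identical(seg$reaction + seg$primary_mt + seg$correction +
                       seg$dwell, seg$acquire)
    expect_gte(seg$correction, 0)
  }
  expect_gt(n_checked, 10)
})

test_that("early target entry clamps the correction phase to zero", {
  set.seed(25)
  # noiseless default: the primary movement ends inside the target, so the
  # last entry precedes the primary end and correction must be 0
  tr <- simulate_trial(noiseless_params(), 1, 0, "point")
  seg <- segment_trial(tr$samples, tr$events, target = c(1, 0))
  expect_lt(seg$last_entry_t, seg$primary_end_t)
  expect_identical(seg$correction, 0)
  expect_equal(seg$dwell, seg$click_t - seg$primary_end_t)
})

test_that("segmentation is invariant to the context flag", {
  # with zero Look penalties the two contexts are behaviourally identical,
  # so the same random draws give identical traces and segmentations
  p <- noiseless_params(look_rt_penalty = 0, look_corr_penalty = 0)
  target <- 0.8 * c(cos(3 * pi / 4), sin(3 * pi / 4))
  set.seed(26)
  tp <- simulate_trial(p, 0.8, 135, "point")
  set.seed(26)
  tl <- simulate_trial(p, 0.8, 135, "look")
  expect_identical(tp$samples, tl$samples)
  expect_identical(segment_trial(tp$samples, tp$events, target),
                   segment_trial(tl$samples, tl$events, target))
})
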