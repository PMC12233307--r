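test_that("the generator is byte-identical under a fixed seed", {
  cfg <- generative_config(n_participants = 2, n_trials = 5, seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$gaze, b$gaze)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
})

test_that("the short-observation variant moves the GO signal to 2 s", {
  cfg <- generative_config(n_participants = 1, n_trials = 3,
                           experiment = "sLAN", seed = 3)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$trials$go_time_ms == 2000))
  expect_true(all(ds$trials$stim_on_ms == 2000))
})

test_that("attention schedules alternate sides and respect the dwell law", {
  sched <- simulate_attention_schedule(8000, dwell_mean_ms = 400,
                                       dwell_shape = 4, seed = 1)
  expect_true(all(sched$side[-1] != sched$side[-nrow(sched)]))
  expect_true(all(sched$end_ms > sched$start_ms))
  expect_true(all(diff(sched$start_ms) > 0))
  # gaps between dwells are exactly the saccade gap (except truncation)
  gaps <- sched$start_ms[-1] - sched$end_ms[-nrow(sched)]
  expect_true(all(abs(gaps - 40) < 1e-9))

  # infinite mean dwell: one dwell, no alternation
  one <- simulate_attention_schedule(4000, dwell_mean_ms = Inf, seed = 2)
  expect_identical(nrow(one), 1L)
  expect_equal(one$end_ms, 4000)

  # renewal expectation: alternation count over 4000 ms with 400 ms mean
  # dwells and 40 ms gaps is about 4000/440 - 1 ~ 8; allow sampling error
  counts <- vapply(1:200, function(s) {
    nrow(simulate_attention_schedule(4000, 400, 4, seed = s)) - 1L
  }, integer(1))
  expect_gt(mean(counts), 6.5)
  expect_lt(mean(counts), 9.5)
})

test_that("gaze streams follow the schedule at the sampling rate", {
  geom <- screen_geometry()
  sched <- simulate_attention_schedule(4000, 500, 4, seed = 5)
  g <- generate_gaze_stream(sched, geom, jitter_sd_px = 0,
                            duration_ms = 4000, seed = 5)
  expect_equal(nrow(g), 240)  # 60 Hz x 4 s
  # zero jitter puts every valid sample exactly at an AOI centre
  centres_x <- c((geom$aoi_left[1] + geom$aoi_left[3]) / 2,
                 (geom$aoi_right[1] + geom$aoi_right[3]) / 2)
  expect_true(all(g$x_px[g$valid == 1] %in% centres_x))
  # empty schedule: all-invalid stream
  empty <- generate_gaze_stream(sched[0, ], geom, duration_ms = 1000)
  expect_true(all(empty$valid == 0))
})

test_that("dwell extraction round-trips a generated stream", {
  geom <- screen_geometry()
  for (s in 1:5) {
    sched <- simulate_attention_schedule(6000, 500, 6, seed = s)
    g <- generate_gaze_stream(sched, geom, jitter_sd_px = 5,
                              duration_ms = 6000, seed = s)
    dw <- extract_dwells(g, geom, min_dwell_ms = 50, max_gap_ms = 30)
    expect_identical(dw$side, sched$side)
    # boundaries recovered to within one sample period per edge
    expect_true(all(abs(dw$start_ms - sched$start_ms) <= 1000 / 60 + 1e-9))
  }
})

test_that("ratings map latent confidence onto the scale correctly", {
  r1 <- ratings_from_latents(1, noise_sd = 0, seed = 1)
  expect_identical(r1$C, 10L)
  r2 <- ratings_from_latents(0.5, noise_sd = 0, seed = 1)
  expect_identical(r2$C, 5L)
  expect_error(ratings_from_latents(1.2), "0, 1")
  # law of large numbers: mean reported confidence tracks the latent
  set.seed(9)
  r <- ratings_from_latents(rep(0.62, 1e4), noise_sd = 0.05)
  expect_lt(abs(mean(r$C) / 10 - 0.62), 0.01)
  expect_true(all(r$C >= 0 & r$C <= 10))
})

test_that("decision times are positive and timeouts become non-responses", {
  co <- cached_cohort("hybrid")
  tr <- co$ds$trials
  expect_true(all(is.na(tr$decision_time_ms) | tr$decision_time_ms > 0))
  expect_identical(is.na(tr$decision_time_ms), tr$button == "none")
  expect_true(all(tr$decision_time_ms <= 4000, na.rm = TRUE))
  # ratings only exist for responded trials
  expect_true(all(is.na(tr$C[tr$button == "none"])))
})

test_that("sequential generation links confidence to the attention-time difference", {
  co <- cached_cohort("sequential", n_participants = 8, n_trials = 80)
  tru <- merge(co$ds$truth, co$ds$trials[, c("participant_id", "trial_index", "C")],
               by = c("participant_id", "trial_index"))
  tru <- tru[!is.na(tru$C) & !is.na(tru$dt1_ms), ]
  expect_gt(nrow(tru), 500)
  expect_gt(cor(tru$C, tru$dt1_ms - tru$dt2_ms), 0)
})

test_that("the motor-reversal variant swaps button and image side", {
  cfg <- generative_config(n_participants = 2, n_trials = 10,
                           experiment = "rLAN", seed = 13)
  ds <- simulate_dataset(cfg)
  tr <- ds$trials[ds$trials$button != "none", ]
  expect_true(all(tr$button != tr$selected_side))
  expect_identical(selected_side_from_button(tr$button, tr$experiment),
                   tr$selected_side)
})

test_that("configurations validate their inputs and survive a JSON round-trip", {
  expect_error(generative_config(n_trials = 0), "positive")
  expect_error(generative_config(experiment = "XXX"))
  expect_error(generative_config(rating_scale_max = 7), "9 or 10")
  cfg <- generative_config(n_participants = 3, n_trials = 12,
                           experiment = "sLAN", seed = 99)
  path <- tempfile(fileext = ".json")
  write_config_json(cfg, path)
  back <- read_config_json(path)
  expect_equal(back$timeline$stim_on_ms, 2000)
  expect_identical(back$seed, 99L)
  expect_identical(simulate_dataset(back)$trials, simulate_dataset(cfg)$trials)
})
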