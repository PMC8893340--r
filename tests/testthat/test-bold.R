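test_that("the double-gamma HRF has the canonical shape", {
  expect_equal(hrf(0), 0)
  expect_true(all(hrf(c(-5, -0.1)) == 0))
  grid <- seq(0, 32, by = 0.1)
  h <- hrf(grid)
  expect_equal(grid[which.max(h)], 5, tolerance = 0.05)
  expect_equal(max(h), 1, tolerance = 1e-6) # unit peak
  auc <- sum(h) * 0.1
  expect_true(is.finite(auc) && auc > 0)
  # undershoot present and later than the peak
  expect_lt(min(h), 0)
  expect_gt(grid[which.min(h)], 10)
})

test_that("event schedules respect the stated timing", {
  tr <- quiet_annotate(build_session(seed = 901))
  sch <- build_event_schedule(tr, seed = 902)
  wide <- tidyr::pivot_wider(
    dplyr::select(sch, block, trial_index, event, onset, duration),
    names_from = event, values_from = c(onset, duration)
  )
  expect_equal(unique(wide$duration_t4), 1.5) # partner estimate display
  expect_equal(unique(wide$duration_t6), 3) # final display
  # the three jitters are uniform draws from [1.5, 4.5] s
  j1 <- wide$onset_t4 - (wide$onset_t3 + wide$duration_t3)
  j2 <- wide$onset_t5 - (wide$onset_t4 + wide$duration_t4)
  expect_true(all(j1 >= 1.5 & j1 <= 4.5))
  expect_true(all(j2 >= 1.5 & j2 <= 4.5))
  # onsets strictly increase within a trial
  expect_true(all(wide$onset_t1 < wide$onset_t2 &
    wide$onset_t2 < wide$onset_t3 &
    wide$onset_t3 < wide$onset_t4 &
    wide$onset_t4 < wide$onset_t5 &
    wide$onset_t5 < wide$onset_t6))
  # run lengths near the 12-17 minute band of the emulated scan runs
  expect_true(all(sch$run_length / 60 > 10 & sch$run_length / 60 < 17))
  # a whole number of TRs
  n_tr <- sch$run_length / 3.74
  expect_equal(n_tr, round(n_tr), tolerance = 1e-9)
})

test_that("signal synthesis is linear in the encoding weights", {
  tr <- quiet_annotate(build_session(seed = 903))
  sch <- build_event_schedule(tr, seed = 904)
  silent <- noise_params(
    ar_rho = 0, ar_sd = 0, white_sd = 0,
    motion_step = 0, motion_gain = 0
  )
  base_only <- encoding_spec()[1:6, ]
  enc1 <- encoding_spec()
  enc2 <- enc1
  enc2$weight[enc2$modulator == "conf"] <-
    2 * enc2$weight[enc2$modulator == "conf"]
  s0 <- synthesize_roi_signal(sch, tr, base_only, silent, seed = 1)
  s1 <- synthesize_roi_signal(sch, tr, enc1, silent, seed = 1)
  s2 <- synthesize_roi_signal(sch, tr, enc2, silent, seed = 1)
  d1 <- s1$samples$value - s0$samples$value
  d2 <- s2$samples$value - s0$samples$value
  # doubling the confidence weight doubles its contribution
  enc_ci <- enc1[enc1$modulator != "conf", ]
  s_ci <- synthesize_roi_signal(sch, tr, enc_ci, silent, seed = 1)
  conf_part1 <- s1$samples$value - s_ci$samples$value
  conf_part2 <- s2$samples$value - s_ci$samples$value
  expect_equal(conf_part2, 2 * conf_part1, tolerance = 1e-9)
  expect_true(any(abs(d1) > 0) && any(abs(d2) > 0))
})

test_that("zero weights and zero noise give the bare baseline response train", {
  tr <- quiet_annotate(build_session(seed = 905))
  sch <- build_event_schedule(tr, seed = 906)
  silent <- noise_params(0, 0, 0, 0, 0)
  enc0 <- encoding_spec()
  enc0$weight[enc0$modulator != "baseline"] <- 0
  base_only <- encoding_spec()[1:6, ]
  a <- synthesize_roi_signal(sch, tr, enc0, silent, seed = 2)
  b <- synthesize_roi_signal(sch, tr, base_only, silent, seed = 2)
  expect_equal(a$samples$value, b$samples$value, tolerance = 1e-12)
})

test_that("unknown modulators in the encoding are a config error", {
  tr <- quiet_annotate(build_session(seed = 907))
  sch <- build_event_schedule(tr, seed = 908)
  bad <- encoding_spec(tibble::tibble(
    event = "t5", role = "revise", condition = "any",
    modulator = "mood", weight = 1
  ))
  expect_error(
    synthesize_roi_signal(sch, tr, bad),
    "unknown modulator"
  )
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  set.seed(909)
  x <- ar1_noise(1e4, rho = 0.3, sd_innov = 1)
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.3), 0.03)
})

test_that("BOLD synthesis is deterministic under a seed", {
  tr <- quiet_annotate(build_session(seed = 910))
  sch <- build_event_schedule(tr, seed = 911)
  a <- synthesize_roi_signal(sch, tr, seed = 912)
  b <- synthesize_roi_signal(sch, tr, seed = 912)
  expect_identical(a$samples, b$samples)
  expect_identical(a$nuisance, b$nuisance)
})

test_that("an uncoupled noiseless target is the seed itself", {
  tr <- quiet_annotate(build_session(seed = 913))
  sch <- build_event_schedule(tr, seed = 914)
  pair <- synthesize_coupled_pair(
    sch, tr,
    coupling = coupling_spec(
      alpha = 1, gamma_conf = 0, gamma_inf = 0,
      gamma_conf_inf = 0, noise_sd = 0
    ),
    seed = 915
  )
  fit <- lm(pair$target$samples$value ~ pair$seed$samples$value)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-9)
})
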