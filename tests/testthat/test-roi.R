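test_that("residualisation removes exactly the nuisance span", {
  set.seed(1001)
  n <- 200
  signal <- rnorm(n)
  # nuisance equal to the signal: residual collapses to zero
  expect_equal(residualize(signal, cbind(signal)), rep(0, n),
    tolerance = 1e-10
  )
  # orthogonal nuisance: signal unchanged up to mean removal
  nuis <- matrix(rnorm(n * 2), n, 2)
  nuis <- qr.resid(qr(cbind(1, signal)), nuis)
  r <- residualize(signal, nuis)
  expect_equal(r, signal - mean(signal), tolerance = 1e-10)
  # constructed motion mixture is removed below numerical noise
  motion <- apply(matrix(rnorm(n * 6, 0, 0.1), n, 6), 2, cumsum)
  mixed <- rnorm(n) + motion %*% runif(6, -1, 1)
  clean <- residualize(as.numeric(mixed), motion)
  expect_true(all(abs(cor(clean, motion)) < 1e-6))
  expect_warning(
    residualize(signal, cbind(nuis, nuis[, 1])),
    "rank deficient"
  )
})

test_that("spline upsampling reproduces smooth series on the fine grid", {
  t_coarse <- seq(0, 374, by = 3.74)
  # constant series stays constant
  up <- upsample_series(t_coarse, rep(2.5, length(t_coarse)))
  expect_equal(up$value, rep(2.5, nrow(up)), tolerance = 1e-9)
  # sample count ratio ~ TR / dt = 18.7
  expect_equal(nrow(up) / length(t_coarse), 18.7, tolerance = 0.1)
  # sinusoid well below Nyquist: interior error < 1% of amplitude
  y <- sin(2 * pi * t_coarse / 80)
  up <- upsample_series(t_coarse, y)
  interior <- up$time > 10 & up$time < 364
  err <- abs(up$value - sin(2 * pi * up$time / 80))
  expect_lt(max(err[interior]), 0.01)
})

test_that("epoch extraction follows the 75-point, 1-s-pre-onset geometry", {
  time <- seq(0, 200, by = 0.2)
  value <- rnorm(length(time))
  em <- extract_epochs(time, value, onsets = 100)
  expect_equal(dim(em), c(1, 75))
  expect_equal(attr(em, "time_rel"), seq(-1, 13.8, by = 0.2))
  # row holds the samples at 99.0, 99.2, ..., 113.8 s
  expect_equal(as.numeric(em), value[time >= 98.9 & time <= 113.9])

  onsets <- seq(10, 180, length.out = 30)
  expect_equal(dim(extract_epochs(time, value, onsets)), c(30, 75))

  # an impulse 5 s after onset lands at 0-based column 30 ((5+1)/0.2)
  value2 <- numeric(length(time))
  value2[time == 105] <- 1
  em2 <- extract_epochs(time, value2, onsets = 100)
  expect_equal(which(em2[1, ] == 1) - 1L, 30L)
  expect_equal(attr(em2, "time_rel")[which(em2[1, ] == 1)], 5)

  expect_warning(
    em3 <- extract_epochs(time, value, onsets = c(0.5, 100, 195)),
    "dropped"
  )
  expect_equal(nrow(em3), 1)
  expect_equal(attr(em3, "kept"), c(FALSE, TRUE, FALSE))
})

test_that("per-timepoint regression recovers constructed encodings", {
  set.seed(1002)
  n_trials <- 40
  time_rel <- seq(-1, 13.8, by = 0.2)
  conf <- rnorm(n_trials)
  rt <- rnorm(n_trials)
  shape <- hrf(time_rel)
  w <- -0.8
  epochs <- structure(
    outer(rep(1, n_trials), 0.5 + shape) +
      outer(as.numeric(scale(conf)) * w, shape),
    time_rel = time_rel, class = c("epoch_matrix", "matrix", "array")
  )
  bt <- beta_timecourse(epochs, data.frame(conf = conf, rt = rt))
  expect_equal(unname(bt["conf", ]), w * shape, tolerance = 1e-8)
  expect_equal(unname(bt["rt", ]), rep(0, 75), tolerance = 1e-8)
  peak <- which.max(abs(bt["conf", ]))
  expect_lt(bt["conf", peak], 0)

  # permuting the modulator across trials destroys the association
  bt_perm <- beta_timecourse(epochs, data.frame(conf = sample(conf)))
  expect_lt(max(abs(bt_perm["conf", ])), 0.35)

  # two modulators injected at weights 2:1 recover betas in ratio 2
  inf <- rnorm(n_trials)
  epochs2 <- structure(
    outer(as.numeric(scale(conf)) * 2, shape) +
      outer(as.numeric(scale(inf)) * 1, shape),
    time_rel = time_rel, class = c("epoch_matrix", "matrix", "array")
  )
  bt2 <- beta_timecourse(epochs2, data.frame(conf = conf, inf = inf))
  pk <- which.max(abs(bt2["inf", ]))
  expect_equal(unname(bt2["conf", pk] / bt2["inf", pk]), 2, tolerance = 1e-6)

  expect_warning(
    bt3 <- beta_timecourse(epochs, data.frame(conf = conf, flat = rep(1, n_trials))),
    "Constant modulator"
  )
  expect_true(all(is.na(bt3["flat", ])))
})

test_that("leave-one-out peak testing is unbiased and symmetric", {
  time_rel <- seq(-1, 13.8, by = 0.2)
  shape <- hrf(time_rel)
  # identical positive-peaked curves: every left-out value is the peak
  betas <- matrix(rep(3 * shape, 20), nrow = 20, byrow = TRUE)
  attr(betas, "time_rel") <- time_rel
  res <- loo_peak_test(betas)
  expect_equal(res$values$beta, rep(3, 20))
  expect_equal(unique(res$values$peak_time), 5)
  expect_lt(res$test$p.value, 0.01)
  # sign flip negates the values and keeps p
  res_neg <- loo_peak_test(-betas)
  expect_equal(res_neg$values$beta, -res$values$beta)
  expect_equal(res_neg$test$p.value, res$test$p.value)
  expect_error(loo_peak_test(betas[1:2, ]), "at least 3")
})

test_that("left-out peak values are individually unbiased under the null", {
  # Leave-one-out selection removes bias from each collected value: the
  # peak time for participant i is chosen without participant i, so
  # E[beta_i at that time] = 0 under a null of zero-mean betas. (The
  # *group* test on the collected values is a different matter: the
  # selections share data across participants, which correlates the
  # values; see the methods vignette.)
  set.seed(1003)
  reps <- 400
  means <- numeric(reps)
  for (r in seq_len(reps)) {
    betas <- matrix(rnorm(15 * 75), 15, 75)
    means[r] <- mean(loo_peak_test(betas)$values$beta)
  }
  mc_se <- sd(means) / sqrt(reps)
  expect_lt(abs(mean(means)), 3 * mc_se)
})

test_that("PPI estimation respects regression identities", {
  set.seed(1004)
  n_trials <- 40
  time_rel <- seq(-1, 13.8, by = 0.2)
  seed_ep <- structure(matrix(rnorm(n_trials * 75), n_trials, 75),
    time_rel = time_rel, class = c("epoch_matrix", "matrix", "array")
  )
  conf <- rnorm(n_trials)
  inf <- rnorm(n_trials)
  # null coupling: target = 1.2 * seed + tiny noise
  target <- structure(1.2 * unclass(seed_ep) +
    matrix(rnorm(n_trials * 75, 0, 0.01), n_trials, 75),
  time_rel = time_rel, class = c("epoch_matrix", "matrix", "array")
  )
  pp <- ppi_timecourse(target, seed_ep, conf, inf)
  expect_equal(mean(pp["seed", ]), 1.2, tolerance = 0.01)
  for (term in c("seed:conf", "seed:inf", "seed:conf:inf")) {
    expect_lt(max(abs(pp[term, ])), 0.05)
  }
  # scaling the seed by c scales its coefficients by 1/c
  seed_scaled <- structure(5 * unclass(seed_ep),
    time_rel = time_rel, class = c("epoch_matrix", "matrix", "array")
  )
  pp_s <- ppi_timecourse(target, seed_scaled, conf, inf)
  expect_equal(unname(pp_s["seed", ]), unname(pp["seed", ]) / 5,
    tolerance = 1e-8
  )
  expect_equal(unname(pp_s["conf", ]), unname(pp["conf", ]),
    tolerance = 1e-6
  )
  # known multiplicative coupling on the triple interaction
  zc <- as.numeric(scale(conf))
  zi <- as.numeric(scale(inf))
  target2 <- structure(
    (1 + 0.5 * zc * zi) * unclass(seed_ep),
    time_rel = time_rel, class = c("epoch_matrix", "matrix", "array")
  )
  pp2 <- ppi_timecourse(target2, seed_ep, conf, inf)
  expect_equal(mean(pp2["seed:conf:inf", ]), 0.5, tolerance = 0.01)
})

test_that("windowed PPI coefficients cover 2-3 s and feed a lawful surface", {
  time_rel <- seq(-1, 13.8, by = 0.2)
  in_window <- which(time_rel >= 2 & time_rel <= 3)
  expect_length(in_window, 6) # 2.0, 2.2, ..., 3.0
  base <- matrix(0, 8, 75, dimnames = list(c(
    "(Intercept)", "seed", "conf", "inf", "conf:inf",
    "seed:conf", "seed:inf", "seed:conf:inf"
  ), NULL))
  base["seed", in_window] <- 2
  bt <- structure(base,
    time_rel = time_rel,
    class = c("beta_timecourse", "matrix", "array")
  )
  w <- ppi_window_coefficients(list(bt))
  expect_equal(unname(w["seed"]), 2)

  # flat surface when all interactions are zero
  g0 <- connectivity_grid(c(seed = 1))
  expect_equal(unique(g0$coupling), 1)
  expect_equal(nrow(g0), 17^2)
  # pure conf x inf term: saddle, symmetric under joint sign flip
  g1 <- connectivity_grid(c(seed = 0, `seed:conf:inf` = 0.5))
  flipped <- dplyr::arrange(
    dplyr::mutate(g1, conf_z = -conf_z, inf_z = -inf_z),
    conf_z, inf_z
  )
  expect_equal(flipped$coupling, dplyr::arrange(g1, conf_z, inf_z)$coupling)
  expect_equal(
    dplyr::filter(g1, conf_z == 2, inf_z == 2)$coupling,
    -dplyr::filter(g1, conf_z == 2, inf_z == -2)$coupling
  )
})

test_that("the pipeline is invariant to constant signal offsets", {
  tr <- quiet_annotate(build_session(seed = 1005))
  sch <- build_event_schedule(tr, seed = 1006)
  sig <- synthesize_roi_signal(sch, tr, seed = 1007)
  shifted <- sig
  shifted$samples$value <- shifted$samples$value + 57.3
  re1 <- roi_epochs(sig, sch, tr, "t5", "revise", "human")
  re2 <- roi_epochs(shifted, sch, tr, "t5", "revise", "human")
  b1 <- beta_timecourse(re1$epochs, eq3_modulators(re1$trials))
  b2 <- beta_timecourse(re2$epochs, eq3_modulators(re2$trials))
  expect_equal(unclass(b1), unclass(b2), tolerance = 1e-8)
})
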