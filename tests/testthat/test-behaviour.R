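make_manual_trials <- function() {
  tibble::tibble(
    participant_id = "P1",
    block = 1L,
    trial_index = 1:4,
    role = c("observe", "revise", "observe", "revise"),
    cover_story = "human",
    susceptibility = "susceptible",
    # observe trials: partner revises towards the participant
    self_initial = c(0, 0, 10, 100),
    partner_initial = c(90, 60, 220, 160),
    reviser_final = c(45, 30, 295, 130), # half-way revisions
    confidence = c(4, 3, 2, 6)
  )
}

test_that("annotation recomputes both statistics from the angles", {
  ann <- annotate_trials(make_manual_trials())
  obs <- dplyr::filter(ann, role == "observe")
  rev <- dplyr::filter(ann, role == "revise")
  expect_equal(obs$influence_stat, c(0.5, 0.5))
  expect_true(all(is.na(obs$revision_stat)))
  expect_equal(rev$revision_stat, c(0.5, 0.5))
  expect_true(all(is.na(rev$influence_stat)))
  expect_equal(rev$prev_influence, c(0.5, 0.5))
  expect_equal(ann$conf_norm[ann$confidence == 3], 0.5)
  expect_equal(unique(ann$cond_dummy), 1)
  expect_error(
    annotate_trials(dplyr::select(make_manual_trials(), -confidence)),
    "missing column"
  )
})

test_that("zero-disagreement trials are dropped with a message", {
  tr <- make_manual_trials()
  tr$partner_initial[1] <- tr$self_initial[1] # no initial gap
  tr$reviser_final[1] <- tr$self_initial[1]
  expect_message(ann <- annotate_trials(tr), "Dropping 2")
  # the observe trial and the revise trial that lost its lag both go
  expect_equal(nrow(ann), 2)
})

test_that("annotation is invariant to global rotation of all angles", {
  coh <- small_cohort(n = 4, seed = 801)
  ann <- quiet_annotate(coh$trials)
  rot <- coh$trials
  for (col in c("target", "self_initial", "partner_initial", "reviser_final")) {
    rot[[col]] <- norm_angle(rot[[col]] + 137.3)
  }
  ann_rot <- quiet_annotate(rot)
  expect_equal(ann_rot$revision_stat, ann$revision_stat, tolerance = 1e-9)
  expect_equal(ann_rot$influence_stat, ann$influence_stat, tolerance = 1e-9)
})

test_that("fits are invariant to participant relabelling", {
  coh <- small_cohort(n = 12, seed = 802)
  ann <- quiet_annotate(coh$trials)
  f1 <- suppressWarnings(fit_lmm2(ann, "human"))
  relabelled <- dplyr::mutate(
    ann,
    participant_id = factor(participant_id,
      levels = sample(unique(participant_id))
    )
  )
  f2 <- suppressWarnings(fit_lmm2(relabelled, "human"))
  expect_equal(tidy(f2)$estimate, tidy(f1)$estimate, tolerance = 1e-6)
})

test_that("noise-free generation is identified exactly", {
  p <- agent_params(
    sd_intercept = 0, sd_conf = 0, sd_inf = 0,
    residual_sd = 0
  )
  coh <- generate_cohort(10, params = p, seed = 803)
  ann <- quiet_annotate(coh$trials)
  rev <- dplyr::filter(
    ann, role == "revise", cover_story == "human",
    !is.na(prev_influence)
  )
  # OLS oracle: with zero noise the coefficients are exactly the
  # generating ones (no trial hit the truncation bounds here)
  ols <- lm(
    revision_stat ~ conf_norm * prev_influence,
    data = rev
  )
  expect_equal(unname(coef(ols)), unname(p$beta_human), tolerance = 1e-7)
})

test_that("both mixed models recover their generating coefficients on one cohort", {
  coh <- generate_cohort(60, seed = 804)
  ann <- quiet_annotate(coh$trials)
  fh <- suppressWarnings(fit_lmm2(ann, "human"))
  truth <- generating_effects(coh$params, "human")
  got <- dplyr::left_join(tidy(fh), truth, by = "term")
  expect_true(all(abs(got$estimate - got$truth) < 0.06))
  expect_s3_class(glance(fh), "tbl_df")
  expect_equal(glance(fh)$n_participants, 60)

  coh1 <- generate_cohort(60, params = agent_params(model = "lmm1"), seed = 805)
  f1 <- suppressWarnings(fit_lmm1(quiet_annotate(coh1$trials)))
  truth1 <- generating_effects(coh1$params)
  got1 <- dplyr::left_join(tidy(f1), truth1, by = "term")
  expect_true(all(abs(got1$estimate - got1$truth) < 0.08))
})

test_that("the shipped random structure beats the confidence-fixed variant on BIC", {
  coh <- generate_cohort(40, seed = 806)
  ann <- quiet_annotate(coh$trials)
  full <- suppressWarnings(fit_lmm2(ann, "human"))
  rev <- dplyr::filter(
    ann, role == "revise", cover_story == "human",
    !is.na(prev_influence)
  )
  conf_fixed <- suppressWarnings(lmerTest::lmer(
    revision_stat ~ conf_norm * prev_influence +
      (1 + prev_influence || participant_id),
    data = rev, REML = TRUE
  ))
  expect_lt(glance(full)$BIC, BIC(conf_fixed))
})

test_that("sliding windows have length n - 4 and average correctly", {
  coh <- small_cohort(n = 3, seed = 807)
  ann <- quiet_annotate(coh$trials)
  w <- sliding_window_revision(ann)
  counts <- dplyr::count(w, participant_id, block)
  # 15 revision trials per block unless a trial was dropped
  expect_true(all(counts$n %in% c(10, 11)))
  # constant series: every window mean equals the constant
  expect_equal(
    window_means(rep(0.4, 15), 5, 1)$mean_revision,
    rep(0.4, 11)
  )
  # non-constant series: window k averages trials k..k+4
  expect_equal(
    window_means(as.numeric(1:15), 5, 1)$mean_revision,
    as.numeric(3:13)
  )
  expect_equal(
    window_means(as.numeric(1:15), 5, 2)$mean_revision,
    as.numeric(c(3, 5, 7, 9, 11, 13))
  )
  expect_equal(nrow(window_means(rep(0, 4), 5, 1)), 0)
})

test_that("reciprocity ramp produces rising revision towards susceptible partners", {
  set.seed(808)
  coh <- generate_cohort(40, params = agent_params(ramp = 0.6), seed = 808)
  ann <- quiet_annotate(coh$trials)
  w <- dplyr::filter(
    sliding_window_revision(ann),
    cover_story == "human", susceptibility == "susceptible"
  )
  firsts <- dplyr::filter(
    dplyr::group_by(w, participant_id, block),
    window == min(window)
  )$mean_revision
  lasts <- dplyr::filter(
    dplyr::group_by(w, participant_id, block),
    window == max(window)
  )$mean_revision
  expect_gt(mean(lasts), mean(firsts))
})

test_that("signed-rank test matches exhaustive enumeration and handles edge cases", {
  d <- c(1.2, -0.8, 2.5, 0.7, -3.1, 1.9, 0.4, -2.2)
  res <- signed_rank(d)
  expect_equal(res$p.value, enumerate_signed_rank_p(d))
  expect_equal(res$statistic, sum(rank(abs(d))[d > 0]))
  # flipping every difference leaves the two-sided p unchanged
  expect_equal(signed_rank(-d)$p.value, res$p.value)
  # identical samples: degenerate, p = 1
  z <- signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$p.value, 1)
  expect_true(z$degenerate)
  # large-sample branch uses the continuity-corrected normal approximation
  set.seed(9)
  big <- signed_rank(rnorm(60, 0.5), mu = 0)
  expect_equal(big$method, "normal approximation")
  expect_lt(big$p.value, 0.05)
})

test_that("Holm adjustment is the step-down procedure", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(rep(0.02, 4))[1], min(4 * 0.02, 1))
  expect_true(all(diff(sort(holm_adjust(c(0.001, 0.2, 0.03, 0.9)))) >= 0))
  expect_error(holm_adjust(c(0.1, NA)), "finite")
})
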