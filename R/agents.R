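#' Generative parameters of a synthetic participant cohort
#'
#' Bundles everything needed to simulate a participant: perceptual noise,
#' the confidence report model, the revision model (fixed effects,
#' participant-level random-effect SDs and residual SD) and reaction-time
#' parameters.
#'
#' Two generative revision models are supported, matching the two
#' mixed-effects analyses:
#' * `model = "lmm2"`: condition-specific coefficient sets
#'   (intercept, confidence, previous influence, confidence x influence),
#'   with random intercept and random confidence and influence slopes.
#'   Defaults mirror the reported human-condition estimates
#'   (-0.3, 0.17, -0.21) and computer-condition estimates
#'   (-0.37, 0.01, -0.03).
#' * `model = "lmm1"`: a single 8-coefficient set over both conditions
#'   with the condition dummy coded 1 = human, 2 = computer, random
#'   intercept and confidence slope only. Defaults mirror the reported
#'   joint-model estimates (confidence -0.33, influence 0.11,
#'   condition 0.07, confidence x influence -0.4,
#'   confidence x condition -0.1, influence x condition -0.09,
#'   triple interaction 0.21).
#'
#' Intercepts, random-effect SDs and the residual SD are not reported
#' quantities; the defaults keep the linear predictor comfortably inside
#' the `[0, 1]` range the task enforces, so that truncation of the
#' Gaussian residual is rare and fixed effects are recoverable without
#' material bias (see the methods vignette).
#'
#' `kappa_subject = 1.02` puts the mean absolute perceptual error near
#' 56.8 degrees; the confidence cutpoints act on an internal precision
#' signal (negative absolute error plus Gaussian noise, SD
#' `conf_noise_sd` degrees) and give confidence levels 5-6 on roughly a
#' quarter of trials, so the partner's high-confidence branch is
#' exercised.
#'
#' @param model Generative revision model, `"lmm2"` (condition-specific)
#'   or `"lmm1"` (joint with condition dummy).
#' @param beta_human,beta_computer Length-4 coefficient vectors
#'   (intercept, confidence, influence, confidence x influence) used when
#'   `model = "lmm2"`.
#' @param beta_joint Length-8 coefficient vector used when
#'   `model = "lmm1"`.
#' @param sd_intercept,sd_conf,sd_inf Random-effect SDs (the influence
#'   slope varies only under `"lmm2"`).
#' @param residual_sd SD of the Gaussian revision residual (truncated to
#'   `[0, 1]`).
#' @param kappa_subject Von Mises concentration of initial estimates
#'   around the target.
#' @param conf_noise_sd SD (degrees) of the noise on the internal
#'   precision signal.
#' @param conf_cutpoints Five increasing thresholds binning the precision
#'   signal into confidence 1-6.
#' @param ramp Optional reciprocity-learning coefficient (default 0):
#'   adds `ramp * (trial/30) * (prev_influence - 0.35)` to the linear
#'   predictor so revision drifts apart between susceptible and
#'   insusceptible partners over a block, emulating the within-block
#'   dynamics seen in sliding-window analyses.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters
#'   (seconds) shared by the timed events.
#' @param setting `"fmri"` or `"behavioural"`; controls the partner's
#'   high-confidence window width (+/-50 vs +/-20 degrees).
#' @return An object of class `agent_params` (a list).
#' @export
agent_params <- function(model = c("lmm2", "lmm1"),
                         beta_human = c(
                           intercept = 0.55, conf = -0.3,
                           inf = 0.17, conf_inf = -0.21
                         ),
                         beta_computer = c(
                           intercept = 0.55, conf = -0.37,
                           inf = 0.01, conf_inf = -0.03
                         ),
                         beta_joint = c(
                           intercept = 0.7, conf = -0.33, inf = 0.11,
                           cond = 0.07, conf_inf = -0.4, conf_cond = -0.1,
                           inf_cond = -0.09, conf_inf_cond = 0.21
                         ),
                         sd_intercept = 0.06,
                         sd_conf = 0.08,
                         sd_inf = 0.05,
                         residual_sd = 0.06,
                         kappa_subject = 1.02,
                         conf_noise_sd = 10,
                         conf_cutpoints = c(-95, -59, -36, -21.5, -7),
                         ramp = 0,
                         rt_meanlog = log(2.2),
                         rt_sdlog = 0.35,
                         setting = c("fmri", "behavioural")) {
  model <- match.arg(model)
  setting <- match.arg(setting)
  stopifnot(
    length(beta_human) == 4, length(beta_computer) == 4,
    length(beta_joint) == 8,
    length(conf_cutpoints) == 5, !is.unsorted(conf_cutpoints, strictly = TRUE),
    sd_intercept >= 0, sd_conf >= 0, sd_inf >= 0, residual_sd >= 0
  )
  structure(
    list(
      model = model,
      beta_human = beta_human, beta_computer = beta_computer,
      beta_joint = beta_joint,
      sd_intercept = sd_intercept, sd_conf = sd_conf, sd_inf = sd_inf,
      residual_sd = residual_sd,
      kappa_subject = kappa_subject,
      conf_noise_sd = conf_noise_sd, conf_cutpoints = conf_cutpoints,
      ramp = ramp,
      rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
      setting = setting
    ),
    class = "agent_params"
  )
}

#' Sample an initial perceptual estimate and its internal precision
#'
#' The estimate is a von Mises draw around the target; the internal
#' precision signal is the negative absolute angular error corrupted with
#' Gaussian noise, i.e. a noisy monotone function of how close the draw
#' landed to the target. Precision feeds the ordinal confidence report,
#' so confidence and accuracy covary as the task assumes.
#'
#' @param target Target angle(s), degrees.
#' @param params An [agent_params()] object.
#' @return A tibble with columns `estimate` (degrees) and `precision`.
#' @export
sample_initial_estimate <- function(target, params = agent_params()) {
  n <- length(target)
  err <- rvonmises(n, 0, params$kappa_subject)
  err <- ifelse(err > 180, err - 360, err)
  tibble::tibble(
    estimate = norm_angle(target + err),
    precision = -abs(err) + stats::rnorm(n, 0, params$conf_noise_sd)
  )
}

#' Bin an internal precision signal into a 1-6 confidence report
#'
#' @param precision Numeric precision signal (higher = more precise).
#' @param cutpoints Five increasing thresholds.
#' @return Integer confidence levels in 1..6.
#' @export
report_confidence <- function(precision,
                              cutpoints = agent_params()$conf_cutpoints) {
  stopifnot(length(cutpoints) == 5, !is.unsorted(cutpoints, strictly = TRUE))
  findInterval(precision, cutpoints) + 1L
}

# Linear predictor of the revision model, without noise or truncation.
revision_linpred <- function(conf_norm, prev_influence, condition, params,
                             b_int = 0, b_conf = 0, b_inf = 0) {
  if (params$model == "lmm2") {
    b <- ifelse(condition == "human", 1, 0)
    beta <- outer(b, params$beta_human) + outer(1 - b, params$beta_computer)
    (beta[, 1] + b_int) +
      (beta[, 2] + b_conf) * conf_norm +
      (beta[, 3] + b_inf) * prev_influence +
      beta[, 4] * conf_norm * prev_influence
  } else {
    cond <- ifelse(condition == "human", 1, 2)
    beta <- params$beta_joint
    (beta[1] + b_int) +
      (beta[2] + b_conf) * conf_norm +
      beta[3] * prev_influence +
      beta[4] * cond +
      beta[5] * conf_norm * prev_influence +
      beta[6] * conf_norm * cond +
      beta[7] * prev_influence * cond +
      beta[8] * conf_norm * prev_influence * cond
  }
}

#' Decide how far to revise towards the partner
#'
#' Evaluates the generative revision model: a linear predictor in
#' normalised confidence (`confidence / 6`), the influence exerted over
#' the partner on the immediately preceding observation trial, and their
#' interaction, plus participant-level random effects and a Gaussian
#' residual, truncated to `[0, 1]` (the task requires the revised
#' estimate to lie between the two initial estimates).
#'
#' @param conf_norm Normalised confidence in `(0, 1]`.
#' @param prev_influence Influence statistic from the preceding
#'   observation trial, in `[0, 1]`. Missing values are an error: the
#'   alternating trial structure guarantees a preceding observation.
#' @param condition `"human"` or `"computer"` (recycled).
#' @param params An [agent_params()] object.
#' @param ranef Optional list with numeric elements `intercept`, `conf`,
#'   `inf` (participant random effects; default all zero).
#' @param noise If `FALSE`, return the truncated linear predictor with no
#'   residual draw (useful for exact checks).
#' @return Revision fractions in `[0, 1]`.
#' @export
#' @examples
#' p <- agent_params(beta_computer = c(0.5, -0.37, 0, 0))
#' decide_revision(1, 0.5, "computer", p, noise = FALSE) # 0.13
decide_revision <- function(conf_norm, prev_influence, condition,
                            params = agent_params(), ranef = NULL,
                            noise = TRUE) {
  if (anyNA(prev_influence)) {
    stop("`prev_influence` is missing; every revision trial must follow ",
      "an observation trial.",
      call. = FALSE
    )
  }
  n <- max(length(conf_norm), length(prev_influence), length(condition))
  conf_norm <- rep_len(conf_norm, n)
  prev_influence <- rep_len(prev_influence, n)
  condition <- rep_len(condition, n)
  if (is.null(ranef)) ranef <- list(intercept = 0, conf = 0, inf = 0)
  lp <- revision_linpred(
    conf_norm, prev_influence, condition, params,
    b_int = rep_len(ranef$intercept, n),
    b_conf = rep_len(ranef$conf, n),
    b_inf = rep_len(ranef$inf, n)
  )
  if (noise) lp <- lp + stats::rnorm(n, 0, params$residual_sd)
  unname(pmin(pmax(lp, 0), 1))
}

# Vectorised trial builder shared by build_session() and generate_cohort().
# `ranef` is a tibble with one row per participant (participant_id,
# b_intercept, b_conf, b_inf).
build_trials <- function(participant_ids, params, design, ranef) {
  n_pp <- length(participant_ids)
  n_trial <- 30L
  grid <- tidyr::expand_grid(
    participant_id = participant_ids,
    block = design$block,
    trial_index = seq_len(n_trial)
  )
  grid <- dplyr::left_join(grid, design, by = "block")
  grid <- dplyr::left_join(grid, ranef, by = "participant_id")
  n <- nrow(grid)

  grid$role <- ifelse(grid$trial_index %% 2L == 1L, "observe", "revise")
  grid$target <- stats::runif(n, 0, 360)
  est <- sample_initial_estimate(grid$target, params)
  grid$self_initial <- est$estimate
  grid$confidence <- report_confidence(est$precision, params$conf_cutpoints)
  grid$partner_initial <- sample_partner_initial(
    grid$target, grid$self_initial, grid$confidence,
    setting = params$setting
  )
  grid$conf_norm <- grid$confidence / 6

  obs <- grid$role == "observe"
  grid$influence_drawn <- NA_real_
  grid$influence_drawn[obs] <- sample_influence(grid$susceptibility[obs])
  grid$reviser_final <- NA_real_
  grid$reviser_final[obs] <- partner_revision(
    grid$partner_initial[obs], grid$self_initial[obs],
    grid$influence_drawn[obs]
  )
  grid$influence_stat <- NA_real_
  grid$influence_stat[obs] <- shift_fraction(
    grid$partner_initial[obs], grid$reviser_final[obs],
    grid$self_initial[obs]
  )

  # influence carried forward from the immediately preceding observation
  # trial of the same block (roles alternate, so lag 1 within block)
  grid <- grid |>
    dplyr::group_by(.data$participant_id, .data$block) |>
    dplyr::mutate(prev_influence = dplyr::lag(.data$influence_drawn)) |>
    dplyr::ungroup()

  rev <- grid$role == "revise"
  lp <- revision_linpred(
    grid$conf_norm[rev], grid$prev_influence[rev],
    grid$cover_story[rev], params,
    b_int = grid$b_intercept[rev],
    b_conf = grid$b_conf[rev],
    b_inf = grid$b_inf[rev]
  )
  if (params$ramp != 0) {
    lp <- lp + params$ramp * (grid$trial_index[rev] / n_trial) *
      (grid$prev_influence[rev] - 0.35)
  }
  grid$revision_drawn <- NA_real_
  grid$revision_drawn[rev] <- pmin(pmax(
    lp + stats::rnorm(sum(rev), 0, params$residual_sd), 0
  ), 1)
  grid$reviser_final[rev] <- move_toward(
    grid$self_initial[rev], grid$partner_initial[rev],
    grid$revision_drawn[rev]
  )
  grid$revision_stat <- NA_real_
  grid$revision_stat[rev] <- shift_fraction(
    grid$self_initial[rev], grid$reviser_final[rev],
    grid$partner_initial[rev]
  )

  grid$rt_estimate <- stats::rlnorm(n, params$rt_meanlog, params$rt_sdlog)
  grid$rt_confidence <- stats::rlnorm(n, params$rt_meanlog - 0.25, params$rt_sdlog)
  grid$rt_revision <- stats::rlnorm(n, params$rt_meanlog, params$rt_sdlog)

  dplyr::select(
    grid, "participant_id", "block", "trial_index", "role",
    "label", "cover_story", "susceptibility",
    "target", "self_initial", "confidence", "conf_norm",
    "partner_initial", "reviser_final",
    "revision_drawn", "influence_drawn",
    "revision_stat", "influence_stat", "prev_influence",
    "rt_estimate", "rt_confidence", "rt_revision"
  )
}

#' Simulate one participant's session
#'
#' Four blocks of 30 trials, one partner per block covering the
#' 2 x 2 cover-story x susceptibility design; roles alternate strictly,
#' starting with an observation trial. Deterministic given `seed`.
#'
#' @param params An [agent_params()] object.
#' @param design A partner design, see [partner_design()].
#' @param seed Optional integer seed.
#' @param participant_id Identifier recorded in the table.
#' @param ranef Optional named list/vector of this participant's random
#'   effects (`intercept`, `conf`, `inf`); drawn from the configured SDs
#'   when omitted.
#' @return A tibble with 120 trial records.
#' @export
#' @examples
#' s <- build_session(seed = 1)
#' table(s$role)
build_session <- function(params = agent_params(), design = partner_design(),
                          seed = NULL, participant_id = "P01",
                          ranef = NULL) {
  design <- validate_partner_design(design)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ranef)) {
    ranef <- list(
      intercept = stats::rnorm(1, 0, params$sd_intercept),
      conf = stats::rnorm(1, 0, params$sd_conf),
      inf = if (params$model == "lmm2") stats::rnorm(1, 0, params$sd_inf) else 0
    )
  }
  rtab <- tibble::tibble(
    participant_id = participant_id,
    b_intercept = ranef$intercept, b_conf = ranef$conf, b_inf = ranef$inf
  )
  build_trials(participant_id, params, design, rtab)
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates `n_participants` full sessions and records the drawn
#' participant-level random effects alongside, so that parameter-recovery
#' analyses can compare fitted quantities against generative truth.
#'
#' @param n_participants Number of participants (60 in the study design).
#' @param params An [agent_params()] object.
#' @param design Partner design shared by all participants.
#' @param seed Optional integer seed; the full table is reproducible.
#' @return An object of class `conformity_cohort`: a list with `trials`
#'   (tibble of all trial records), `ranef` (tibble of true random
#'   effects per participant), `params` and `design`.
#' @export
#' @examples
#' coh <- generate_cohort(4, seed = 1)
#' nrow(coh$trials) # 4 x 120
generate_cohort <- function(n_participants = 60,
                            params = agent_params(),
                            design = partner_design(),
                            seed = NULL) {
  design <- validate_partner_design(design)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n_participants))
  ranef <- tibble::tibble(
    participant_id = ids,
    b_intercept = stats::rnorm(n_participants, 0, params$sd_intercept),
    b_conf = stats::rnorm(n_participants, 0, params$sd_conf),
    b_inf = if (params$model == "lmm2") {
      stats::rnorm(n_participants, 0, params$sd_inf)
    } else {
      rep(0, n_participants)
    }
  )
  trials <- build_trials(ids, params, design, ranef)
  structure(
    list(trials = trials, ranef = ranef, params = params, design = design),
    class = "conformity_cohort"
  )
}

#' @export
print.conformity_cohort <- function(x, ...) {
  cat(
    "<conformity_cohort> ", dplyr::n_distinct(x$trials$participant_id),
    " participants, ", nrow(x$trials), " trials (generative model: ",
    x$params$model, ")\n",
    sep = ""
  )
  invisible(x)
}
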