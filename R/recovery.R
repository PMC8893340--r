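#' Parameter-recovery experiment for the revision mixed models
#'
#' Generates replicate synthetic cohorts from the packaged generative
#' coefficient sets and refits the corresponding mixed model to each,
#' returning every fixed-effect estimate with its confidence interval.
#' This is the core validation of the behavioural analysis: with the
#' generative model matched to the fitted model, the averaged estimates
#' should recover the generating coefficients and the 95% intervals
#' should cover them at close to nominal rate.
#'
#' For `model = "lmm2"` each replicate cohort is generated with the
#' condition-specific coefficient sets and both single-condition models
#' are fitted (human and computer). For `model = "lmm1"` cohorts are
#' generated from the joint 8-coefficient model and the joint model is
#' fitted.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param n_participants Participants per cohort (60 in the emulated
#'   design).
#' @param model `"lmm2"` or `"lmm1"` (generative and fitted).
#' @param params Generative parameters; default [agent_params()] with
#'   the requested model.
#' @param seed Integer seed; replicate `r` uses `seed + r`.
#' @return A tibble with `replicate`, `condition`, `term`, `estimate`,
#'   `conf.low`, `conf.high`, `singular`.
#' @export
#' @examples
#' \donttest{
#' rec <- recovery_experiment(3, 20, "lmm2", seed = 1)
#' }
recovery_experiment <- function(n_cohorts = 100, n_participants = 60,
                                model = c("lmm2", "lmm1"),
                                params = NULL, seed = 1) {
  model <- match.arg(model)
  if (is.null(params)) params <- agent_params(model = model)
  stopifnot(params$model == model)
  out <- vector("list", n_cohorts)
  for (r in seq_len(n_cohorts)) {
    coh <- generate_cohort(n_participants, params = params, seed = seed + r)
    ann <- suppressMessages(annotate_trials(coh$trials))
    fits <- if (model == "lmm2") {
      list(
        human = suppressWarnings(fit_lmm2(ann, "human")),
        computer = suppressWarnings(fit_lmm2(ann, "computer"))
      )
    } else {
      list(both = suppressWarnings(fit_lmm1(ann)))
    }
    out[[r]] <- purrr::imap_dfr(fits, function(f, cond) {
      dplyr::mutate(
        tidy(f)[, c("term", "estimate", "conf.low", "conf.high")],
        condition = cond, singular = f$singular, replicate = r
      )
    })
  }
  dplyr::bind_rows(out)
}

#' Generating fixed effects in fitted-model parameterisation
#'
#' Maps an [agent_params()] coefficient set onto the term names produced
#' by [fit_lmm1()]/[fit_lmm2()], for comparison against recovery output.
#'
#' @param params An [agent_params()] object.
#' @param condition For `"lmm2"` params, `"human"` or `"computer"`.
#' @return A tibble with `term` and `truth`.
#' @export
generating_effects <- function(params = agent_params(),
                               condition = c("human", "computer")) {
  if (params$model == "lmm2") {
    condition <- match.arg(condition)
    beta <- if (condition == "human") params$beta_human else params$beta_computer
    tibble::tibble(
      term = c(
        "(Intercept)", "conf_norm", "prev_influence",
        "conf_norm:prev_influence"
      ),
      truth = unname(beta)
    )
  } else {
    tibble::tibble(
      term = c(
        "(Intercept)", "conf_norm", "prev_influence", "cond_dummy",
        "conf_norm:prev_influence", "conf_norm:cond_dummy",
        "prev_influence:cond_dummy", "conf_norm:prev_influence:cond_dummy"
      ),
      truth = unname(params$beta_joint)
    )
  }
}

#' Summarise a recovery experiment against generative truth
#'
#' @param recovery Output of [recovery_experiment()].
#' @param params The generative [agent_params()] used.
#' @return A tibble per condition and term: mean estimate, Monte-Carlo
#'   standard error of the mean, bias, and 95% CI coverage.
#' @export
summarise_recovery <- function(recovery, params = agent_params()) {
  truth <- if (params$model == "lmm2") {
    dplyr::bind_rows(
      dplyr::mutate(generating_effects(params, "human"), condition = "human"),
      dplyr::mutate(
        generating_effects(params, "computer"),
        condition = "computer"
      )
    )
  } else {
    dplyr::mutate(generating_effects(params), condition = "both")
  }
  recovery |>
    dplyr::left_join(truth, by = c("term", "condition")) |>
    dplyr::group_by(.data$condition, .data$term) |>
    dplyr::summarise(
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      mc_se = stats::sd(.data$estimate) / sqrt(dplyr::n()),
      bias = .data$mean_estimate - .data$truth,
      coverage = mean(
        .data$conf.low <= .data$truth & .data$truth <= .data$conf.high
      ),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
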