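#' Default end-to-end pipeline configuration
#'
#' A fully serialisable list describing one complete simulate-and-analyse
#' run: cohort size, generative agent parameters, partner design, event
#' timing, ROI encoding, noise, coupling, and analysis options. Every
#' random draw in [run_pipeline()] traces back to the single `seed`
#' argument, so a persisted configuration plus a seed reproduces every
#' output.
#'
#' @param n_participants Behavioural cohort size.
#' @param n_fmri Number of participants given synthetic ROI signals.
#' @param params Generative [agent_params()].
#' @param design Partner [partner_design()].
#' @param timing [timing_params()].
#' @param encoding [encoding_spec()] for the dACC-like region.
#' @param noise [noise_params()].
#' @param coupling [coupling_spec()] for the seed-target pair.
#' @param lock_event Event the ROI analysis is locked to.
#' @param ppi_window Averaging window (s) for the connectivity surface.
#' @return A list of class `pipeline_config`.
#' @export
default_config <- function(n_participants = 12, n_fmri = 8,
                           params = agent_params(),
                           design = partner_design(),
                           timing = timing_params(),
                           encoding = encoding_spec(),
                           noise = noise_params(),
                           coupling = coupling_spec(),
                           lock_event = "t5",
                           ppi_window = c(2, 3)) {
  structure(
    list(
      n_participants = n_participants, n_fmri = n_fmri,
      params = params, design = design, timing = timing,
      encoding = encoding, noise = noise, coupling = coupling,
      lock_event = lock_event, ppi_window = ppi_window
    ),
    class = "pipeline_config"
  )
}

validate_config <- function(config) {
  required <- c(
    "n_participants", "n_fmri", "params", "design", "timing",
    "encoding", "noise", "coupling", "lock_event", "ppi_window"
  )
  missing_fields <- setdiff(required, names(config))
  if (length(missing_fields) > 0) {
    stop("Pipeline config is missing field(s): ",
      paste(missing_fields, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(config$encoding) || nrow(config$encoding) == 0) {
    stop("Pipeline config field `encoding` must be a non-empty ",
      "encoding specification.",
      call. = FALSE
    )
  }
  invisible(config)
}

# Beta time courses for one participant's dACC-like region.
participant_roi_analysis <- function(trials, schedule, signal, lock_event,
                                     condition) {
  re <- roi_epochs(signal, schedule, trials,
    event = lock_event,
    role = "revise", condition = condition
  )
  mods <- data.frame(
    conf = re$trials$conf_norm,
    inf = re$trials$prev_influence,
    conf_inf = re$trials$conf_norm * re$trials$prev_influence,
    log_rt = log(re$trials$rt_revision),
    block = re$trials$block
  )
  beta_timecourse(re$epochs, mods)
}

#' Run the full simulate-and-analyse pipeline
#'
#' Executes every stage on synthetic data: cohort simulation, annotation,
#' both mixed-model analyses, sliding-window reciprocity dynamics with a
#' signed-rank contrast of late-window revision towards susceptible vs
#' insusceptible human partners, synthetic ROI signal generation for a
#' subset of participants, per-timepoint GLMs with leave-one-out peak
#' inference for confidence (both conditions) and the
#' confidence-by-influence interaction (per condition), and a PPI
#' analysis of a coupled seed-target pair with its connectivity surface.
#'
#' @param config A [default_config()] list.
#' @param seed Integer seed governing all randomness.
#' @return A list of class `conformity_report` with elements `cohort`,
#'   `fits` (lmm1 + per-condition lmm2), `windows`, `late_window_test`,
#'   `loo` (per condition and predictor), `ppi` (windowed coefficients,
#'   grid, and LOO test of the triple interaction), and `config`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1) {
  validate_config(config)
  cohort <- generate_cohort(
    config$n_participants,
    params = config$params,
    design = config$design, seed = seed
  )
  ann <- suppressMessages(annotate_trials(cohort$trials))

  fits <- list(
    lmm1 = suppressWarnings(fit_lmm1(ann)),
    lmm2_human = suppressWarnings(fit_lmm2(ann, "human")),
    lmm2_computer = suppressWarnings(fit_lmm2(ann, "computer"))
  )

  windows <- sliding_window_revision(ann)
  late <- windows |>
    dplyr::filter(.data$cover_story == "human") |>
    dplyr::group_by(.data$participant_id, .data$susceptibility) |>
    dplyr::filter(.data$window == max(.data$window)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(
      id_cols = "participant_id",
      names_from = "susceptibility", values_from = "mean_revision"
    )
  late_test <- signed_rank(late$susceptible, late$insusceptible)

  ids <- unique(ann$participant_id)[seq_len(min(
    config$n_fmri,
    config$n_participants
  ))]
  betas <- list(human = list(), computer = list())
  ppi_list <- list()
  for (k in seq_along(ids)) {
    tr <- dplyr::filter(ann, .data$participant_id == ids[k])
    sch <- build_event_schedule(tr, config$timing, seed = seed + 1000 + k)
    sig <- synthesize_roi_signal(sch, tr,
      encoding = config$encoding,
      noise = config$noise, seed = seed + 2000 + k
    )
    for (cond in c("human", "computer")) {
      betas[[cond]][[k]] <- participant_roi_analysis(
        tr, sch, sig, config$lock_event, cond
      )
    }
    pair <- synthesize_coupled_pair(sch, tr,
      coupling = config$coupling,
      encoding = config$encoding, noise = config$noise,
      event = config$lock_event, seed = seed + 3000 + k
    )
    te <- roi_epochs(pair$target, sch, tr, config$lock_event,
      role = "revise", condition = "human"
    )
    se <- roi_epochs(pair$seed, sch, tr, config$lock_event,
      role = "revise", condition = "human"
    )
    ppi_list[[k]] <- ppi_timecourse(
      te$epochs, se$epochs,
      te$trials$conf_norm, te$trials$prev_influence
    )
  }
  loo <- list(
    conf_human = loo_peak_test(betas$human, "conf"),
    conf_computer = loo_peak_test(betas$computer, "conf"),
    conf_inf_human = loo_peak_test(betas$human, "conf_inf"),
    conf_inf_computer = loo_peak_test(betas$computer, "conf_inf")
  )
  wcoef <- ppi_window_coefficients(ppi_list, config$ppi_window)
  ppi <- list(
    window_coefficients = wcoef,
    grid = connectivity_grid(wcoef),
    loo_triple = loo_peak_test(ppi_list, "seed:conf:inf")
  )

  structure(
    list(
      cohort = cohort, fits = fits, windows = windows,
      late_window_test = late_test, loo = loo, ppi = ppi,
      config = config, seed = seed
    ),
    class = "conformity_report"
  )
}

#' @export
print.conformity_report <- function(x, ...) {
  cat("<conformity_report> seed", x$seed, "\n")
  cat("Cohort:", x$config$n_participants, "participants;",
    x$config$n_fmri, "with synthetic ROI signals\n\n")
  cat("Mixed-model fixed effects (lmm2, human):\n")
  print(tidy(x$fits$lmm2_human)[, c("term", "estimate", "p.value")])
  cat("\nLate-window susceptible vs insusceptible (human): W =",
    x$late_window_test$statistic, ", p =",
    signif(x$late_window_test$p.value, 3), "\n")
  cat("\nLeave-one-out peak tests:\n")
  for (nm in names(x$loo)) {
    cat(
      "  ", nm, ": p =", signif(x$loo[[nm]]$test$p.value, 3), "\n"
    )
  }
  cat("\nPPI windowed coefficients:\n")
  print(round(x$ppi$window_coefficients, 3))
  invisible(x)
}
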