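# Shared fixtures and small utilities for the test suite. Everything is
# generated in code; no stored data.

quiet_annotate <- function(trials) suppressMessages(annotate_trials(trials))

small_cohort <- function(n = 10, seed = 101, ...) {
  generate_cohort(n, params = agent_params(...), seed = seed)
}

# Per-trial modulator frame for the dACC-style per-timepoint GLM.
eq3_modulators <- function(trials) {
  data.frame(
    conf = trials$conf_norm,
    inf = trials$prev_influence,
    conf_inf = trials$conf_norm * trials$prev_influence,
    log_rt = log(trials$rt_revision),
    block = trials$block
  )
}

# One participant's beta time courses for both conditions.
participant_betas <- function(seed) {
  tr <- quiet_annotate(build_session(seed = seed))
  sch <- build_event_schedule(tr, seed = seed + 1)
  sig <- synthesize_roi_signal(sch, tr, seed = seed + 2)
  lapply(c(human = "human", computer = "computer"), function(cond) {
    re <- roi_epochs(sig, sch, tr, "t5", "revise", cond)
    beta_timecourse(re$epochs, eq3_modulators(re$trials))
  })
}

# Group ROI replicate: n participants, LOO p-values for confidence and
# the confidence-by-influence interaction in each condition.
roi_group_pvalues <- function(n = 20, seed = 1) {
  betas <- lapply(seq_len(n), function(k) participant_betas(seed + 10 * k))
  human <- lapply(betas, `[[`, "human")
  computer <- lapply(betas, `[[`, "computer")
  c(
    conf_human = loo_peak_test(human, "conf")$test$p.value,
    conf_computer = loo_peak_test(computer, "conf")$test$p.value,
    conf_inf_human = loo_peak_test(human, "conf_inf")$test$p.value,
    conf_inf_computer = loo_peak_test(computer, "conf_inf")$test$p.value
  )
}

# Exhaustive signed-rank null: two-sided p for W over all sign flips.
enumerate_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}
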