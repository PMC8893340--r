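#' Annotate a trial table with conformity statistics
#'
#' Recomputes, from the recorded angles alone, the two conformity
#' statistics: `revision_stat` on revision trials (how far the
#' participant moved towards the partner) and `influence_stat` on
#' observation trials (how far the partner moved towards the
#' participant), both as fractions of the initial disagreement via
#' [shift_fraction()]. Adds normalised confidence (`confidence / 6`), the
#' influence carried forward from the immediately preceding observation
#' trial (`prev_influence`), and the condition dummy (`cond_dummy`,
#' 1 = human, 2 = computer). Trials with zero initial disagreement have
#' undefined statistics and are dropped with a message.
#'
#' @param trials A trial table as produced by [build_session()] or
#'   [generate_cohort()] (columns `participant_id`, `block`,
#'   `trial_index`, `role`, `cover_story`, `self_initial`,
#'   `partner_initial`, `reviser_final`, `confidence`; `susceptibility`
#'   is carried through when present).
#' @return A tibble of annotated trials.
#' @export
annotate_trials <- function(trials) {
  required <- c(
    "participant_id", "block", "trial_index", "role", "cover_story",
    "self_initial", "partner_initial", "reviser_final", "confidence"
  )
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop("Trial table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  obs <- trials$role == "observe"
  rev <- trials$role == "revise"
  out <- trials
  out$influence_stat <- NA_real_
  out$influence_stat[obs] <- shift_fraction(
    out$partner_initial[obs], out$reviser_final[obs], out$self_initial[obs]
  )
  out$revision_stat <- NA_real_
  out$revision_stat[rev] <- shift_fraction(
    out$self_initial[rev], out$reviser_final[rev], out$partner_initial[rev]
  )
  out$conf_norm <- out$confidence / 6
  out$cond_dummy <- ifelse(out$cover_story == "human", 1, 2)
  out <- out |>
    dplyr::group_by(.data$participant_id, .data$block) |>
    dplyr::mutate(prev_influence = dplyr::lag(.data$influence_stat)) |>
    dplyr::ungroup()
  undefined <- (obs & is.na(out$influence_stat)) |
    (rev & (is.na(out$revision_stat) | is.na(out$prev_influence)))
  if (any(undefined)) {
    message(
      "Dropping ", sum(undefined),
      " trial(s) with undefined conformity statistics ",
      "(zero initial disagreement or missing lag)."
    )
    out <- out[!undefined, ]
  }
  out
}

# Revision-trial subset with complete predictors, ready for model fitting.
revision_data <- function(annotated) {
  out <- dplyr::filter(
    annotated, .data$role == "revise",
    !is.na(.data$revision_stat), !is.na(.data$prev_influence)
  )
  if (nrow(out) == 0) stop("No usable revision trials.", call. = FALSE)
  out
}

lmm_from_fit <- function(fit, model, condition, fallback_used) {
  sm <- summary(fit)$coefficients # estimate, se, df (Satterthwaite), t, p
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  df <- sm[, "df"]
  tval <- sm[, "t value"]
  p <- sm[, "Pr(>|t|)"]
  tcrit <- stats::qt(0.975, df)
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - tcrit * se),
    conf.high = unname(est + tcrit * se),
    statistic = unname(tval^2), # F on (1, df): square of Satterthwaite t
    num.df = 1,
    den.df = unname(df),
    p.value = unname(p),
    p.holm = holm_adjust(unname(p))
  )
  structure(
    list(
      fit = fit,
      coefficients = coefs,
      model = model,
      condition = condition,
      singular = lme4::isSingular(fit),
      fallback_used = fallback_used,
      n_obs = stats::nobs(fit),
      n_participants = length(unique(lme4::getME(fit, "flist")[[1]])),
      logLik = as.numeric(stats::logLik(fit)),
      BIC = stats::BIC(fit)
    ),
    class = "conformity_lmm"
  )
}

fit_lmm_formula <- function(data, formulas, model, condition) {
  fallback_used <- FALSE
  fit <- NULL
  for (i in seq_along(formulas)) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(formulas[[i]], data = data, REML = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      if (i > 1) fallback_used <- TRUE
      break
    }
  }
  if (is.null(fit)) stop("Mixed-model fit failed.", call. = FALSE)
  if (lme4::isSingular(fit)) {
    warning("Singular random-effect fit; variance estimates are on the ",
      "boundary. Fixed effects reported as-is.",
      call. = FALSE
    )
  }
  lmm_from_fit(fit, model, condition, fallback_used)
}

#' Fit the joint two-condition mixed model of revision
#'
#' Revision on revision trial *t* is modelled as a full factorial in
#' normalised confidence, previous-trial influence and the condition
#' dummy (1 = human, 2 = computer): eight fixed effects in total. The
#' intercept and the confidence slope vary across participants as
#' independent Gaussian random effects; estimation is REML and each fixed
#' effect is tested with an F statistic on Satterthwaite denominator
#' degrees of freedom (the square of the Satterthwaite t). Holm-adjusted
#' p-values are reported alongside raw ones, with the family defined as
#' the fixed effects of the one fitted model.
#'
#' If the full random structure fails to converge the model falls back to
#' a random intercept only, flagged via `fallback_used`.
#'
#' @param annotated An annotated trial table from [annotate_trials()],
#'   containing both conditions.
#' @return A `conformity_lmm` object; see [tidy.conformity_lmm()].
#' @export
fit_lmm1 <- function(annotated) {
  data <- revision_data(annotated)
  if (dplyr::n_distinct(data$cond_dummy) < 2) {
    stop("Both conditions must be present; use `fit_lmm2()` for a single ",
      "condition.",
      call. = FALSE
    )
  }
  fit_lmm_formula(
    data,
    list(
      revision_stat ~ conf_norm * prev_influence * cond_dummy +
        (1 + conf_norm || participant_id),
      revision_stat ~ conf_norm * prev_influence * cond_dummy +
        (1 | participant_id)
    ),
    model = "lmm1", condition = "both"
  )
}

#' Fit the single-condition mixed model of revision
#'
#' Revision is modelled from normalised confidence, previous-trial
#' influence and their interaction, within one partner condition. The
#' intercept and both slopes vary across participants as independent
#' Gaussian random effects; the interaction coefficient is a fixed effect
#' only (the fully varying model is overparameterised). REML estimation
#' with Satterthwaite F tests, as in [fit_lmm1()].
#'
#' @param annotated An annotated trial table from [annotate_trials()].
#' @param condition `"human"` or `"computer"`; the table is subset
#'   accordingly (pass a pre-subset table with a single condition to skip
#'   subsetting).
#' @return A `conformity_lmm` object.
#' @export
fit_lmm2 <- function(annotated, condition = c("human", "computer")) {
  condition <- match.arg(condition)
  data <- revision_data(annotated)
  data <- dplyr::filter(data, .data$cover_story == condition)
  if (nrow(data) == 0) {
    stop("No revision trials in condition '", condition, "'.", call. = FALSE)
  }
  fit_lmm_formula(
    data,
    list(
      revision_stat ~ conf_norm * prev_influence +
        (1 + conf_norm + prev_influence || participant_id),
      revision_stat ~ conf_norm * prev_influence +
        (1 + conf_norm || participant_id),
      revision_stat ~ conf_norm * prev_influence + (1 | participant_id)
    ),
    model = "lmm2", condition = condition
  )
}

#' @export
print.conformity_lmm <- function(x, ...) {
  cat("<conformity_lmm> ", x$model, " (", x$condition, "), ",
    x$n_obs, " trials / ", x$n_participants, " participants",
    if (x$singular) " [singular]", "\n",
    sep = ""
  )
  print(x$coefficients)
  invisible(x)
}

#' Tidy a fitted conformity mixed model
#'
#' @param x A `conformity_lmm` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `estimate`,
#'   `std.error`, 95% confidence bounds, F `statistic` with `num.df` and
#'   Satterthwaite `den.df`, raw and Holm-adjusted p-values.
#' @method tidy conformity_lmm
#' @export
tidy.conformity_lmm <- function(x, ...) x$coefficients

#' Model-level summary of a fitted conformity mixed model
#'
#' @param x A `conformity_lmm` object.
#' @param ... Unused.
#' @return A one-row tibble with fit criteria and flags.
#' @method glance conformity_lmm
#' @export
glance.conformity_lmm <- function(x, ...) {
  tibble::tibble(
    model = x$model, condition = x$condition,
    nobs = x$n_obs, n_participants = x$n_participants,
    logLik = x$logLik, BIC = x$BIC,
    singular = x$singular, fallback_used = x$fallback_used
  )
}

#' Sliding-window mean revision
#'
#' Averages revision in windows of `window` consecutive revision trials
#' moved in steps of `step` trial, separately for every participant and
#' partner (block), exposing within-block reciprocity dynamics. With 15
#' revision trials per block and the default 5-trial window there are 11
#' windows.
#'
#' @param annotated Annotated trial table.
#' @param window Window length in revision trials (default 5).
#' @param step Step between consecutive windows (default 1).
#' @return A tibble with `participant_id`, `cover_story`,
#'   `susceptibility`, `block`, `window` (index of the first trial in the
#'   window) and `mean_revision`. Groups with fewer than `window` trials
#'   yield no rows, with a warning.
#' @export
sliding_window_revision <- function(annotated, window = 5, step = 1) {
  data <- revision_data(annotated)
  group_cols <- intersect(
    c("participant_id", "cover_story", "susceptibility", "block"),
    names(data)
  )
  win_len <- as.integer(window)
  win_step <- as.integer(step)
  out <- data |>
    dplyr::arrange(.data$participant_id, .data$block, .data$trial_index) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::reframe(window_means(.data$revision_stat, win_len, win_step))
  if (nrow(out) == 0) {
    warning("Fewer than `window` revision trials in every group; ",
      "empty series returned.",
      call. = FALSE
    )
  }
  out
}

window_means <- function(x, window, step) {
  n <- length(x)
  if (n < window) {
    return(tibble::tibble(window = integer(0), mean_revision = numeric(0)))
  }
  starts <- seq(1L, n - window + 1L, by = step)
  means <- vapply(
    starts,
    function(s) mean(x[s:(s + window - 1L)]), numeric(1)
  )
  tibble::tibble(window = seq_along(starts), mean_revision = means)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired samples (`x` vs `y`) or of a
#' single sample against a scalar null value. The exact distribution is
#' used for n <= 25 without ties or zero differences; otherwise the
#' normal approximation with continuity correction. All-zero differences
#' leave the test degenerate: `p = 1` is returned with `degenerate =
#' TRUE`.
#'
#' @param x Numeric vector.
#' @param y Optional paired numeric vector.
#' @param mu Null value when `y` is absent (e.g. 0.5 for a revision
#'   fraction against indifference).
#' @return A one-row tibble: `statistic` (W, sum of positive ranks),
#'   `p.value`, `n` (non-zero differences), `method`, `degenerate`.
#' @export
#' @examples
#' signed_rank(c(0.2, 0.4, 0.3, 0.5), mu = 0.5)
signed_rank <- function(x, y = NULL, mu = 0) {
  d <- if (is.null(y)) x - mu else x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(tibble::tibble(
      statistic = 0, p.value = 1, n = 0L,
      method = "degenerate", degenerate = TRUE
    ))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- length(nz) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p.value = wt$p.value,
    n = length(nz),
    method = if (exact) "exact" else "normal approximation",
    degenerate = FALSE
  )
}

#' Holm step-down multiple-comparison adjustment
#'
#' Monotone step-down adjustment, capped at 1; controls the family-wise
#' error rate for the supplied family of p-values.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04)) # 0.02, 0.04
holm_adjust <- function(p) {
  if (any(!is.finite(p))) stop("p-values must be finite.", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}
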