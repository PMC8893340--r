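#' Regress nuisance signals out of an ROI time series
#'
#' Ordinary least-squares residualisation of the signal on the nuisance
#' regressors plus an intercept, run by run (head-motion removal).
#' Collinear nuisance columns are handled by the pivoted QR: they receive
#' no weight and a warning is emitted.
#'
#' @param signal A `roi_signal` object, or a numeric vector.
#' @param nuisance For the vector method, a numeric matrix with one row
#'   per sample; for `roi_signal` the object's own motion regressors are
#'   used when omitted.
#' @return Same shape as the input, with nuisance variation removed
#'   (including the mean).
#' @export
residualize <- function(signal, nuisance = NULL) {
  UseMethod("residualize")
}

#' @export
residualize.default <- function(signal, nuisance = NULL) {
  if (is.null(nuisance)) {
    nuisance <- matrix(numeric(0), length(signal), 0)
  }
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != length(signal)) {
    stop("Nuisance matrix must have one row per sample.", call. = FALSE)
  }
  x <- cbind(1, nuisance)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    warning("Nuisance matrix is rank deficient; collinear columns carry ",
      "no weight.",
      call. = FALSE
    )
  }
  as.numeric(qr.resid(qrx, signal))
}

#' @export
residualize.roi_signal <- function(signal, nuisance = NULL) {
  out <- signal
  for (b in unique(signal$samples$block)) {
    sel <- signal$samples$block == b
    nuis <- if (is.null(nuisance)) {
      as.matrix(signal$nuisance[signal$nuisance$block == b, -(1:2)])
    } else {
      as.matrix(nuisance[sel, , drop = FALSE])
    }
    out$samples$value[sel] <- residualize.default(
      signal$samples$value[sel], nuis
    )
  }
  out
}

#' Upsample a time series to a fine grid by cubic spline
#'
#' Natural cubic-spline interpolation onto a regular grid (default
#' 0.2 s) spanning the sampled run; no extrapolation beyond the run.
#'
#' @param time,value Numeric vectors: sample times (s) and values.
#' @param dt Target sample spacing in seconds (default 0.2).
#' @return A tibble (`time`, `value`) on the fine grid.
#' @export
upsample_series <- function(time, value, dt = 0.2) {
  if (length(time) < 4) stop("Need at least 4 samples.", call. = FALSE)
  grid <- seq(min(time), max(time), by = dt)
  sp <- stats::spline(time, value, xout = grid, method = "natural")
  tibble::tibble(time = sp$x, value = sp$y)
}

#' Upsample every run of an ROI signal
#'
#' @param signal A `roi_signal`.
#' @param dt Target sample spacing in seconds.
#' @return The `roi_signal` with `samples` on the fine grid.
#' @export
upsample <- function(signal, dt = 0.2) {
  stopifnot(inherits(signal, "roi_signal"))
  out <- signal
  runs <- lapply(unique(signal$samples$block), function(b) {
    sel <- signal$samples$block == b
    up <- upsample_series(
      signal$samples$time[sel], signal$samples$value[sel],
      dt = dt
    )
    dplyr::bind_cols(tibble::tibble(block = b), up)
  })
  out$samples <- dplyr::bind_rows(runs)
  attr(out, "dt") <- dt
  out
}

#' Extract event-locked epochs from an upsampled series
#'
#' Cuts one row per onset: `n_points` samples at `dt` spacing starting
#' `pre` seconds before the event (defaults give the 15-second,
#' 75-point window anchored 1 s before onset). The epoch grid is aligned
#' to the nearest sample of the upsampled series, so alignment error is
#' at most `dt / 2`. Onsets whose window leaves the run are dropped with
#' a warning.
#'
#' @param time,value Upsampled series (regular spacing `dt`).
#' @param onsets Event onset times in seconds.
#' @param pre Seconds before onset at which the window starts.
#' @param n_points Number of samples per epoch.
#' @param dt Sample spacing of the series (s).
#' @return A matrix (`length(onsets)` kept rows x `n_points`) of class
#'   `epoch_matrix`, with attributes `time_rel` (seconds relative to
#'   onset) and `kept` (logical, which onsets survived).
#' @export
extract_epochs <- function(time, value, onsets, pre = 1, n_points = 75,
                           dt = 0.2) {
  starts <- round((onsets - pre - time[1]) / dt) + 1L
  ends <- starts + n_points - 1L
  kept <- starts >= 1L & ends <= length(time)
  if (any(!kept)) {
    warning(sum(!kept), " epoch(s) outside the run were dropped.",
      call. = FALSE
    )
  }
  mat <- t(vapply(
    starts[kept],
    function(s) value[s:(s + n_points - 1L)],
    numeric(n_points)
  ))
  structure(mat,
    time_rel = seq(-pre, by = dt, length.out = n_points),
    kept = kept, class = c("epoch_matrix", "matrix", "array")
  )
}

#' Residualise, upsample and epoch an ROI signal in one step
#'
#' Convenience composition used throughout the pipeline: motion
#' residualisation, 0.2 s spline upsampling, and extraction of
#' event-locked epochs for one event type, pooled across the selected
#' runs. Returns the epochs together with the matching trial rows so
#' per-trial modulators stay aligned with epoch rows.
#'
#' @param signal A `roi_signal`.
#' @param schedule The participant's event schedule.
#' @param trials The participant's annotated trial table.
#' @param event Which event to lock to (default `"t5"`).
#' @param role Restrict to `"revise"` or `"observe"` trials
#'   (`"any"` keeps both).
#' @param condition Restrict to `"human"` or `"computer"` partner blocks
#'   (`"any"` keeps both).
#' @param dt,pre,n_points Epoch geometry, see [extract_epochs()].
#' @return A list with `epochs` (an `epoch_matrix`) and `trials` (the
#'   matching rows).
#' @export
roi_epochs <- function(signal, schedule, trials, event = "t5",
                       role = "revise", condition = "any",
                       dt = 0.2, pre = 1, n_points = 75) {
  keep <- trials
  if (role != "any") keep <- dplyr::filter(keep, .data$role == !!role)
  if (condition != "any") {
    keep <- dplyr::filter(keep, .data$cover_story == condition)
  }
  ev <- dplyr::semi_join(
    dplyr::filter(schedule, .data$event == !!event),
    keep,
    by = c("block", "trial_index")
  )
  clean <- upsample(residualize(signal), dt = dt)
  mats <- list()
  rows <- list()
  for (b in unique(ev$block)) {
    sel <- clean$samples$block == b
    em <- extract_epochs(
      clean$samples$time[sel], clean$samples$value[sel],
      ev$onset[ev$block == b],
      pre = pre, n_points = n_points, dt = dt
    )
    mats[[length(mats) + 1]] <- unclass(em)[, , drop = FALSE]
    tr <- dplyr::semi_join(
      keep[keep$block == b, ],
      ev[ev$block == b, ][attr(em, "kept"), ],
      by = c("block", "trial_index")
    )
    rows[[length(rows) + 1]] <- tr
  }
  epochs <- do.call(rbind, mats)
  structure(
    list(
      epochs = structure(epochs,
        time_rel = seq(-pre, by = dt, length.out = n_points),
        class = c("epoch_matrix", "matrix", "array")
      ),
      trials = dplyr::bind_rows(rows)
    ),
    class = "roi_epochs"
  )
}

#' Per-timepoint regression of epochs on trial modulators
#'
#' Fits, at each of the 75 epoch time points, an ordinary least-squares
#' regression of the epoch samples across trials on the supplied
#' modulators, and concatenates the coefficients into one beta time
#' course per predictor. Modulators are z-scored across trials before
#' fitting (never orthogonalised, so correlated modulators compete for
#' variance); a constant modulator has no variance, is flagged, and its
#' coefficients are returned as `NA`.
#'
#' @param epochs An `epoch_matrix` (trials x time points).
#' @param modulators A data frame of per-trial modulators, rows aligned
#'   with the epoch rows (e.g. confidence, previous influence, their
#'   product, log reaction time, block number).
#' @param standardize z-score the modulators (default `TRUE`).
#' @return A `beta_timecourse`: matrix (predictors x time points) with
#'   rows `(Intercept)` plus one per modulator, attribute `time_rel`.
#' @export
beta_timecourse <- function(epochs, modulators, standardize = TRUE) {
  modulators <- as.data.frame(modulators)
  if (nrow(modulators) != nrow(epochs)) {
    stop("One modulator row per epoch row is required.", call. = FALSE)
  }
  x <- as.matrix(modulators)
  if (standardize) {
    x <- scale(x)
    bad <- apply(!is.finite(x), 2, any)
    if (any(bad)) {
      warning(
        "Constant modulator(s): ",
        paste(colnames(x)[bad], collapse = ", "),
        "; coefficients undefined.",
        call. = FALSE
      )
      x[, bad] <- 0
    }
  } else {
    bad <- rep(FALSE, ncol(x))
  }
  design <- cbind(`(Intercept)` = 1, x)
  fit <- stats::lm.fit(design, unclass(epochs))
  coefs <- fit$coefficients
  if (any(bad)) coefs[which(bad) + 1L, ] <- NA_real_
  structure(coefs,
    time_rel = attr(epochs, "time_rel"),
    class = c("beta_timecourse", "matrix", "array")
  )
}

# Stack one predictor's beta time courses across participants.
stack_betas <- function(beta_list, predictor) {
  mat <- t(vapply(
    beta_list,
    function(b) {
      if (!predictor %in% rownames(b)) {
        stop("Predictor '", predictor, "' not in beta time course.",
          call. = FALSE
        )
      }
      b[predictor, ]
    },
    numeric(ncol(beta_list[[1]]))
  ))
  attr(mat, "time_rel") <- attr(beta_list[[1]], "time_rel")
  mat
}

#' Leave-one-out peak test of a group of beta time courses
#'
#' For each participant, the group-mean beta time course is computed with
#' that participant excluded, the peak is located as the time of maximal
#' absolute mean (positive or negative; earliest time on ties), and the
#' left-out participant's beta at that time is collected. The collected
#' values are tested against zero with a two-sided Wilcoxon signed-rank
#' test. Selecting the peak without the tested participant avoids
#' selection bias.
#'
#' @param betas Either a numeric matrix (participants x time points,
#'   optionally with a `time_rel` attribute) or a list of
#'   `beta_timecourse` objects together with `predictor`.
#' @param predictor Predictor name when `betas` is a list.
#' @return A `loo_peak_result`: list with `values` (tibble `participant`,
#'   `peak_time`, `beta`), `test` (signed-rank row), `predictor`.
#' @export
loo_peak_test <- function(betas, predictor = NULL) {
  if (is.list(betas) && !is.matrix(betas)) {
    stopifnot(!is.null(predictor))
    betas <- stack_betas(betas, predictor)
  }
  n <- nrow(betas)
  if (n < 3) stop("Need at least 3 participants.", call. = FALSE)
  time_rel <- attr(betas, "time_rel")
  if (is.null(time_rel)) time_rel <- seq_len(ncol(betas))
  peak_idx <- integer(n)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    gm <- colMeans(betas[-i, , drop = FALSE])
    peak_idx[i] <- which.max(abs(gm)) # first index on ties: earliest time
    vals[i] <- betas[i, peak_idx[i]]
  }
  structure(
    list(
      values = tibble::tibble(
        participant = seq_len(n),
        peak_time = time_rel[peak_idx],
        beta = vals
      ),
      test = signed_rank(vals),
      predictor = predictor %||% "beta"
    ),
    class = "loo_peak_result"
  )
}

#' @export
print.loo_peak_result <- function(x, ...) {
  cat("<loo_peak_result> ", x$predictor, ": n = ", nrow(x$values),
    ", W = ", x$test$statistic, ", p = ", signif(x$test$p.value, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a leave-one-out peak result
#'
#' @param x A `loo_peak_result`.
#' @param ... Unused.
#' @return The per-participant tibble of left-out peak betas.
#' @method tidy loo_peak_result
#' @export
tidy.loo_peak_result <- function(x, ...) x$values

#' @method glance loo_peak_result
#' @export
glance.loo_peak_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(predictor = x$predictor), x$test)
}

#' Psychophysiological interaction time course for one participant
#'
#' At every epoch time point, the target-region samples are regressed
#' across trials on the seed-region samples at the same time point, the
#' behavioural modulators (confidence, influence and their product) and
#' all seed-by-modulator interaction terms, with every main effect
#' controlled. The seed-by-modulator coefficient time courses quantify
#' how inter-region coupling varies with the task variables.
#'
#' @param target_epochs,seed_epochs `epoch_matrix` objects from the same
#'   trials and event lock.
#' @param conf,inf Per-trial confidence and previous-influence values
#'   (z-scored internally).
#' @param include_triple Include the seed x confidence x influence term
#'   (default `TRUE`).
#' @return A `beta_timecourse` with rows `(Intercept)`, `seed`, `conf`,
#'   `inf`, `conf:inf`, `seed:conf`, `seed:inf` and (optionally)
#'   `seed:conf:inf`.
#' @export
ppi_timecourse <- function(target_epochs, seed_epochs, conf, inf,
                           include_triple = TRUE) {
  stopifnot(
    nrow(target_epochs) == nrow(seed_epochs),
    length(conf) == nrow(target_epochs),
    length(inf) == nrow(target_epochs)
  )
  zc <- as.numeric(scale(conf))
  zi <- as.numeric(scale(inf))
  if (anyNA(zc) || anyNA(zi)) {
    stop("Constant confidence or influence; PPI design is collinear.",
      call. = FALSE
    )
  }
  nt <- ncol(target_epochs)
  terms <- c(
    "(Intercept)", "seed", "conf", "inf", "conf:inf",
    "seed:conf", "seed:inf", if (include_triple) "seed:conf:inf"
  )
  out <- matrix(NA_real_, length(terms), nt,
    dimnames = list(terms, NULL)
  )
  for (j in seq_len(nt)) {
    s <- seed_epochs[, j]
    x <- cbind(
      1, s, zc, zi, zc * zi, s * zc, s * zi,
      if (include_triple) s * zc * zi
    )
    out[, j] <- stats::lm.fit(x, target_epochs[, j])$coefficients
  }
  structure(out,
    time_rel = attr(target_epochs, "time_rel"),
    class = c("beta_timecourse", "matrix", "array")
  )
}

#' Average PPI coefficients over a post-onset window
#'
#' Group-level summary of per-participant PPI time courses: each
#' coefficient is averaged over the epoch times falling inside the
#' window (default 2-3 s after onset, 6 samples at 0.2 s), then averaged
#' across participants.
#'
#' @param ppi_list List of `beta_timecourse` objects from
#'   [ppi_timecourse()], one per participant.
#' @param window Length-2 window in seconds relative to onset.
#' @return A named numeric vector of group-mean windowed coefficients.
#' @export
ppi_window_coefficients <- function(ppi_list, window = c(2, 3)) {
  time_rel <- attr(ppi_list[[1]], "time_rel")
  cols <- which(time_rel >= window[1] & time_rel <= window[2])
  per_pp <- vapply(
    ppi_list,
    function(b) rowMeans(b[, cols, drop = FALSE]),
    numeric(nrow(ppi_list[[1]]))
  )
  rowMeans(per_pp)
}

#' Connectivity surface over modulator z-scores
#'
#' Evaluates the modulator-dependent seed slope implied by windowed
#' group-level PPI coefficients on a grid of confidence and influence
#' z-scores: `seed + seed:conf * conf + seed:inf * inf + seed:conf:inf *
#' conf * inf`. The surface is linear in the coefficients; with only the
#' `seed:conf:inf` term nonzero it is a saddle, symmetric under a joint
#' sign flip of both axes.
#'
#' @param coefficients Named numeric vector containing `seed` and any of
#'   `seed:conf`, `seed:inf`, `seed:conf:inf` (e.g. from
#'   [ppi_window_coefficients()]).
#' @param conf_range,inf_range Grid ranges in z-score units.
#' @param step Grid step.
#' @return A tibble with `conf_z`, `inf_z`, `coupling`.
#' @export
connectivity_grid <- function(coefficients,
                              conf_range = c(-2, 2), inf_range = c(-2, 2),
                              step = 0.25) {
  g <- function(name) {
    if (name %in% names(coefficients)) unname(coefficients[name]) else 0
  }
  grid <- tidyr::expand_grid(
    conf_z = seq(conf_range[1], conf_range[2], by = step),
    inf_z = seq(inf_range[1], inf_range[2], by = step)
  )
  grid$coupling <- g("seed") +
    g("seed:conf") * grid$conf_z +
    g("seed:inf") * grid$inf_z +
    g("seed:conf:inf") * grid$conf_z * grid$inf_z
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a
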