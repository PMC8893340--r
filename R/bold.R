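#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with unit peak normalisation:
#' response peaking about 5 s after the event with an undershoot around
#' 15 s. `hrf(0) = 0` and the response is zero for `t < 0`.
#'
#' @param t Time in seconds since the event.
#' @param shape1,rate1 Gamma parameters of the positive lobe (mode
#'   `(shape1 - 1) / rate1` = 5 s by default).
#' @param shape2,rate2 Gamma parameters of the undershoot lobe.
#' @param undershoot Relative amplitude of the undershoot lobe.
#' @return Response amplitude, unit peak.
#' @export
#' @examples
#' curve(hrf(x), 0, 30)
hrf <- function(t, shape1 = 6, rate1 = 1, shape2 = 16, rate2 = 1,
                undershoot = 1 / 6) {
  peak <- max(raw_hrf(
    seq(0, 32, by = 0.01), shape1, rate1,
    shape2, rate2, undershoot
  ))
  out <- raw_hrf(t, shape1, rate1, shape2, rate2, undershoot) / peak
  out[t < 0] <- 0
  out
}

raw_hrf <- function(t, shape1, rate1, shape2, rate2, undershoot) {
  stats::dgamma(t, shape1, rate1) - undershoot * stats::dgamma(t, shape2, rate2)
}

#' Trial event timing parameters
#'
#' Fixed display durations and jitter bounds of the scanner version of
#' the task: partner photo 2 s, stimulus stream 1.38 s (91 rapid
#' blobs), partner-estimate display 1.5 s, final display of all
#' estimates 3 s, blank jitters uniform on 1.5-4.5 s after the
#' confidence report, the partner display and the final display;
#' estimate, confidence and revision screens last the participant's
#' reaction time. Repetition time 3.74 s.
#'
#' @param photo,stimulus,partner_display,final_display Durations (s).
#' @param jitter Length-2 lower/upper bounds (s) of the uniform jitters.
#' @param lead_in,washout Rest periods (s) at run start/end.
#' @param tr Repetition time (s).
#' @return A list of class `timing_params`.
#' @export
timing_params <- function(photo = 2, stimulus = 1.38, partner_display = 1.5,
                          final_display = 3, jitter = c(1.5, 4.5),
                          lead_in = 10, washout = 12, tr = 3.74) {
  structure(
    list(
      photo = photo, stimulus = stimulus,
      partner_display = partner_display, final_display = final_display,
      jitter = jitter, lead_in = lead_in, washout = washout, tr = tr
    ),
    class = "timing_params"
  )
}

#' Build the event schedule of a simulated session
#'
#' Lays the six trial events on a per-run clock: t1 stimulus stream, t2
#' initial estimate (reaction-timed), t3 confidence report
#' (reaction-timed), t4 partner estimate (1.5 s), t5 revision/observation
#' screen (reaction-timed), t6 display of the revised estimate (3 s),
#' with uniform 1.5-4.5 s jitters after t3, t4 and t6 and the partner
#' photo opening each trial. Runs land near 12-13 minutes, inside the
#' 12-17 minute band of the scan runs being emulated.
#'
#' @param trials One participant's trial table ([build_session()]).
#' @param timing A [timing_params()] object.
#' @param seed Optional seed for the jitter draws.
#' @return A tibble of events: `participant_id`, `block`, `trial_index`,
#'   `event` (`"t1"`..`"t6"`), `onset`, `duration` (s) and `run_length`
#'   (s, constant within block; rounded up to a whole number of TRs).
#' @export
build_event_schedule <- function(trials, timing = timing_params(),
                                 seed = NULL) {
  if (length(unique(trials$participant_id)) != 1) {
    stop("Schedules are built per participant.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  trials <- dplyr::arrange(trials, .data$block, .data$trial_index)
  n <- nrow(trials)
  j <- matrix(stats::runif(3 * n, timing$jitter[1], timing$jitter[2]), n, 3)
  per_run <- split(seq_len(n), trials$block)
  out <- vector("list", length(per_run))
  for (b in seq_along(per_run)) {
    idx <- per_run[[b]]
    cursor <- timing$lead_in
    rows <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      t1 <- cursor + timing$photo
      t2 <- t1 + timing$stimulus
      t3 <- t2 + trials$rt_estimate[i]
      t4 <- t3 + trials$rt_confidence[i] + j[i, 1]
      t5 <- t4 + timing$partner_display + j[i, 2]
      t6 <- t5 + trials$rt_revision[i]
      rows[[k]] <- tibble::tibble(
        trial_index = trials$trial_index[i],
        event = paste0("t", 1:6),
        onset = c(t1, t2, t3, t4, t5, t6),
        duration = c(
          timing$stimulus, trials$rt_estimate[i],
          trials$rt_confidence[i], timing$partner_display,
          trials$rt_revision[i], timing$final_display
        )
      )
      cursor <- t6 + timing$final_display + j[i, 3]
    }
    run <- dplyr::bind_rows(rows)
    run$block <- trials$block[idx[1]]
    run$run_length <-
      ceiling((cursor + timing$washout) / timing$tr) * timing$tr
    out[[b]] <- run
  }
  res <- dplyr::bind_rows(out)
  res$participant_id <- trials$participant_id[1]
  dplyr::select(
    res, "participant_id", "block", "trial_index",
    "event", "onset", "duration", "run_length"
  )
}

#' Ground-truth encoding specification for synthetic ROI signals
#'
#' Each row injects `weight` signal units per standard deviation of a
#' trial modulator into the response evoked by one event type, optionally
#' restricted by trial role and partner condition. Modulators are
#' z-scored per participant across the trials entering the event before
#' injection. `modulator = "baseline"` rows set the constant evoked
#' amplitude of the event.
#'
#' The default mimics the dACC findings the pipeline is designed to
#' recover: negative confidence encoding at the initial estimate (t2,
#' both conditions) and at the revision screen (t5, revise trials, both
#' conditions), plus negative confidence-by-influence interaction
#' encoding at t5 in the human condition only.
#'
#' @param extra Optional tibble of additional rows with the same columns.
#' @return A tibble with columns `event`, `role`, `condition`,
#'   `modulator`, `weight`.
#' @export
encoding_spec <- function(extra = NULL) {
  base <- tibble::tibble(
    event = c(paste0("t", 1:6), "t2", "t5", "t5"),
    role = c(rep("any", 6), "any", "revise", "revise"),
    condition = c(rep("any", 6), "any", "any", "human"),
    modulator = c(rep("baseline", 6), "conf", "conf", "conf_inf"),
    weight = c(rep(1, 6), -1, -1, -1)
  )
  if (!is.null(extra)) base <- dplyr::bind_rows(base, extra)
  base
}

#' Noise parameters for synthetic ROI signals
#'
#' AR(1) noise plus white measurement noise at the TR, and six smooth
#' random-walk motion regressors mixed into the signal with small random
#' weights so that nuisance residualisation is exercised non-trivially.
#'
#' @param ar_rho Lag-1 autocorrelation of the AR(1) component.
#' @param ar_sd Innovation SD of the AR(1) component.
#' @param white_sd SD of additive white noise.
#' @param motion_step SD of the motion random-walk increments.
#' @param motion_gain SD of the random weights mixing motion into the
#'   signal.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(ar_rho = 0.3, ar_sd = 0.5, white_sd = 0.2,
                         motion_step = 0.05, motion_gain = 0.1) {
  structure(
    list(
      ar_rho = ar_rho, ar_sd = ar_sd, white_sd = white_sd,
      motion_step = motion_step, motion_gain = motion_gain
    ),
    class = "noise_params"
  )
}

# Per-trial modulator values used by encoding specs.
trial_modulators <- function(trials) {
  tibble::tibble(
    block = trials$block,
    trial_index = trials$trial_index,
    role = trials$role,
    condition = trials$cover_story,
    conf = trials$conf_norm,
    inf = trials$prev_influence,
    conf_inf = trials$conf_norm * trials$prev_influence,
    log_rt = log(trials$rt_revision)
  )
}

# Evoked amplitude per (event, trial) row of a schedule under `encoding`.
event_amplitudes <- function(schedule, trials, encoding) {
  mods <- trial_modulators(trials)
  ev <- dplyr::left_join(
    schedule, mods,
    by = c("block", "trial_index")
  )
  amp <- numeric(nrow(ev))
  for (r in seq_len(nrow(encoding))) {
    spec <- encoding[r, ]
    sel <- ev$event == spec$event &
      (spec$role == "any" | ev$role == spec$role) &
      (spec$condition == "any" | ev$condition == spec$condition)
    if (!any(sel)) next
    if (spec$modulator == "baseline") {
      amp[sel] <- amp[sel] + spec$weight
    } else {
      if (!spec$modulator %in% names(ev)) {
        stop("Encoding references unknown modulator '", spec$modulator,
          "'.",
          call. = FALSE
        )
      }
      x <- ev[[spec$modulator]][sel]
      z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
      z[is.na(z)] <- 0
      amp[sel] <- amp[sel] + spec$weight * z
    }
  }
  amp
}

# Convolve impulses (onset, height) with the HRF and sample on a grid.
convolve_events <- function(onsets, heights, run_length, tr, dt = 0.1) {
  fine_t <- seq(0, run_length, by = dt)
  impulses <- numeric(length(fine_t))
  idx <- pmin(round(onsets / dt) + 1L, length(fine_t))
  for (k in seq_along(idx)) {
    impulses[idx[k]] <- impulses[idx[k]] + heights[k]
  }
  kernel <- hrf(seq(0, 32, by = dt))
  conv <- stats::filter(impulses, kernel, method = "convolution", sides = 1)
  conv[is.na(conv)] <- 0
  sample_t <- seq(0, run_length - tr, by = tr)
  list(time = sample_t, value = conv[round(sample_t / dt) + 1L])
}

ar1_noise <- function(n, rho, sd_innov) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd_innov), rho,
    method = "recursive"
  ))
}

#' Synthesise an ROI BOLD time series with known encoding
#'
#' The noiseless signal is the superposition of HRF responses to every
#' scheduled event, with evoked amplitudes set by the encoding
#' specification (baseline plus linear loading on z-scored trial
#' modulators). AR(1) noise, white noise and a linear mixture of six
#' synthetic motion regressors are added, and the result is sampled at
#' the TR. Fully deterministic under `seed`.
#'
#' @param schedule Event schedule from [build_event_schedule()].
#' @param trials Matching annotated trial table (one participant).
#' @param encoding An [encoding_spec()] tibble.
#' @param noise A [noise_params()] object; pass SDs of 0 for a noiseless
#'   signal.
#' @param label ROI label recorded on the object.
#' @param seed Optional seed.
#' @return An object of class `roi_signal`: list with `label`, `tr`,
#'   `samples` (tibble `block`, `time`, `value`) and `nuisance` (tibble
#'   `block`, `time`, `m1`..`m6`).
#' @export
synthesize_roi_signal <- function(schedule, trials,
                                  encoding = encoding_spec(),
                                  noise = noise_params(),
                                  label = "dACC", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- timing_params()$tr
  amp <- event_amplitudes(schedule, trials, encoding)
  samples <- list()
  nuis <- list()
  for (b in unique(schedule$block)) {
    sel <- schedule$block == b
    run_length <- schedule$run_length[sel][1]
    clean <- convolve_events(
      schedule$onset[sel], amp[sel], run_length, tr
    )
    n <- length(clean$time)
    motion <- matrix(stats::rnorm(6 * n, 0, noise$motion_step), n, 6)
    motion <- apply(motion, 2, cumsum)
    gains <- stats::rnorm(6, 0, noise$motion_gain)
    value <- clean$value +
      ar1_noise(n, noise$ar_rho, noise$ar_sd) +
      stats::rnorm(n, 0, noise$white_sd) +
      as.numeric(motion %*% gains)
    samples[[length(samples) + 1]] <- tibble::tibble(
      block = b, time = clean$time, value = value
    )
    colnames(motion) <- paste0("m", 1:6)
    nuis[[length(nuis) + 1]] <- dplyr::bind_cols(
      tibble::tibble(block = b, time = clean$time),
      tibble::as_tibble(motion)
    )
  }
  structure(
    list(
      label = label, tr = tr,
      samples = dplyr::bind_rows(samples),
      nuisance = dplyr::bind_rows(nuis)
    ),
    class = "roi_signal"
  )
}

#' @export
print.roi_signal <- function(x, ...) {
  cat("<roi_signal> ", x$label, ": ",
    length(unique(x$samples$block)), " run(s), ",
    nrow(x$samples), " samples at TR = ", x$tr, " s\n",
    sep = ""
  )
  invisible(x)
}

#' Coupling specification for a synthetic seed-target region pair
#'
#' Ground truth for psychophysiological interaction recovery: within the
#' epoch of each revision-screen event the target tracks the seed with a
#' gain that depends linearly on that trial's z-scored modulators,
#' `alpha + gamma_conf * conf + gamma_inf * inf + gamma_conf_inf *
#' conf x inf`; outside epochs the gain is `alpha`.
#'
#' @param alpha Baseline coupling gain.
#' @param gamma_conf,gamma_inf,gamma_conf_inf Modulator-dependent gains.
#' @param noise_sd SD of white noise added to the target.
#' @return A list of class `coupling_spec`.
#' @export
coupling_spec <- function(alpha = 1, gamma_conf = 0, gamma_inf = 0,
                          gamma_conf_inf = 1, noise_sd = 0.3) {
  structure(
    list(
      alpha = alpha, gamma_conf = gamma_conf, gamma_inf = gamma_inf,
      gamma_conf_inf = gamma_conf_inf, noise_sd = noise_sd
    ),
    class = "coupling_spec"
  )
}

#' Synthesise a coupled seed/target ROI pair
#'
#' The seed region is synthesised with [synthesize_roi_signal()]; the
#' target is the seed multiplied by a trial-dependent coupling gain (see
#' [coupling_spec()]) inside each revision-screen epoch, plus noise. The
#' pair provides ground truth for the PPI analysis: the recovered
#' seed-by-modulator interaction coefficients should match the signs of
#' the `gamma` gains.
#'
#' @param schedule Event schedule for one participant.
#' @param trials Matching trial table.
#' @param coupling A [coupling_spec()] object.
#' @param encoding Encoding for the seed region.
#' @param noise Noise for the seed region.
#' @param event Event whose epochs carry the modulated coupling.
#' @param seed Optional seed.
#' @return A list with `seed` and `target`, both `roi_signal` objects
#'   (the target shares the seed's motion nuisance).
#' @export
synthesize_coupled_pair <- function(schedule, trials,
                                    coupling = coupling_spec(),
                                    encoding = encoding_spec(),
                                    noise = noise_params(),
                                    event = "t5", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seed_sig <- synthesize_roi_signal(
    schedule, trials,
    encoding = encoding,
    noise = noise, label = "seed"
  )
  ev <- dplyr::filter(
    schedule, .data$event == !!event,
    .data$trial_index %in% trials$trial_index[trials$role == "revise"]
  )
  mods <- trial_modulators(trials)
  ev <- dplyr::left_join(ev, mods, by = c("block", "trial_index"))
  zsc <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      return(rep(0, length(x)))
    }
    z <- (x - mean(x, na.rm = TRUE)) / s
    z[is.na(z)] <- 0
    z
  }
  ev$gain <- coupling$alpha +
    coupling$gamma_conf * zsc(ev$conf) +
    coupling$gamma_inf * zsc(ev$inf) +
    coupling$gamma_conf_inf * zsc(ev$conf_inf)
  gain <- rep(coupling$alpha, nrow(seed_sig$samples))
  for (k in seq_len(nrow(ev))) {
    sel <- seed_sig$samples$block == ev$block[k] &
      seed_sig$samples$time >= ev$onset[k] - 1 &
      seed_sig$samples$time <= ev$onset[k] + 14
    gain[sel] <- ev$gain[k]
  }
  target <- seed_sig
  target$label <- "target"
  target$samples$value <- gain * seed_sig$samples$value +
    stats::rnorm(nrow(seed_sig$samples), 0, coupling$noise_sd)
  list(seed = seed_sig, target = target)
}
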