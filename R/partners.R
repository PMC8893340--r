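#' Default partner design for a session
#'
#' One partner per block; across a session the four partners realise the
#' full 2 x 2 crossing of cover story (human vs computer) and
#' susceptibility (susceptible vs insusceptible). The default order
#' interleaves human and computer blocks; the task structure itself does
#' not prescribe a block order, so any permutation covering the crossing
#' is accepted.
#'
#' @param order Optional integer permutation of 1:4 reordering the blocks.
#' @return A tibble with columns `block`, `label`, `cover_story`,
#'   `susceptibility`.
#' @export
#' @examples
#' partner_design()
partner_design <- function(order = NULL) {
  design <- tibble::tibble(
    label = c("H-sus", "C-sus", "H-ins", "C-ins"),
    cover_story = c("human", "computer", "human", "computer"),
    susceptibility = c(
      "susceptible", "susceptible",
      "insusceptible", "insusceptible"
    )
  )
  if (!is.null(order)) {
    stopifnot(length(order) == 4, setequal(order, 1:4))
    design <- design[order, ]
  }
  design$block <- 1:4
  validate_partner_design(design)
}

validate_partner_design <- function(design) {
  required <- c("block", "label", "cover_story", "susceptibility")
  if (!all(required %in% names(design))) {
    stop("Partner design needs columns: ", paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(design) != 4) {
    stop("A session has exactly 4 blocks, one partner each.", call. = FALSE)
  }
  cells <- paste(design$cover_story, design$susceptibility)
  expected <- c(
    "human susceptible", "human insusceptible",
    "computer susceptible", "computer insusceptible"
  )
  if (!setequal(cells, expected) || anyDuplicated(cells) > 0) {
    stop(
      "Partners must realise the 2 x 2 crossing of cover story x ",
      "susceptibility exactly once each.",
      call. = FALSE
    )
  }
  dplyr::select(
    design, "block", "label",
    "cover_story", "susceptibility"
  )
}

#' Sample a partner's first estimate
#'
#' On most trials the partner's first estimate is a von Mises draw centred
#' on the target with concentration `kappa = 7.4`. On high-confidence
#' trials (participant confidence 5 or 6) the partner instead answers
#' close to the participant: uniformly within +/-20 degrees of the
#' participant's choice in the behavioural setting, +/-50 degrees in the
#' fMRI setting (wrap-aware). This keeps high-confidence disagreements
#' small while all partners share the same accuracy-generating algorithm.
#'
#' @param target Target angle(s), degrees.
#' @param self_initial Participant initial estimate(s), degrees.
#' @param confidence Integer confidence report(s) in 1..6.
#' @param setting `"behavioural"` or `"fmri"`.
#' @param kappa Concentration of the target-centred draw (default 7.4).
#' @return Angles in `[0, 360)`, one per trial.
#' @export
sample_partner_initial <- function(target, self_initial, confidence,
                                   setting = c("behavioural", "fmri"),
                                   kappa = 7.4) {
  setting <- match.arg(setting)
  n <- max(length(target), length(self_initial), length(confidence))
  target <- rep_len(target, n)
  self_initial <- rep_len(self_initial, n)
  confidence <- rep_len(confidence, n)
  if (any(!confidence %in% 1:6)) {
    stop("`confidence` must be integers in 1..6.", call. = FALSE)
  }
  width <- if (setting == "behavioural") 20 else 50
  high <- confidence >= 5
  out <- numeric(n)
  if (any(!high)) {
    # draw at mu = 0 then rotate, so one batch serves all targets
    out[!high] <- norm_angle(
      target[!high] + rvonmises(sum(!high), mu = 0, kappa = kappa)
    )
  }
  if (any(high)) {
    out[high] <- norm_angle(
      self_initial[high] + stats::runif(sum(high), -width, width)
    )
  }
  out
}

#' Sample the influence a partner will exert back on the participant
#'
#' Insusceptible partners barely move: influence is uniform on
#' `[0, 0.2]`. Susceptible partners are strongly influenced: a mixture
#' drawing from `[0.7, 1]` with probability 0.5, `[0.3, 0.7]` with
#' probability 0.2 and `[0, 0.3]` with probability 0.3 (analytic mean
#' 0.57).
#'
#' @param susceptibility `"susceptible"` or `"insusceptible"` (vector
#'   recycled to `n`).
#' @param n Number of draws.
#' @return Influence fractions in `[0, 1]`.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_influence("susceptible", 1e4))
sample_influence <- function(susceptibility, n = length(susceptibility)) {
  susceptibility <- rep_len(susceptibility, n)
  bad <- !susceptibility %in% c("susceptible", "insusceptible")
  if (any(bad)) {
    stop(
      "Unknown susceptibility label: ",
      paste(unique(susceptibility[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out <- numeric(n)
  ins <- susceptibility == "insusceptible"
  out[ins] <- stats::runif(sum(ins), 0, 0.2)
  ns <- sum(!ins)
  if (ns > 0) {
    comp <- sample.int(3L, ns, replace = TRUE, prob = c(0.5, 0.2, 0.3))
    lo <- c(0.7, 0.3, 0)[comp]
    hi <- c(1, 0.7, 0.3)[comp]
    out[!ins] <- stats::runif(ns, lo, hi)
  }
  out
}

#' Apply a drawn influence to produce the partner's revised estimate
#'
#' Shorter-arc linear interpolation from the partner's initial estimate
#' towards the participant's, so that the recorded influence statistic
#' (`shift_fraction`) equals the drawn influence value by construction.
#' With zero initial disagreement the partner keeps its estimate and the
#' influence statistic is undefined (recorded as missing downstream).
#'
#' @param partner_initial Partner initial estimate(s), degrees.
#' @param self_initial Participant initial estimate(s), degrees.
#' @param influence Influence fraction(s) in `[0, 1]`.
#' @return Revised partner estimate(s) in `[0, 360)`.
#' @export
partner_revision <- function(partner_initial, self_initial, influence) {
  move_toward(partner_initial, self_initial, influence)
}
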