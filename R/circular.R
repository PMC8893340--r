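#' Circular geometry in degrees
#'
#' All angles in the package live on the circle, measured in degrees and
#' normalised to the half-open interval `[0, 360)`. Distances between angles
#' are shortest-arc distances in `[0, 180]`. These primitives underpin every
#' estimate, error and conformity statistic in the package.
#'
#' @name circular
NULL

#' Normalise an angle to `[0, 360)`
#'
#' Idempotent: `norm_angle(norm_angle(x)) == norm_angle(x)`, and
#' `x + 360 * k` maps to the same angle for every integer `k`.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of angles in `[0, 360)`.
#' @export
#' @examples
#' norm_angle(c(-30, 360, 725))
norm_angle <- function(x) {
  check_angle(x)
  x %% 360
}

#' Shortest-arc distance between two angles
#'
#' Symmetric in its arguments, zero iff the two angles coincide on the
#' circle, and a metric (the triangle inequality holds).
#'
#' @param x,y Numeric vectors of angles in degrees (recycled to a common
#'   length).
#' @return Distances in degrees, in `[0, 180]`.
#' @export
#' @examples
#' arc_distance(10, 350) # 20, across the wrap
#' arc_distance(90, 300) # 150 = min(210, 150)
arc_distance <- function(x, y) {
  check_angle(x)
  check_angle(y)
  d <- abs(x - y) %% 360
  pmin(d, 360 - d)
}

#' Move a fraction of the way along the shorter arc
#'
#' Returns the angle a fraction `w` along the shorter arc from `origin`
#' to `target`, so that `arc_distance(result, origin)` equals
#' `w * arc_distance(origin, target)`. This realises the task rule that a
#' revised estimate must lie between the two initial estimates. Exact
#' antipodes (`arc_distance == 180`) are a tie between the two arcs; the
#' tie is broken deterministically by moving counter-clockwise (in the
#' direction of increasing angle).
#'
#' @param origin,target Angles in degrees.
#' @param w Interpolation fraction in `[0, 1]`; 0 returns `origin`,
#'   1 returns `target` (up to normalisation).
#' @return Angle in `[0, 360)`.
#' @export
#' @examples
#' move_toward(100, 40, 0.5) # 70
#' move_toward(350, 10, 0.5) # 0, shorter arc crosses the wrap
move_toward <- function(origin, target, w) {
  check_angle(origin)
  check_angle(target)
  if (!is.numeric(w) || any(!is.finite(w))) {
    stop("`w` must be finite and numeric.", call. = FALSE)
  }
  if (any(w < 0 | w > 1)) {
    stop("`w` must lie in [0, 1].", call. = FALSE)
  }
  # signed shortest-arc step in (-180, 180]; +180 for antipodes = counter-clockwise
  delta <- (target - origin) %% 360
  delta <- ifelse(delta > 180, delta - 360, delta)
  (origin + w * delta) %% 360
}

#' Fraction of the initial gap closed by a revision
#'
#' The single statistic that quantifies both *revision* (how far a
#' participant moved their estimate towards the partner's) and *influence*
#' (how far the partner moved towards the participant's): the shortest-arc
#' distance between the initial and final estimate, divided by the
#' shortest-arc distance between the two initial estimates. 0 means the
#' estimate was kept, 1 means full adoption of the other's estimate.
#'
#' Trials with zero initial disagreement leave the statistic undefined;
#' those elements are returned as `NA` and callers are expected to drop
#' them. A `final` estimate off the permitted shorter arc between `init`
#' and `other_init` violates the task rule and raises an error.
#'
#' @param init Initial estimate of the revising party (degrees).
#' @param final Revised estimate of the same party (degrees).
#' @param other_init Initial estimate of the other party (degrees).
#' @param tol Tolerance (degrees) for the on-arc check.
#' @return Fractions in `[0, 1]`; `NA` where `init == other_init`.
#' @export
#' @examples
#' shift_fraction(0, 30, 60) # 0.5
#' shift_fraction(0, 60, 60) # 1, full adoption
shift_fraction <- function(init, final, other_init, tol = 1e-6) {
  check_angle(init)
  check_angle(final)
  check_angle(other_init)
  gap <- arc_distance(init, other_init)
  moved <- arc_distance(init, final)
  rest <- arc_distance(final, other_init)
  defined <- gap > 0
  off_arc <- defined & (abs(moved + rest - gap) > tol)
  if (any(off_arc)) {
    stop(
      sum(off_arc), " final estimate(s) lie off the shorter arc between ",
      "the two initial estimates.",
      call. = FALSE
    )
  }
  out <- rep(NA_real_, length(gap))
  out[defined] <- pmin(moved[defined] / gap[defined], 1)
  out
}

check_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("Angles must be finite numeric values (degrees).", call. = FALSE)
  }
  invisible(x)
}
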