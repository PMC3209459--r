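# Natural course of clinical conduct disorder and intervention-modified
# persistence trajectories.
#
# The cohort model tracks a single quantity: the probability that a child
# who has clinical conduct disorder at the model start age still has it at
# each later age. The natural course is an anchored piecewise-linear curve
# for the reference cohort (clinical at age 3); every trajectory is a
# conditional slice of that curve.

#' Default persistence anchors for the natural course
#'
#' Published anchor points for the proportion of an age-3 clinical cohort
#' still showing clinical conduct problems at later ages: all are clinical
#' at age 3, about 60% still are at age 8, and about 50% continue into
#' adulthood (placed at age 16, the last age before adult costs apply).
#'
#' @return A tibble with columns `age` and `proportion`.
#' @export
default_anchors <- function() {
  tibble::tibble(age = c(3L, 8L, 16L), proportion = c(1.00, 0.60, 0.50))
}

#' Build a natural-course persistence curve
#'
#' Constructs the piecewise-linear natural course of clinical conduct
#' disorder from anchor points. Between anchors the proportion of the
#' reference cohort still clinical is linearly interpolated; beyond the
#' last anchor it is held constant (persistent conduct disorder is treated
#' as absorbing into adulthood).
#'
#' @param anchors A data frame with columns `age` (strictly increasing
#'   integers) and `proportion` (non-increasing values in \[0, 1\]).
#' @return An object of class `natural_course`.
#' @examples
#' course <- natural_course()
#' proportion_at(course, 8)
#' @export
natural_course <- function(anchors = default_anchors()) {
  anchors <- tibble::as_tibble(anchors)
  if (!all(c("age", "proportion") %in% names(anchors))) {
    stop("`anchors` must have columns `age` and `proportion`", call. = FALSE)
  }
  if (nrow(anchors) < 2L) {
    stop("at least two anchors are required", call. = FALSE)
  }
  if (any(diff(anchors$age) <= 0)) {
    stop("anchor ages must be strictly increasing", call. = FALSE)
  }
  if (any(anchors$proportion < 0 | anchors$proportion > 1)) {
    stop("anchor proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(anchors$proportion) > 0)) {
    stop("anchor proportions must be non-increasing with age", call. = FALSE)
  }
  structure(list(anchors = anchors), class = "natural_course")
}

#' @export
print.natural_course <- function(x, ...) {
  cat("Natural course of clinical conduct disorder\n")
  cat(sprintf("  anchors: %s\n",
              paste(sprintf("%d yr -> %.2f", x$anchors$age,
                            x$anchors$proportion), collapse = ", ")))
  cat("  constant beyond last anchor\n")
  invisible(x)
}

#' Proportion of the reference cohort still clinical at an age
#'
#' Piecewise-linear interpolation of the natural-course curve, constant at
#' the last anchor's proportion for later ages.
#'
#' @param course A [natural_course()] object.
#' @param age Age(s) in years; must not precede the first anchor.
#' @return Numeric vector of proportions in \[0, 1\].
#' @export
proportion_at <- function(course, age) {
  stopifnot(inherits(course, "natural_course"))
  a <- course$anchors
  if (any(age < a$age[1L])) {
    stop(sprintf("age must be >= first anchor age (%d)", a$age[1L]),
         call. = FALSE)
  }
  stats::approx(a$age, a$proportion, xout = age, method = "linear",
                rule = 2)$y
}

#' Conditional persistence probability between two ages
#'
#' The probability that conduct disorder still persists at `to_age` given
#' that it persists at `from_age`, computed as the ratio of the natural
#' course proportions at the two ages.
#'
#' @param course A [natural_course()] object.
#' @param from_age Conditioning age (years).
#' @param to_age Target age(s), each `>= from_age`.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
conditional_persistence <- function(course, from_age, to_age) {
  stopifnot(length(from_age) == 1L)
  if (any(to_age < from_age)) {
    stop("`to_age` must be >= `from_age`", call. = FALSE)
  }
  denom <- proportion_at(course, from_age)
  if (denom <= 0) {
    stop("proportion at `from_age` is zero; conditional probability undefined",
         call. = FALSE)
  }
  clamp01(proportion_at(course, to_age) / denom)
}

new_trajectory <- function(age, p_clinical, start_age) {
  out <- tibble::tibble(age = as.integer(age), p_clinical = p_clinical)
  attr(out, "start_age") <- as.integer(start_age)
  class(out) <- c("cd_trajectory", class(out))
  out
}

#' Natural (no-intervention) persistence trajectory
#'
#' The probability that a child clinical at `start_age` is still clinical
#' at each age up to `start_age + horizon`, following the natural course.
#'
#' @param course A [natural_course()] object.
#' @param start_age Model start age in years (default 5).
#' @param horizon Number of annual periods (default 25).
#' @return A `cd_trajectory` tibble with columns `age` and `p_clinical`.
#' @examples
#' natural_trajectory(natural_course())
#' @export
natural_trajectory <- function(course, start_age = 5L, horizon = 25L) {
  stopifnot(horizon >= 1L)
  ages <- start_age + 0:horizon
  new_trajectory(ages, conditional_persistence(course, start_age, ages),
                 start_age)
}

#' Intervention scenario parameters
#'
#' Bundles the three levers of an intervention scenario: the drop-out rate
#' (families starting but not completing the programme, who receive no
#' effect), the effectiveness (relative reduction in the start-age to next-
#' age conditional persistence probability among completers), and the
#' recidivism rate (fraction of intervention-attributable improvers who
#' revert to clinical behaviour one year after the effect year).
#'
#' @param dropout Fraction in \[0, 1\].
#' @param effectiveness Fraction in \[0, 1\].
#' @param recidivism Fraction in \[0, 1\].
#' @return An object of class `scenario_params`.
#' @examples
#' scenario_params(dropout = 0.44, effectiveness = 0.34, recidivism = 0.50)
#' @export
scenario_params <- function(dropout, effectiveness, recidivism) {
  assert_fraction(dropout, "dropout")
  assert_fraction(effectiveness, "effectiveness")
  assert_fraction(recidivism, "recidivism")
  structure(list(dropout = dropout, effectiveness = effectiveness,
                 recidivism = recidivism),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf(
    "Scenario parameters: drop-out %.0f%%, effectiveness %.0f%%, recidivism %.0f%%\n",
    100 * x$dropout, 100 * x$effectiveness, 100 * x$recidivism))
  invisible(x)
}

#' Intervention-modified persistence trajectory
#'
#' Applies a parenting-programme scenario to the natural course. In the
#' intervention year (`start_age`, period 0) the whole cohort is clinical.
#' Completers (share `1 - dropout`) transition to `start_age + 1` with the
#' natural conditional probability reduced by the factor
#' `1 - effectiveness`; drop-outs transition with the unreduced
#' probability. One year later, a fraction `recidivism` of the
#' intervention-attributable improvers reverts to the clinical pool, after
#' which every clinical child follows the natural course (which itself
#' allows spontaneous resolution). The clinical share is never allowed to
#' exceed the natural-course trajectory: reverters rejoin the path they
#' would have followed without intervention, so full recidivism restores
#' the natural trajectory exactly from `start_age + 2` onward.
#'
#' @param course A [natural_course()] object.
#' @param params A [scenario_params()] object.
#' @param start_age Model start age in years (default 5).
#' @param horizon Number of annual periods, at least 2 (default 25).
#' @return A `cd_trajectory` tibble with columns `age` and `p_clinical`.
#' @examples
#' base <- scenario_params(0.44, 0.34, 0.50)
#' tr <- intervention_trajectory(natural_course(), base)
#' truncate_pct(tr$p_clinical[tr$age == 17])  # 54
#' @export
intervention_trajectory <- function(course, params, start_age = 5L,
                                    horizon = 25L) {
  stopifnot(inherits(params, "scenario_params"), horizon >= 2L)
  d <- params$dropout
  e <- params$effectiveness
  rho <- params$recidivism

  p1 <- conditional_persistence(course, start_age, start_age + 1L)
  c1 <- clamp01(p1 * (1 - (1 - d) * e))
  x <- p1 - c1  # intervention-attributable improvers
  if (x == 0) {
    # no completers benefit (e = 0 or d = 1): the natural course, exactly
    return(natural_trajectory(course, start_age, horizon))
  }
  q <- conditional_persistence(course, start_age + 1L, start_age + 2L)
  c2 <- clamp01(c1 * q + rho * x)
  c2 <- min(c2, p1 * q)  # reverters cannot overshoot the natural path

  ages <- start_age + 0:horizon
  p <- numeric(horizon + 1L)
  p[1L] <- 1
  p[2L] <- c1
  p[3L] <- c2
  if (horizon > 2L) {
    later <- ages[-(1:3)]
    p[-(1:3)] <- clamp01(
      c2 * conditional_persistence(course, start_age + 2L, later))
  }
  new_trajectory(ages, p, start_age)
}

#' Persistence probability beyond a given age
#'
#' Reads the trajectory value just past `age` (by default 16, so the value
#' reported is the probability that conduct disorder persists into
#' adulthood). Under the constant-beyond-last-anchor rule this value is
#' flat for all later ages.
#'
#' @param trajectory A `cd_trajectory` tibble.
#' @param age Age threshold in years (default 16).
#' @return A single probability.
#' @export
persistence_beyond <- function(trajectory, age = 16L) {
  stopifnot(inherits(trajectory, "cd_trajectory"))
  idx <- which(trajectory$age > age)
  if (length(idx) == 0L) {
    stop(sprintf("trajectory does not extend beyond age %d", age),
         call. = FALSE)
  }
  trajectory$p_clinical[idx[1L]]
}
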