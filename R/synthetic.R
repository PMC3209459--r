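# Seed-deterministic generators for synthetic model inputs: a per-age
# crime-cost schedule with the structure the costing module expects, and
# trial summary tables for effectiveness parameter recovery.
#
# The true per-age crime costs derive from offending-survey and unit-cost
# data that are not redistributable; the generator reproduces their
# structure (ages 10-25, unimodal profile peaking in the late teens, four
# cost components) and a calibration step rescales each component so its
# discounted present-value saving matches a supplied target. Calibration,
# not the shape, carries the quantitative burden.

#' Published present-value targets for the crime components
#'
#' Present value of base-case savings (GBP per family over 25 years)
#' attributed to the four crime-cost components, used as default
#' calibration targets for the synthetic crime schedule.
#'
#' @return Named numeric vector.
#' @export
crime_pv_targets <- function() {
  c(criminal_justice = 2842, victim = 7468, lost_output = 2197, other = 906)
}

#' Generate a synthetic per-age crime-cost schedule
#'
#' Builds a schedule of annual crime-related costs (GBP) incurred given
#' clinical childhood conduct disorder, for ages 10-25 by default. The age
#' profile is a discretised gamma-shaped curve with its mode at
#' `peak_age`, optionally perturbed by seeded multiplicative log-normal
#' noise; all components share the profile, so component totals (and, at
#' zero discounting, component present values) stay proportional to
#' `splits`.
#'
#' @param ages Integer ages covered (default `10:25`).
#' @param peak_age Mode of the age profile (default 18).
#' @param splits Named fractions over [crime_components()] summing to 1;
#'   default proportional to [crime_pv_targets()].
#' @param scale Total nominal cost across all ages and components (GBP;
#'   default 60000, a placeholder magnitude ahead of calibration).
#' @param noise_sd SD of log-normal noise on the age profile (default
#'   0.1; 0 gives the smooth curve).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A tibble with columns `age`, `component`, `cost_gbp`.
#' @examples
#' gen_crime_schedule(seed = 1)
#' @export
gen_crime_schedule <- function(ages = 10:25, peak_age = 18, splits = NULL,
                               scale = 60000, noise_sd = 0.1, seed = 1) {
  if (is.null(splits)) {
    tg <- crime_pv_targets()
    splits <- tg / sum(tg)
  }
  if (!all(sort(names(splits)) == sort(crime_components()))) {
    stop("`splits` must be named over crime_components()", call. = FALSE)
  }
  if (any(splits < 0) || abs(sum(splits) - 1) > 1e-8) {
    stop("`splits` must be non-negative and sum to 1", call. = FALSE)
  }
  assert_scalar_number(scale, "scale", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot(peak_age >= min(ages), peak_age <= max(ages))

  offset <- ages - min(ages) + 1
  gshape <- (peak_age - min(ages) + 1) / 2 + 1  # gamma mode at peak_age
  w <- stats::dgamma(offset, shape = gshape, scale = 2)
  if (noise_sd > 0) {
    w <- with_local_seed(seed,
                         w * exp(stats::rnorm(length(w), 0, noise_sd)))
  }
  profile <- w / sum(w)

  comps <- crime_components()
  tibble::tibble(
    age = rep(as.integer(ages), times = length(comps)),
    component = rep(comps, each = length(ages)),
    cost_gbp = as.numeric(vapply(comps, function(cp) scale * splits[[cp]] *
                                   profile, numeric(length(ages))))
  )
}

# PV of discounted savings per crime component for a given trajectory pair.
crime_component_pv <- function(crime, control, intervention, discount) {
  check_aligned(control, intervention)
  start_age <- attr(control, "start_age")
  gap <- control$p_clinical - intervention$p_clinical
  out <- vapply(crime_components(), function(cp) {
    cc <- crime[crime$component == cp, , drop = FALSE]
    idx <- match(cc$age, control$age)
    keep <- !is.na(idx)
    sum(cc$cost_gbp[keep] * gap[idx[keep]] *
          discount_factor(discount, cc$age[keep] - start_age))
  }, numeric(1))
  out
}

#' Calibrate a crime schedule to present-value targets
#'
#' Rescales each component of a crime-cost schedule by the single factor
#' that makes the discounted present value of its savings — for the given
#' control/intervention trajectory pair — equal the target. PV is linear
#' in costs, so the calibration is exact.
#'
#' @param crime A crime schedule as from [gen_crime_schedule()].
#' @param control,intervention Aligned `cd_trajectory` objects (normally
#'   the base-case pair).
#' @param discount A [discount_spec()].
#' @param targets Named PV targets in GBP (default [crime_pv_targets()]).
#' @return The rescaled schedule, with the per-component scale factors in
#'   the `"scales"` attribute.
#' @export
calibrate_to_pv <- function(crime, control, intervention,
                            discount = discount_spec(),
                            targets = crime_pv_targets()) {
  crime <- check_crime_schedule(crime)
  if (!all(names(targets) %in% crime_components())) {
    stop("`targets` must be named over crime_components()", call. = FALSE)
  }
  pv <- crime_component_pv(crime, control, intervention, discount)
  scales <- stats::setNames(rep(1, length(crime_components())),
                            crime_components())
  for (cp in names(targets)) {
    if (pv[[cp]] <= 0 && targets[[cp]] > 0) {
      stop(sprintf(
        "component '%s' has zero present value; cannot calibrate to %.0f",
        cp, targets[[cp]]), call. = FALSE)
    }
    if (targets[[cp]] == 0) {
      scales[[cp]] <- 0
    } else {
      scales[[cp]] <- targets[[cp]] / pv[[cp]]
    }
  }
  crime$cost_gbp <- crime$cost_gbp * scales[crime$component]
  attr(crime, "scales") <- scales
  crime
}

#' Generate a synthetic trial table for parameter recovery
#'
#' Simulates post-treatment ECBI-I summary statistics for parallel-arm
#' parenting-programme trials with a known true effect. Control arm
#' moments are drawn from the supplied ranges; the intervention mean is
#' solved so that the closed-form relative reduction in the clinical
#' fraction equals `true_reduction` exactly before sampling noise.
#' Optional noise perturbs the reported means and SDs at the level
#' expected of summary statistics (mean ~ Normal(mu, sigma^2/n), SD from a
#' scaled chi distribution); control arms are redrawn in the rare case the
#' observed mean falls at or below the cut-off, so every generated trial
#' passes the eligibility filter.
#'
#' @param n_trials Number of trials (default 50).
#' @param true_reduction True relative reduction in the clinical fraction,
#'   in `[0, 1)` (default 0.34).
#' @param ctrl_mean_range,sd_range Uniform ranges for the control mean and
#'   both arms' SDs (defaults 135-160 and 20-35, typical of clinical-range
#'   trial arms).
#' @param arm_n_range Integer range of per-arm sizes (default 15-60).
#' @param cutoff Clinical cut-off (default 126).
#' @param sampling_noise Add summary-statistic sampling noise? (default
#'   TRUE)
#' @param seed Integer seed; the table is deterministic given the seed.
#' @return A trial tibble with columns `id`, `int_mean`, `int_sd`,
#'   `int_n`, `ctrl_mean`, `ctrl_sd`, `ctrl_n`.
#' @examples
#' gen_trials(n_trials = 5, seed = 1)
#' @export
gen_trials <- function(n_trials = 50, true_reduction = 0.34,
                       ctrl_mean_range = c(135, 160), sd_range = c(20, 35),
                       arm_n_range = c(15, 60), cutoff = 126,
                       sampling_noise = TRUE, seed = 1) {
  stopifnot(n_trials >= 1)
  if (!is.numeric(true_reduction) || true_reduction < 0 ||
      true_reduction >= 1) {
    stop("`true_reduction` must lie in [0, 1): a full (or larger) ",
         "reduction gives a degenerate intervention arm", call. = FALSE)
  }
  if (min(arm_n_range) < 10) {
    stop("arm sizes must be >= 10", call. = FALSE)
  }
  if (min(ctrl_mean_range) <= cutoff) {
    stop("`ctrl_mean_range` must lie above the cut-off so generated ",
         "trials pass the eligibility filter", call. = FALSE)
  }

  with_local_seed(seed, {
    rows <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      ctrl_mu <- stats::runif(1, ctrl_mean_range[1], ctrl_mean_range[2])
      ctrl_sigma <- stats::runif(1, sd_range[1], sd_range[2])
      int_sigma <- stats::runif(1, sd_range[1], sd_range[2])
      n_c <- sample(arm_n_range[1]:arm_n_range[2], 1)
      n_i <- sample(arm_n_range[1]:arm_n_range[2], 1)

      f_ctrl <- stats::pnorm(cutoff, ctrl_mu, ctrl_sigma,
                             lower.tail = FALSE)
      f_int <- f_ctrl * (1 - true_reduction)
      int_mu <- cutoff - int_sigma * stats::qnorm(1 - f_int)

      if (sampling_noise) {
        repeat {
          ctrl_mean_obs <- ctrl_mu + stats::rnorm(1) * ctrl_sigma / sqrt(n_c)
          if (ctrl_mean_obs > cutoff) break
        }
        int_mean_obs <- int_mu + stats::rnorm(1) * int_sigma / sqrt(n_i)
        ctrl_sd_obs <- ctrl_sigma *
          sqrt(stats::rchisq(1, df = n_c - 1) / (n_c - 1))
        int_sd_obs <- int_sigma *
          sqrt(stats::rchisq(1, df = n_i - 1) / (n_i - 1))
      } else {
        ctrl_mean_obs <- ctrl_mu
        int_mean_obs <- int_mu
        ctrl_sd_obs <- ctrl_sigma
        int_sd_obs <- int_sigma
      }
      rows[[i]] <- tibble::tibble(
        id = sprintf("trial_%03d", i),
        int_mean = int_mean_obs, int_sd = int_sd_obs, int_n = n_i,
        ctrl_mean = ctrl_mean_obs, ctrl_sd = ctrl_sd_obs, ctrl_n = n_c
      )
    }
    do.call(rbind, rows)
  })
}

#' Read/write crime schedules as CSV
#'
#' @param path CSV path with columns `age`, `component`, `cost_gbp`.
#' @return `read_crime_schedule` returns a validated tibble;
#'   `write_crime_schedule` writes and returns the schedule invisibly.
#' @export
read_crime_schedule <- function(path) {
  check_crime_schedule(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_crime_schedule
#' @param crime A crime schedule tibble.
#' @export
write_crime_schedule <- function(crime, path) {
  utils::write.csv(check_crime_schedule(crime), path, row.names = FALSE)
  invisible(crime)
}
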