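# Responder-proportion estimation from trial arm summary statistics.
#
# Parenting-programme trials report post-treatment Eyberg Child Behaviour
# Inventory intensity (ECBI-I) means and SDs per arm. Assuming scores are
# Normal with those moments, the fraction of children above the clinical
# cut-off (126) is a tail probability; the difference between the control
# and intervention fractions is the per-trial intervention effect.

#' Fraction of an arm's children in the clinical range
#'
#' Estimates the proportion of a trial arm scoring strictly above the
#' ECBI-I clinical cut-off, assuming scores follow a Normal distribution
#' with the arm's post-treatment mean and SD. The closed form is the
#' Normal upper-tail probability; the Monte Carlo method draws seeded
#' samples and converges to the closed form as `draws` grows.
#'
#' @param mean Post-treatment mean score (vectorised for the closed form).
#' @param sd Post-treatment standard deviation, `> 0`.
#' @param cutoff Clinical cut-off score (default 126).
#' @param method `"closed_form"` (default) or `"monte_carlo"`.
#' @param draws Number of Monte Carlo draws (default 1e5).
#' @param seed Integer seed, required for the Monte Carlo method.
#' @return Estimated clinical fraction(s) in \[0, 1\].
#' @examples
#' clinical_fraction(140, 30)                    # closed form
#' clinical_fraction(140, 30, method = "monte_carlo", seed = 1)
#' @export
clinical_fraction <- function(mean, sd, cutoff = 126,
                              method = c("closed_form", "monte_carlo"),
                              draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("`sd` must be > 0", call. = FALSE)
  }
  if (method == "closed_form") {
    return(stats::pnorm(cutoff, mean = mean, sd = sd, lower.tail = FALSE))
  }
  stopifnot(length(mean) == 1L, length(sd) == 1L)
  if (draws < 1) stop("`draws` must be >= 1", call. = FALSE)
  if (is.null(seed)) {
    stop("a `seed` is required for the Monte Carlo method", call. = FALSE)
  }
  with_local_seed(seed, {
    base::mean(stats::rnorm(draws, mean = mean, sd = sd) > cutoff)
  })
}

check_trial_table <- function(trials) {
  trials <- tibble::as_tibble(trials)
  needed <- c("id", "int_mean", "int_sd", "int_n",
              "ctrl_mean", "ctrl_sd", "ctrl_n")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0L) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(trials$int_sd <= 0) || any(trials$ctrl_sd <= 0)) {
    stop("arm SDs must be > 0", call. = FALSE)
  }
  if (any(trials$int_n < 1) || any(trials$ctrl_n < 1)) {
    stop("arm sizes must be >= 1", call. = FALSE)
  }
  trials
}

#' Trial eligibility filter
#'
#' A trial enters the effectiveness estimate only if its control arm's
#' post-treatment mean is above the clinical cut-off (the control group
#' remains, on average, in the clinical range) and the total number of
#' participants is at least `min_total_n`.
#'
#' @param trials Trial table with columns `id`, `int_mean`, `int_sd`,
#'   `int_n`, `ctrl_mean`, `ctrl_sd`, `ctrl_n`.
#' @param cutoff Clinical cut-off (default 126).
#' @param min_total_n Minimum total participants (default 20).
#' @return Logical vector, one element per trial.
#' @export
eligible_trials <- function(trials, cutoff = 126, min_total_n = 20) {
  trials <- check_trial_table(trials)
  trials$ctrl_mean > cutoff & (trials$int_n + trials$ctrl_n) >= min_total_n
}

#' Per-trial intervention effects on the clinical fraction
#'
#' For each trial, estimates the clinical fraction in both arms and
#' returns the absolute reduction (control minus intervention) and the
#' relative reduction (absolute reduction over the control fraction). The
#' relative reduction is `NA` when the control fraction is zero.
#'
#' @inheritParams eligible_trials
#' @param method,draws,seed Passed to [clinical_fraction()]; Monte Carlo
#'   uses `seed + i` for the i-th arm evaluation, so results are
#'   reproducible row by row.
#' @return A tibble with columns `id`, `ctrl_fraction`, `int_fraction`,
#'   `absolute_reduction`, `relative_reduction`.
#' @examples
#' trials <- tibble::tibble(id = "t", int_mean = 130, int_sd = 20, int_n = 20,
#'                          ctrl_mean = 150, ctrl_sd = 20, ctrl_n = 20)
#' trial_effects(trials)
#' @export
trial_effects <- function(trials, cutoff = 126,
                          method = c("closed_form", "monte_carlo"),
                          draws = 1e5, seed = NULL) {
  trials <- check_trial_table(trials)
  method <- match.arg(method)
  n <- nrow(trials)
  ctrl <- numeric(n)
  int <- numeric(n)
  for (i in seq_len(n)) {
    seeds <- if (is.null(seed)) list(NULL, NULL) else
      list(seed + 2L * i, seed + 2L * i + 1L)
    ctrl[i] <- clinical_fraction(trials$ctrl_mean[i], trials$ctrl_sd[i],
                                 cutoff, method, draws, seeds[[1L]])
    int[i] <- clinical_fraction(trials$int_mean[i], trials$int_sd[i],
                                cutoff, method, draws, seeds[[2L]])
  }
  abs_red <- ctrl - int
  rel_red <- ifelse(ctrl > 0, abs_red / ctrl, NA_real_)
  if (anyNA(rel_red)) {
    warning("control clinical fraction is zero for some trials; ",
            "relative reduction undefined (NA)", call. = FALSE)
  }
  tibble::tibble(id = trials$id, ctrl_fraction = ctrl, int_fraction = int,
                 absolute_reduction = abs_red, relative_reduction = rel_red)
}

#' Pool per-trial relative reductions
#'
#' Summarises a set of per-trial relative reductions by their arithmetic
#' mean, minimum and maximum — the form in which the effectiveness
#' parameter and its sensitivity range enter the cohort model.
#'
#' @param effects Either the tibble returned by [trial_effects()] or a
#'   numeric vector of relative reductions.
#' @return A one-row tibble with columns `n`, `mean`, `min`, `max`.
#' @export
pool_effects <- function(effects) {
  x <- if (is.data.frame(effects)) effects$relative_reduction else effects
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    stop("no effect estimates to pool", call. = FALSE)
  }
  tibble::tibble(n = length(x), mean = base::mean(x), min = min(x),
                 max = max(x))
}

#' Estimate programme effectiveness from a trial table
#'
#' Convenience pipeline: applies the eligibility filter, computes
#' per-trial effects, and pools the relative reductions.
#'
#' @inheritParams trial_effects
#' @param min_total_n Minimum total participants (default 20).
#' @return A list with elements `effects` (per eligible trial) and
#'   `pooled` (one-row summary tibble).
#' @export
estimate_effectiveness <- function(trials, cutoff = 126, min_total_n = 20,
                                   method = c("closed_form", "monte_carlo"),
                                   draws = 1e5, seed = NULL) {
  trials <- check_trial_table(trials)
  keep <- eligible_trials(trials, cutoff, min_total_n)
  if (!any(keep)) stop("no eligible trials", call. = FALSE)
  eff <- trial_effects(trials[keep, , drop = FALSE], cutoff,
                       match.arg(method), draws, seed)
  list(effects = eff, pooled = pool_effects(eff))
}

#' Read a trial table from CSV
#'
#' @param path CSV file with columns `id`, `int_mean`, `int_sd`, `int_n`,
#'   `ctrl_mean`, `ctrl_sd`, `ctrl_n`.
#' @return A validated tibble.
#' @export
read_trials <- function(path) {
  check_trial_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
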