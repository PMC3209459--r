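# Discounted sector-level cost savings, NPV, break-even and returns.
#
# Costs accrue while a child is clinical: the expected annual cost in a
# sector is P(clinical at that age) times the sector's annual cost for
# that age band. Savings are the control-minus-intervention probability
# gap times cost, discounted to the intervention year.

#' Default age-banded sector cost table
#'
#' Average annual cost (GBP, 2008/09 prices) of services per person with
#' persistent conduct disorder, over and above a child without conduct
#' problems, by sector and inclusive age band. Education support costs
#' cease at 17+.
#'
#' @return A tibble with columns `sector`, `age_lo`, `age_hi`,
#'   `annual_cost`.
#' @export
sector_cost_bands <- function() {
  tibble::tibble(
    sector = rep(c("nhs", "social_services", "education", "voluntary"),
                 each = 3L),
    age_lo = rep(c(5, 11, 17), times = 4L),
    age_hi = rep(c(10, 16, Inf), times = 4L),
    annual_cost = c(1113, 101, 101,
                    157, 63, 63,
                    882, 1202, 0,
                    23, 23, 23)
  )
}

#' Sectors counted in the public-sector perspective
#'
#' NHS, social services, education and criminal justice; all other
#' streams (voluntary sector, crime victim costs, lost output, other
#' crime costs) accrue to wider society.
#'
#' @return Character vector of sector identifiers.
#' @export
public_sectors <- function() {
  c("nhs", "social_services", "education", "criminal_justice")
}

#' Crime cost components
#'
#' Component labels of the per-age crime-cost schedule. The criminal
#' justice component is a public-sector cost; the rest fall to wider
#' society.
#'
#' @return Character vector of component identifiers.
#' @export
crime_components <- function() {
  c("criminal_justice", "victim", "lost_output", "other")
}

#' Intervention cost specification
#'
#' Median per-participant costs of group-based and individually delivered
#' parenting programmes, and the share delivered in group format.
#'
#' @param group_median Median cost of group delivery (GBP, default 952).
#' @param individual_median Median cost of individual delivery (GBP,
#'   default 2078).
#' @param group_share Fraction delivered in group format (default 0.8).
#' @return An object of class `intervention_cost_spec`.
#' @examples
#' mixed_cost(intervention_cost_spec())  # 1177
#' @export
intervention_cost_spec <- function(group_median = 952,
                                   individual_median = 2078,
                                   group_share = 0.8) {
  assert_scalar_number(group_median, "group_median", lower = 0)
  assert_scalar_number(individual_median, "individual_median", lower = 0)
  assert_fraction(group_share, "group_share")
  structure(list(group_median = group_median,
                 individual_median = individual_median,
                 group_share = group_share),
            class = "intervention_cost_spec")
}

#' Expected per-participant intervention cost for a provision mix
#'
#' Weighted average of the group and individual median costs, rounded to
#' whole GBP (the convention for all reported cost figures).
#'
#' @param spec An [intervention_cost_spec()].
#' @param group_share Optional override of the specification's group
#'   share (e.g. 1 for group-only provision).
#' @return Cost in GBP.
#' @export
mixed_cost <- function(spec = intervention_cost_spec(), group_share = NULL) {
  stopifnot(inherits(spec, "intervention_cost_spec"))
  s <- if (is.null(group_share)) spec$group_share else group_share
  assert_fraction(s, "group_share")
  round(s * spec$group_median + (1 - s) * spec$individual_median)
}

#' Discounting specification
#'
#' Annual discount rate with the convention that the intervention year is
#' period 0 and is undiscounted.
#'
#' @param rate Annual discount rate (default 0.035).
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(rate = 0.035) {
  assert_scalar_number(rate, "rate", lower = 0)
  structure(list(rate = rate), class = "discount_spec")
}

#' Discount factor for a year offset
#'
#' @param spec A [discount_spec()].
#' @param k Years after the intervention year (`>= 0`, vectorised).
#' @return `(1 + rate)^(-k)`.
#' @export
discount_factor <- function(spec = discount_spec(), k) {
  stopifnot(inherits(spec, "discount_spec"))
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  (1 + spec$rate)^(-k)
}

check_crime_schedule <- function(crime) {
  crime <- tibble::as_tibble(crime)
  needed <- c("age", "component", "cost_gbp")
  if (!all(needed %in% names(crime))) {
    stop("crime schedule must have columns age, component, cost_gbp",
         call. = FALSE)
  }
  if (any(crime$cost_gbp < 0)) {
    stop("crime costs must be >= 0", call. = FALSE)
  }
  unknown <- setdiff(unique(crime$component), crime_components())
  if (length(unknown) > 0L) {
    stop("unknown crime components: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  crime
}

check_aligned <- function(control, intervention) {
  stopifnot(inherits(control, "cd_trajectory"),
            inherits(intervention, "cd_trajectory"))
  if (!identical(control$age, intervention$age) ||
      !identical(attr(control, "start_age"), attr(intervention, "start_age"))) {
    stop("control and intervention trajectories must share the same ages ",
         "and start age", call. = FALSE)
  }
  invisible(TRUE)
}

# Long table of per-age, per-sector costs given clinical status. Service
# sectors come from the band table; crime components contribute at the
# ages present in the schedule (zero elsewhere).
sector_costs_by_age <- function(ages, bands, crime) {
  bands <- tibble::as_tibble(bands)
  rows <- lapply(unique(bands$sector), function(s) {
    b <- bands[bands$sector == s, , drop = FALSE]
    cost <- vapply(ages, function(a) {
      hit <- which(b$age_lo <= a & a <= b$age_hi)
      if (length(hit) == 0L) 0 else b$annual_cost[hit[1L]]
    }, numeric(1))
    tibble::tibble(age = ages, sector = s, cost_gbp = cost)
  })
  out <- do.call(rbind, rows)
  if (!is.null(crime)) {
    crime <- check_crime_schedule(crime)
    for (comp in unique(crime$component)) {
      cc <- crime[crime$component == comp, , drop = FALSE]
      cost <- vapply(ages, function(a) {
        hit <- which(cc$age == a)
        if (length(hit) == 0L) 0 else sum(cc$cost_gbp[hit])
      }, numeric(1))
      out <- rbind(out, tibble::tibble(age = ages, sector = comp,
                                       cost_gbp = cost))
    }
  }
  out
}

#' Annual savings streams from an intervention
#'
#' Long table of per-year, per-sector savings: the control-minus-
#' intervention probability gap times the sector's annual cost at that
#' age, nominal and discounted to the intervention year.
#'
#' @param control,intervention Aligned `cd_trajectory` objects.
#' @param bands Sector cost bands, as [sector_cost_bands()].
#' @param crime Crime cost schedule (columns `age`, `component`,
#'   `cost_gbp`) or `NULL` for none.
#' @param discount A [discount_spec()].
#' @return A tibble with columns `age`, `k`, `sector`, `cost_gbp`, `gap`,
#'   `saving_gbp`, `discounted_gbp`.
#' @export
savings_streams <- function(control, intervention,
                            bands = sector_cost_bands(), crime = NULL,
                            discount = discount_spec()) {
  check_aligned(control, intervention)
  start_age <- attr(control, "start_age")
  gap <- control$p_clinical - intervention$p_clinical
  costs <- sector_costs_by_age(control$age, bands, crime)
  idx <- match(costs$age, control$age)
  costs$k <- costs$age - start_age
  costs$gap <- gap[idx]
  costs$saving_gbp <- costs$gap * costs$cost_gbp
  costs$discounted_gbp <- costs$saving_gbp * discount_factor(discount, costs$k)
  costs[, c("age", "k", "sector", "cost_gbp", "gap", "saving_gbp",
            "discounted_gbp")]
}

#' Present value of savings by sector
#'
#' Sums discounted annual savings per sector over the model horizon.
#'
#' @inheritParams savings_streams
#' @param horizon Number of years after the intervention to include
#'   (default: the full trajectory).
#' @return A tibble with columns `sector`, `pv_gbp`.
#' @examples
#' course <- natural_course()
#' ctrl <- natural_trajectory(course)
#' int <- intervention_trajectory(course, scenario_params(0.44, 0.34, 0.5))
#' pv_savings(ctrl, int)
#' @export
pv_savings <- function(control, intervention, bands = sector_cost_bands(),
                       crime = NULL, discount = discount_spec(),
                       horizon = NULL) {
  streams <- savings_streams(control, intervention, bands, crime, discount)
  if (!is.null(horizon)) {
    if (horizon > max(streams$k)) {
      stop("`horizon` exceeds the trajectory length", call. = FALSE)
    }
    streams <- streams[streams$k <= horizon, , drop = FALSE]
  }
  pv <- tapply(streams$discounted_gbp, streams$sector, sum)
  out <- tibble::tibble(sector = names(pv), pv_gbp = as.numeric(pv))
  # stable, report-friendly ordering: public sectors first
  ord <- c(public_sectors(), "voluntary", "lost_output", "victim", "other")
  out[order(match(out$sector, ord)), , drop = FALSE]
}

#' Savings report: totals, NPVs and return multiples
#'
#' Assembles the headline economics from per-sector present-value savings
#' and an intervention cost specification: public-sector, other-sector and
#' grand totals; net present value per provision mix (group only, the
#' spec's mixed share, individual only) from both perspectives; and return
#' multiples (gross savings over intervention cost) at the group and
#' individual cost bounds. The public return uses public-sector savings;
#' the societal return uses other-sector savings.
#'
#' Printed table totals may be passed through `public_total` /
#' `other_total` to reproduce published arithmetic exactly when the
#' per-sector rows carry independent rounding.
#'
#' @param sector_pv Tibble with columns `sector`, `pv_gbp` (or a named
#'   numeric vector).
#' @param cost_spec An [intervention_cost_spec()].
#' @param public_total,other_total Optional overrides of the totals
#'   computed from `sector_pv`.
#' @return An object of class `savings_report`: a list with `sector_pv`
#'   (with `pct_of_total`), `public_total`, `other_total`, `grand_total`,
#'   `npv` (per provision mix) and `returns` (per perspective).
#' @export
savings_report <- function(sector_pv, cost_spec = intervention_cost_spec(),
                           public_total = NULL, other_total = NULL) {
  if (!is.data.frame(sector_pv)) {
    sector_pv <- tibble::tibble(sector = names(sector_pv),
                                pv_gbp = as.numeric(sector_pv))
  }
  stopifnot(inherits(cost_spec, "intervention_cost_spec"))
  is_public <- sector_pv$sector %in% public_sectors()
  if (is.null(public_total)) public_total <- sum(sector_pv$pv_gbp[is_public])
  if (is.null(other_total)) other_total <- sum(sector_pv$pv_gbp[!is_public])
  grand_total <- public_total + other_total
  sector_pv$pct_of_total <- if (grand_total > 0) {
    sector_pv$pv_gbp / grand_total
  } else {
    rep(NA_real_, nrow(sector_pv))
  }

  costs <- c(group_only = mixed_cost(cost_spec, group_share = 1),
             mixed = mixed_cost(cost_spec),
             individual_only = mixed_cost(cost_spec, group_share = 0))
  npv <- tibble::tibble(
    provision = names(costs),
    group_share = c(1, cost_spec$group_share, 0),
    cost_gbp = as.numeric(costs),
    npv_public_gbp = public_total - as.numeric(costs),
    npv_society_gbp = grand_total - as.numeric(costs)
  )
  returns <- tibble::tibble(
    perspective = c("public", "society"),
    savings_gbp = c(public_total, other_total),
    multiple_low = c(public_total, other_total) / costs[["individual_only"]],
    multiple_high = c(public_total, other_total) / costs[["group_only"]]
  )
  structure(list(sector_pv = sector_pv, public_total = public_total,
                 other_total = other_total, grand_total = grand_total,
                 npv = npv, returns = returns, cost_spec = cost_spec),
            class = "savings_report")
}

#' @export
print.savings_report <- function(x, ...) {
  cat("Present value of savings per family\n")
  df <- x$sector_pv
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-16s £%s (%s%%)\n", df$sector[i],
                format(round(df$pv_gbp[i]), big.mark = ","),
                round(100 * df$pct_of_total[i])))
  }
  cat(sprintf("  public total   £%s\n",
              format(round(x$public_total), big.mark = ",")))
  cat(sprintf("  other total    £%s\n",
              format(round(x$other_total), big.mark = ",")))
  cat(sprintf("  grand total    £%s\n",
              format(round(x$grand_total), big.mark = ",")))
  cat("NPV by provision mix (public; society)\n")
  for (i in seq_len(nrow(x$npv))) {
    cat(sprintf("  %-16s cost £%s: £%s; £%s\n",
                x$npv$provision[i],
                format(x$npv$cost_gbp[i], big.mark = ","),
                format(round(x$npv$npv_public_gbp[i]), big.mark = ","),
                format(round(x$npv$npv_society_gbp[i]), big.mark = ",")))
  }
  cat(sprintf("Return multiples: public %.1f-%.1f, society %.1f-%.1f\n",
              x$returns$multiple_low[1], x$returns$multiple_high[1],
              x$returns$multiple_low[2], x$returns$multiple_high[2]))
  invisible(x)
}

#' First year in which cumulative discounted savings cover the cost
#'
#' @param annual_savings Numeric vector of nominal (undiscounted) savings;
#'   element `j` is the saving in year `j` after the intervention.
#' @param discount A [discount_spec()].
#' @param cost Up-front intervention cost (GBP, `>= 0`), incurred in year
#'   0.
#' @return The smallest year `k` with cumulative discounted savings
#'   `>= cost` (0 if `cost` is 0), or `NA` if the cost is never recovered
#'   within the stream's horizon.
#' @examples
#' break_even_year(rep(100, 10), discount_spec(rate = 0), cost = 250)  # 3
#' @export
break_even_year <- function(annual_savings, discount = discount_spec(),
                            cost) {
  if (length(annual_savings) == 0L) {
    stop("`annual_savings` must be non-empty", call. = FALSE)
  }
  if (!is.numeric(cost) || length(cost) != 1L || cost < 0) {
    stop("`cost` must be a single number >= 0", call. = FALSE)
  }
  if (cost == 0) return(0L)
  k <- seq_along(annual_savings)
  cum <- cumsum(annual_savings * discount_factor(discount, k))
  hit <- which(cum >= cost)
  if (length(hit) == 0L) NA_integer_ else as.integer(hit[1L])
}
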