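# Pipeline orchestration: scenario definitions, configuration,
# end-to-end runs, sensitivity grids and CSV reports.

#' Default scenario set
#'
#' The base, best and worst parameter triples of the sensitivity analysis:
#' drop-out 44/6/60%, effectiveness 34/68/20%, recidivism 50/0/50%.
#'
#' @return Named list of [scenario_params()] objects.
#' @export
scenario_set <- function() {
  list(
    base = scenario_params(dropout = 0.44, effectiveness = 0.34,
                           recidivism = 0.50),
    best = scenario_params(dropout = 0.06, effectiveness = 0.68,
                           recidivism = 0.00),
    worst = scenario_params(dropout = 0.60, effectiveness = 0.20,
                            recidivism = 0.50)
  )
}

#' Default run configuration
#'
#' All model defaults in one list: a 5-year-old cohort followed for 25
#' annual periods, the published persistence anchors, 3.5% discounting,
#' the published cost bands and intervention cost mix, the three-scenario
#' sensitivity set, and a synthetic crime schedule calibrated so the
#' base-case crime-component present values equal the published rows.
#'
#' @param seed Integer seed for the synthetic crime schedule (default 1).
#' @return A named list usable by [run_scenario()] and
#'   [sensitivity_grid()].
#' @export
default_config <- function(seed = 1L) {
  list(
    start_age = 5L,
    horizon = 25L,
    discount_rate = 0.035,
    anchors = default_anchors(),
    cost_bands = sector_cost_bands(),
    cost_spec = intervention_cost_spec(),
    scenarios = scenario_set(),
    provision_mixes = c(1.0, 0.8, 0.0),
    crime = list(
      schedule_csv = NULL,          # path to a ready-made schedule, or NULL
      calibrate = TRUE,             # rescale to `targets` under the base case
      targets = as.list(crime_pv_targets()),
      peak_age = 18,
      scale = 60000,
      noise_sd = 0.1
    ),
    seed = as.integer(seed)
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a config list with defaults filled in for
#'   any field not present in the file.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) {
    cfg[[nm]] <- switch(
      nm,
      anchors = tibble::as_tibble(as.data.frame(raw$anchors)),
      cost_bands = {
        cb <- tibble::as_tibble(as.data.frame(raw$cost_bands))
        cb$age_hi[is.na(cb$age_hi)] <- Inf
        cb
      },
      cost_spec = do.call(intervention_cost_spec, raw$cost_spec),
      scenarios = lapply(raw$scenarios, function(s)
        do.call(scenario_params, s)),
      crime = {
        cr <- utils::modifyList(cfg$crime, raw$crime)
        # modifyList drops NULL-valued fields; a missing schedule path
        # means "generate synthetically"
        if (!"schedule_csv" %in% names(cr)) {
          cr <- c(list(schedule_csv = NULL), cr)
        }
        cr
      },
      raw[[nm]]
    )
  }
  cfg
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  ser <- config
  ser$anchors <- as.list(as.data.frame(config$anchors))
  cb <- as.data.frame(config$cost_bands)
  cb$age_hi[is.infinite(cb$age_hi)] <- NA  # YAML-safe; read_config restores Inf
  ser$cost_bands <- as.list(cb)
  ser$cost_spec <- unclass(config$cost_spec)
  ser$scenarios <- lapply(config$scenarios, unclass)
  yaml::write_yaml(ser, path)
  invisible(config)
}

# Resolve the crime schedule for a config: load from CSV if given,
# otherwise generate; optionally calibrate against the base-case
# trajectory pair so the published PV rows are matched.
resolve_crime_schedule <- function(config, course) {
  crime <- if (!is.null(config$crime$schedule_csv)) {
    read_crime_schedule(config$crime$schedule_csv)
  } else {
    gen_crime_schedule(peak_age = config$crime$peak_age,
                       scale = config$crime$scale,
                       noise_sd = config$crime$noise_sd,
                       seed = config$seed)
  }
  if (isTRUE(config$crime$calibrate)) {
    ctrl <- natural_trajectory(course, config$start_age, config$horizon)
    int <- intervention_trajectory(course, config$scenarios$base,
                                   config$start_age, config$horizon)
    crime <- calibrate_to_pv(crime, ctrl, int,
                             discount_spec(config$discount_rate),
                             targets = unlist(config$crime$targets))
  }
  crime
}

run_one <- function(config, params, course, crime, cost_spec) {
  discount <- discount_spec(config$discount_rate)
  ctrl <- natural_trajectory(course, config$start_age, config$horizon)
  int <- intervention_trajectory(course, params, config$start_age,
                                 config$horizon)
  streams <- savings_streams(ctrl, int, config$cost_bands, crime, discount)
  sector_pv <- pv_savings(ctrl, int, config$cost_bands, crime, discount)
  report <- savings_report(sector_pv, cost_spec)

  pub <- streams[streams$sector %in% public_sectors() & streams$k >= 1, ,
                 drop = FALSE]
  public_stream <- as.numeric(tapply(pub$saving_gbp, pub$k, sum))
  break_even <- tibble::tibble(
    provision = c("group_only", "mixed", "individual_only"),
    group_share = c(1, cost_spec$group_share, 0),
    cost_gbp = c(mixed_cost(cost_spec, 1), mixed_cost(cost_spec),
                 mixed_cost(cost_spec, 0)),
    years = vapply(c(1, cost_spec$group_share, 0), function(s)
      break_even_year(public_stream, discount, mixed_cost(cost_spec, s)),
      integer(1))
  )
  list(params = params,
       trajectories = tibble::tibble(
         age = ctrl$age,
         p_clinical_control = ctrl$p_clinical,
         p_clinical_intervention = int$p_clinical),
       control = ctrl, intervention = int,
       streams = streams, sector_pv = sector_pv, report = report,
       break_even = break_even,
       persistence_pct = truncate_pct(persistence_beyond(int)),
       persistence_pct_control = truncate_pct(persistence_beyond(ctrl)))
}

#' Run a named scenario end to end
#'
#' Builds the natural and intervention trajectories for the named
#' scenario, resolves (and, by default, calibrates) the crime-cost
#' schedule, computes per-sector present-value savings, the savings
#' report and break-even years, and optionally writes CSV reports.
#' Deterministic given the configuration.
#'
#' @param config A configuration list as from [default_config()] or
#'   [read_config()].
#' @param name Scenario name present in `config$scenarios` (default
#'   `"base"`).
#' @param out_dir Optional directory for `trajectories.csv`,
#'   `sector_savings.csv` and `scenario_summary.csv`.
#' @return An object of class `cd_run`: a list with `trajectories`,
#'   `sector_pv`, `report`, `break_even`, `persistence_pct` and the
#'   underlying streams.
#' @examples
#' run <- run_scenario(default_config(), "base")
#' run$persistence_pct  # 54
#' @export
run_scenario <- function(config = default_config(), name = "base",
                         out_dir = NULL) {
  if (!name %in% names(config$scenarios)) {
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(names(config$scenarios), collapse = ", ")),
         call. = FALSE)
  }
  course <- natural_course(config$anchors)
  crime <- resolve_crime_schedule(config, course)
  out <- run_one(config, config$scenarios[[name]], course, crime,
                 config$cost_spec)
  out$scenario <- name
  out$crime <- crime
  class(out) <- "cd_run"
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.cd_run <- function(x, ...) {
  cat(sprintf("Scenario '%s': persistence beyond age 16 = %d%% (control %d%%)\n",
              x$scenario, x$persistence_pct, x$persistence_pct_control))
  print(x$report)
  cat("Years to break even (public sector):\n")
  for (i in seq_len(nrow(x$break_even))) {
    cat(sprintf("  %-16s %s\n", x$break_even$provision[i],
                ifelse(is.na(x$break_even$years[i]), "never within horizon",
                       x$break_even$years[i])))
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trajectories,
                   file.path(out_dir, "trajectories.csv"), row.names = FALSE)
  sect <- run$report$sector_pv
  sect$pv_gbp <- round(sect$pv_gbp)
  sect$pct_of_total <- round(100 * sect$pct_of_total)
  utils::write.csv(sect, file.path(out_dir, "sector_savings.csv"),
                   row.names = FALSE)
  summ <- run$report$npv
  summ$break_even_years <- run$break_even$years[
    match(summ$provision, run$break_even$provision)]
  summ$npv_public_gbp <- round(summ$npv_public_gbp)
  summ$npv_society_gbp <- round(summ$npv_society_gbp)
  utils::write.csv(summ, file.path(out_dir, "scenario_summary.csv"),
                   row.names = FALSE)
  invisible(run)
}

#' Deterministic sensitivity grid
#'
#' Runs the model over a grid of scenario parameters and provision mixes.
#' `grid` may be a data frame whose rows are parameter combinations
#' (columns among `dropout`, `effectiveness`, `recidivism`,
#' `group_share`), or a named list of value vectors that is expanded to
#' its cross-product. Omitted parameters take the base-case values.
#'
#' @param config A configuration list.
#' @param grid Data frame of combinations or named list of value vectors.
#' @return A tibble with one row per combination: the parameters, the
#'   persistence endpoint, savings totals, NPVs from both perspectives
#'   and the public-sector break-even year.
#' @examples
#' sensitivity_grid(default_config(), list(effectiveness = c(0.2, 0.34)))
#' @export
sensitivity_grid <- function(config = default_config(), grid) {
  if (is.data.frame(grid)) {
    combos <- grid
  } else {
    if (!is.list(grid) || length(grid) == 0L) {
      stop("`grid` must be a non-empty named list or a data frame",
           call. = FALSE)
    }
    combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  }
  allowed <- c("dropout", "effectiveness", "recidivism", "group_share")
  if (nrow(combos) == 0L || !all(names(combos) %in% allowed)) {
    stop("grid columns must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  base <- config$scenarios$base
  course <- natural_course(config$anchors)
  crime <- resolve_crime_schedule(config, course)
  discount <- discount_spec(config$discount_rate)

  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, , drop = FALSE]
    params <- scenario_params(
      dropout = if ("dropout" %in% names(cm)) cm$dropout else base$dropout,
      effectiveness = if ("effectiveness" %in% names(cm))
        cm$effectiveness else base$effectiveness,
      recidivism = if ("recidivism" %in% names(cm))
        cm$recidivism else base$recidivism)
    share <- if ("group_share" %in% names(cm)) cm$group_share else
      config$cost_spec$group_share
    res <- run_one(config, params, course, crime, config$cost_spec)
    cost <- mixed_cost(config$cost_spec, share)
    pub <- res$report$public_total
    tot <- res$report$grand_total
    stream <- res$streams[res$streams$sector %in% public_sectors() &
                            res$streams$k >= 1, , drop = FALSE]
    public_stream <- as.numeric(tapply(stream$saving_gbp, stream$k, sum))
    tibble::tibble(
      dropout = params$dropout, effectiveness = params$effectiveness,
      recidivism = params$recidivism, group_share = share,
      cost_gbp = cost, persistence_pct = res$persistence_pct,
      public_savings_gbp = pub, total_savings_gbp = tot,
      npv_public_gbp = pub - cost, npv_society_gbp = tot - cost,
      break_even_years = break_even_year(public_stream, discount, cost))
  })
  do.call(rbind, rows)
}

#' Plot control and intervention trajectories
#'
#' @param runs A named list of `cd_run` objects (e.g. one per scenario);
#'   the control trajectory is shared and drawn once.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(runs) {
  if (inherits(runs, "cd_run")) runs <- list(run = runs)
  ctrl <- runs[[1L]]$trajectories
  df <- do.call(rbind, lapply(names(runs), function(nm) {
    tibble::tibble(age = runs[[nm]]$trajectories$age,
                   p_clinical = runs[[nm]]$trajectories$p_clinical_intervention,
                   scenario = nm)
  }))
  df <- rbind(df, tibble::tibble(age = ctrl$age,
                                 p_clinical = ctrl$p_clinical_control,
                                 scenario = "no intervention"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$p_clinical,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Age (years)",
                  y = "P(clinical conduct disorder)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
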