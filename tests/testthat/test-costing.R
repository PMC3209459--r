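test_that("provision-mix cost reproduces the published weighting", {
  spec <- intervention_cost_spec()
  expect_identical(mixed_cost(spec), 1177)
  expect_identical(mixed_cost(spec, group_share = 1), 952)
  expect_identical(mixed_cost(spec, group_share = 0), 2078)
})

test_that("discount factors follow (1+r)^-k with an undiscounted intervention year", {
  expect_equal(discount_factor(discount_spec(0.035), 0), 1)
  expect_equal(discount_factor(discount_spec(0), 0:10), rep(1, 11))
  expect_equal(discount_factor(discount_spec(0.035), 2), 1 / 1.035^2)
  expect_error(discount_factor(discount_spec(0.035), -1), ">= 0")
})

toy_pair <- function(gap, years) {
  ages <- 5L + 0:years
  ctrl <- cdsavings:::new_trajectory(ages, rep(1, years + 1), 5L)
  int <- cdsavings:::new_trajectory(ages, c(1, rep(1 - gap, years)), 5L)
  list(ctrl = ctrl, int = int)
}

test_that("present-value savings match hand arithmetic on a toy single sector", {
  bands <- tibble::tibble(sector = "nhs", age_lo = 5, age_hi = Inf,
                          annual_cost = 100)
  tp <- toy_pair(gap = 0.1, years = 3)
  pv <- pv_savings(tp$ctrl, tp$int, bands, crime = NULL,
                   discount = discount_spec(0))
  expect_equal(pv$pv_gbp, 30)  # 3 years x 0.1 x 100

  # identical trajectories save nothing in any sector
  pair <- fixture_trajectory_pair("base")
  pv0 <- pv_savings(pair$control, pair$control, sector_cost_bands(),
                    gen_crime_schedule(seed = 1))
  expect_true(all(pv0$pv_gbp == 0))
})

test_that("PV equals the nominal sum at zero discounting and decreases with the rate", {
  pair <- fixture_trajectory_pair("base")
  crime <- gen_crime_schedule(seed = 2)
  streams0 <- savings_streams(pair$control, pair$intervention,
                              sector_cost_bands(), crime, discount_spec(0))
  pv0 <- pv_savings(pair$control, pair$intervention, sector_cost_bands(),
                    crime, discount_spec(0))
  expect_equal(sum(pv0$pv_gbp), sum(streams0$saving_gbp))
  rates <- c(0, 0.02, 0.035, 0.06)
  totals <- vapply(rates, function(r)
    sum(pv_savings(pair$control, pair$intervention, sector_cost_bands(),
                   crime, discount_spec(r))$pv_gbp), numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("misaligned trajectories are rejected", {
  pair <- fixture_trajectory_pair("base")
  short <- natural_trajectory(fixture_course(), 5L, 10L)
  expect_error(pv_savings(pair$control, short), "same ages")
})

test_that("savings report reproduces the published Table arithmetic from printed totals", {
  rep <- savings_report(table3_sector_pv(), intervention_cost_spec(),
                        public_total = 5837, other_total = 10598)
  expect_equal(rep$grand_total, 16435)
  npv <- rep$npv
  expect_equal(npv$npv_society_gbp[npv$provision == "mixed"], 15258)
  expect_equal(npv$npv_society_gbp[npv$provision == "group_only"], 15483)
  expect_equal(npv$npv_society_gbp[npv$provision == "individual_only"], 14357)
  expect_equal(npv$npv_public_gbp[npv$provision == "group_only"], 4885)
  expect_equal(npv$npv_public_gbp[npv$provision == "mixed"], 4660)
  expect_equal(npv$npv_public_gbp[npv$provision == "individual_only"], 3759)
  ret <- rep$returns
  expect_equal(round(ret$multiple_high[ret$perspective == "public"], 1), 6.1)
  expect_equal(round(ret$multiple_low[ret$perspective == "public"], 1), 2.8)
  expect_equal(round(ret$multiple_high[ret$perspective == "society"], 1), 11.1)
  expect_equal(round(ret$multiple_low[ret$perspective == "society"], 1), 5.1)
  # victim costs carry almost half of total savings
  victim_share <- rep$sector_pv$pct_of_total[rep$sector_pv$sector == "victim"]
  expect_equal(round(100 * victim_share), 45)
})

test_that("report totals and NPV identities hold exactly for computed sector PVs", {
  pair <- fixture_trajectory_pair("base")
  crime <- calibrate_to_pv(gen_crime_schedule(seed = 1), pair$control,
                           pair$intervention)
  pv <- pv_savings(pair$control, pair$intervention, sector_cost_bands(),
                   crime)
  rep <- savings_report(pv)
  expect_equal(rep$grand_total, rep$public_total + rep$other_total)
  expect_equal(rep$grand_total, sum(pv$pv_gbp))
  expect_equal(rep$npv$npv_society_gbp, rep$grand_total - rep$npv$cost_gbp)
  expect_equal(rep$npv$npv_public_gbp, rep$public_total - rep$npv$cost_gbp)
})

test_that("break-even year is the first cumulative crossing and is monotone in cost", {
  expect_identical(break_even_year(rep(100, 10), discount_spec(0), 250), 3L)
  expect_identical(break_even_year(rep(100, 10), discount_spec(0), 0), 0L)
  expect_true(is.na(break_even_year(rep(10, 5), discount_spec(0), 1000)))
  expect_error(break_even_year(numeric(0), discount_spec(0), 10),
               "non-empty")
  expect_error(break_even_year(rep(100, 5), discount_spec(0), -5), ">= 0")
  set.seed(11)
  for (i in 1:20) {
    stream <- runif(25, 0, 500)
    costs <- sort(runif(5, 0, 4000))
    yrs <- vapply(costs, function(cc)
      break_even_year(stream, discount_spec(0.035), cc), integer(1))
    yrs[is.na(yrs)] <- 999L  # treat 'never' as beyond any horizon
    expect_true(all(diff(yrs) >= 0))
  }
})
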