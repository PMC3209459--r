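test_that("natural-course interpolation matches the anchor geometry", {
  course <- fixture_course()
  expect_equal(proportion_at(course, 3), 1.00)
  expect_equal(proportion_at(course, 8), 0.60)
  # hand interpolation between (3, 1.00) and (8, 0.60)
  expect_equal(proportion_at(course, 5), 1.00 - 2 * (0.40 / 5))
  # constant beyond the last anchor
  expect_equal(proportion_at(course, c(16, 20, 30, 100)), rep(0.50, 4))
  expect_error(proportion_at(course, 2), "first anchor")
})

test_that("anchor validation rejects malformed curves", {
  expect_error(natural_course(tibble::tibble(age = 3, proportion = 1)),
               "two anchors")
  expect_error(natural_course(tibble::tibble(age = c(3, 3),
                                             proportion = c(1, 0.5))),
               "strictly increasing")
  expect_error(natural_course(tibble::tibble(age = c(3, 8),
                                             proportion = c(0.5, 0.9))),
               "non-increasing")
  expect_error(natural_course(tibble::tibble(age = c(3, 8),
                                             proportion = c(1.2, 0.5))),
               "\\[0, 1\\]")
})

test_that("conditional persistence is the ratio of curve proportions", {
  course <- fixture_course()
  expect_equal(conditional_persistence(course, 5, 16), 0.50 / 0.84)
  expect_equal(truncate_pct(conditional_persistence(course, 5, 16)), 59L)
  expect_equal(conditional_persistence(course, 9, 9), 1.0)
  expect_equal(conditional_persistence(course, 5, 8), 0.60 / 0.84)
  expect_error(conditional_persistence(course, 8, 5), ">=")
  zero_course <- natural_course(tibble::tibble(age = c(3, 8),
                                               proportion = c(1, 0)))
  expect_error(conditional_persistence(zero_course, 8, 10), "zero")
})

test_that("natural trajectory follows the conditional curve and is flat after the last anchor", {
  tr <- natural_trajectory(fixture_course(), 5L, 25L)
  expect_equal(nrow(tr), 26L)
  expect_equal(tr$p_clinical[tr$age == 5], 1.0)
  expect_equal(tr$p_clinical[tr$age == 6], 0.76 / 0.84)
  expect_equal(tr$p_clinical[tr$age == 30], 0.50 / 0.84)
  expect_true(all(diff(tr$p_clinical) <= 1e-12))
  expect_true(all(tr$p_clinical >= 0 & tr$p_clinical <= 1))
})

test_that("intervention endpoints reproduce the hand-arithmetic chain for all three scenarios", {
  course <- fixture_course()
  for (nm in c("base", "best", "worst")) {
    p <- fixture_params(nm)
    tr <- intervention_trajectory(course, p)
    expect_equal(persistence_beyond(tr),
                 hand_endpoint(p$dropout, p$effectiveness, p$recidivism),
                 tolerance = 1e-12, label = nm)
  }
  # published truncated percentages for base and worst
  expect_identical(truncate_pct(persistence_beyond(
    intervention_trajectory(course, fixture_params("base")))), 54L)
  expect_identical(truncate_pct(persistence_beyond(
    intervention_trajectory(course, fixture_params("worst")))), 57L)
})

test_that("no-effect and full-dropout scenarios reduce to the natural course", {
  course <- fixture_course()
  ctrl <- natural_trajectory(course)
  for (p in list(scenario_params(0.44, 0, 0.5), scenario_params(1, 0.34, 0.5))) {
    tr <- intervention_trajectory(course, p)
    expect_equal(tr$p_clinical, ctrl$p_clinical, tolerance = 1e-12)
  }
})

test_that("full recidivism restores the natural course from the second post-intervention year", {
  course <- fixture_course()
  ctrl <- natural_trajectory(course)
  tr <- intervention_trajectory(course, scenario_params(0.44, 0.34, 1.0))
  from_7 <- ctrl$age >= 7
  expect_equal(tr$p_clinical[from_7], ctrl$p_clinical[from_7],
               tolerance = 1e-12)
  expect_lt(tr$p_clinical[tr$age == 6], ctrl$p_clinical[ctrl$age == 6])
})

test_that("intervention trajectories are bounded, dominated by the natural course, and monotone where reversion cannot overshoot", {
  course <- fixture_course()
  ctrl <- natural_trajectory(course)
  set.seed(42)
  for (i in 1:50) {
    d <- runif(1); e <- runif(1); rho <- runif(1)
    tr <- intervention_trajectory(course, scenario_params(d, e, rho))
    expect_true(all(tr$p_clinical >= 0 & tr$p_clinical <= 1))
    expect_true(all(tr$p_clinical <= ctrl$p_clinical + 1e-12))
    # monotone whenever reverters do not outnumber natural resolution
    p1 <- conditional_persistence(course, 5, 6)
    c1 <- (1 - d) * p1 * (1 - e) + d * p1
    q <- conditional_persistence(course, 6, 7)
    if (rho * (p1 - c1) <= c1 * (1 - q)) {
      expect_true(all(diff(tr$p_clinical) <= 1e-12))
    }
  }
})

test_that("scenario parameters are validated", {
  expect_error(scenario_params(-0.1, 0.3, 0.5), "dropout")
  expect_error(scenario_params(0.4, 1.3, 0.5), "effectiveness")
  expect_error(scenario_params(0.4, 0.3, NA), "recidivism")
})
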