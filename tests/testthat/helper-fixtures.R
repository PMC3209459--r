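# Shared fixtures: the published model inputs, rebuilt in code.

fixture_course <- function() natural_course()

fixture_params <- function(name = c("base", "best", "worst")) {
  scenario_set()[[match.arg(name)]]
}

# Independent hand-arithmetic chain for the intervention endpoint,
# coded directly from the anchor geometry (does not call the package's
# trajectory machinery).
hand_endpoint <- function(d, e, rho) {
  prop <- function(a) { # anchors (3,1), (8,.6), (16,.5), flat after
    if (a <= 8) 1 - (a - 3) * (0.4 / 5)
    else if (a <= 16) 0.6 - (a - 8) * (0.1 / 8)
    else 0.5
  }
  p1 <- prop(6) / prop(5)
  c1 <- (1 - d) * p1 * (1 - e) + d * p1
  q <- prop(7) / prop(6)
  c2 <- min(c1 * q + rho * (p1 - c1), p1 * q)
  c2 * (prop(16) / prop(7))
}

# Table 3 sector rows (GBP), used where tests exercise published
# report arithmetic.
table3_sector_pv <- function() {
  c(nhs = 2195, social_services = 109, education = 690,
    criminal_justice = 2842, voluntary = 27, lost_output = 2197,
    victim = 7468, other = 906)
}

fixture_trajectory_pair <- function(name = "base", horizon = 25L) {
  course <- fixture_course()
  list(control = natural_trajectory(course, 5L, horizon),
       intervention = intervention_trajectory(course, fixture_params(name),
                                              5L, horizon))
}
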