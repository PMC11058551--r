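# Shared scenario builders for the test suite. The worked example itself
# comes from activity_mortality_scenario(); these are smaller or degenerate
# variants used to exercise properties cheaply.

small_scenario <- function(n = 500, alpha = 0.05) {
  activity_mortality_scenario(n = n, alpha = alpha)
}

# Exponential (gamma = 1) variant of the worked example.
exponential_scenario <- function(n = 5000) {
  scenario(
    confounder = confounder_model(0.6),
    exposure   = exposure_model(0.5, log(1 / 3)),
    outcome    = weibull_outcome(log(7 / 1000), log(0.8), log(4), 1),
    followup   = followup_design(10),
    n = n
  )
}

# High-rate scenario: most subjects die, useful for boundary behaviour.
high_rate_scenario <- function(n = 500, gamma = 1.4) {
  scenario(
    confounder = confounder_model(0.3),
    exposure   = exposure_model(0.4, 0.5),
    outcome    = weibull_outcome(log(0.15), log(1.5), 0.7, gamma),
    followup   = followup_design(8),
    n = n
  )
}
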