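# Shared fixtures: small deterministic signals and simulated recordings.

fixture_sine <- function(f = 0.25, fs = 10, dur = 120, amp = 1, offset = 0) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  signal_segment(offset + amp * sin(2 * pi * f * t), fs, label = "resp")
}

# AR(2) resonator respiration like the simulator's
fixture_resonator <- function(n, f0 = 0.25, bw = 0.05, fs = 4) {
  theta <- 2 * pi * f0 / fs
  rho <- 1 - pi * bw / fs
  y <- as.numeric(stats::filter(rnorm(n + 200), c(2 * rho * cos(theta), -rho^2),
                                method = "recursive"))[(201):(n + 200)]
  y / sd(y)
}

# one constant-state recording (labels all `state`), short
fixture_recording <- function(state = "S4_NA", minutes = 10, seed = 11,
                              group = "healthy") {
  cfg <- sim_config(duration_s = minutes * 60, seed = seed)
  lab <- factor(rep(state, minutes * 2), levels = cap_stage_levels())
  rec <- simulate_cardioresp(lab, group_profile(group), cfg)
  rec$labels <- lab
  rec
}

expect_no_nan <- function(x) {
  expect_false(any(vapply(x, function(v) any(is.nan(v)), logical(1))))
}
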