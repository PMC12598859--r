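# Shared oracles and small scenario fixtures for the unit tests.

# Central-difference force oracle: numerically differentiate a scalar energy
# function of a state.  With h = 1e-6 the truncation + roundoff error is well
# below 1e-6 in absolute force units for WCA-scale potentials.
num_force <- function(energy_fn, state, h = 1e-6) {
  n <- length(state$x)
  F <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    for (d in 1:2) {
      sp <- state
      sm <- state
      if (d == 1L) {
        sp$x[i] <- sp$x[i] + h
        sm$x[i] <- sm$x[i] - h
      } else {
        sp$y[i] <- sp$y[i] + h
        sm$y[i] <- sm$y[i] - h
      }
      F[i, d] <- -(energy_fn(sp) - energy_fn(sm)) / (2 * h)
    }
  }
  F
}

# Closed-form WCA pair energy/force magnitude for a single separation r
wca_energy <- function(r) ifelse(r < 2^(1 / 6), 4 * (r^-12 - r^-6) + 1, 0)
wca_fmag <- function(r) ifelse(r < 2^(1 / 6), 48 * r^-13 - 24 * r^-7, 0)

# Small scenarios for fast unit tests (never used for acceptance statistics)
small_channel <- function(overrides = list()) {
  make_scenario("channel", utils::modifyList(
    list(box_lengths = c(16, 10), width = 6, amplitude = 1.5), overrides))
}
small_obstacle <- function(overrides = list()) {
  make_scenario("obstacle", utils::modifyList(
    list(box_lengths = c(12, 12), R = 2), overrides))
}
small_active <- function(overrides = list()) {
  make_scenario("active", utils::modifyList(
    list(box_lengths = c(8, 8)), overrides))
}

# One equilibrated starting configuration for a spec (short chain; unit tests
# only need a physically sensible state, not deep decorrelation).
equilibrated_state <- function(spec, seed = 1, burn_in = 5) {
  equilibrate(spec, 1, spacing = 1, burn_in = burn_in, seed = seed,
              cfg = integrator_config(dt = 0.005))[[1]]
}

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
sample_excess_kurtosis <- function(x) mean((x - mean(x))^4) / sd(x)^4 - 3
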