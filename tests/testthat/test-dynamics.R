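test_that("integrator_config validates its inputs", {
  expect_equal(integrator_config()$dt, 0.002)
  expect_error(integrator_config(dt = 0.02), "dt")
  expect_error(integrator_config(dt = 0), "dt")
  expect_error(integrator_config(constraint_tolerance = -1), "positive")
})

test_that("thermostat multipliers make the constrained quantity stationary", {
  set.seed(3)
  p <- matrix(rnorm(20), 10, 2)
  f <- matrix(rnorm(20), 10, 2)
  a <- isokinetic_alpha(p, f)
  # d(sum p^2)/dt = 2 sum p.(f - a p) = 0
  expect_lt(abs(sum(p * (f - a * p))), 1e-12)
  expect_error(isokinetic_alpha(matrix(0, 2, 2), f[1:2, ]), "zero kinetic")

  st <- sim_state(x = runif(10), y = runif(10), px = rnorm(10), py = rnorm(10),
                  c = rep(c(1L, -1L), 5))
  a2 <- ergostat_alpha(st, 0.3)
  expect_equal(a2, sum(st$c * 0.3 * st$px) / sum(st$px^2 + st$py^2))
})

test_that("ou_update is the exact OU propagator", {
  # dt = 0 is the identity
  xi <- rnorm(5)
  expect_equal(ou_update(xi, tau = 0.1, sigma_noise = 0.1, dt = 0), xi)
  expect_error(ou_update(xi, tau = 0, sigma_noise = 0.1, dt = 0.01), "tau")
  # stationary distribution N(0, sigma^2) and one-step autocorrelation
  # e^(-dt/tau), independent of dt
  set.seed(9)
  n <- 2e5
  x0 <- rnorm(n, 0, 0.1)
  x1 <- ou_update(x0, tau = 0.1, sigma_noise = 0.1, dt = 0.05)
  expect_lt(abs(sd(x1) - 0.1), 0.002)
  expect_lt(abs(mean(x1)), 0.002)
  expect_lt(abs(cor(x0, x1) - exp(-0.5)), 0.01)
})

test_that("step() equals a one-step run_trajectory and is seed-deterministic", {
  sp <- small_active()
  st <- equilibrated_state(sp, seed = 2)
  cfg <- integrator_config()
  s1 <- step(st, sp, cfg, seed = 5)
  s2 <- run_trajectory(st, sp, duration = cfg$dt, cfg = cfg,
                       seed = 5)$final_state
  expect_equal(s1, s2)
  # same seed reproduces, different seed gives a different noise stream
  s3 <- step(st, sp, cfg, seed = 5)
  expect_identical(s1$px, s3$px)
  s4 <- step(st, sp, cfg, seed = 6)
  expect_false(identical(s1$px, s4$px))
})

test_that("run_trajectory conserves the constrained quantity and records series", {
  sp <- small_channel()
  st <- equilibrated_state(sp, seed = 1)
  rec <- run_trajectory(st, sp, duration = 1, seed = 1)
  expect_s3_class(rec, "trajectory_record")
  expect_lte(rec$max_constraint_drift, 1e-10)
  # wall kinetic energy series is flat
  expect_lt(diff(range(rec$K_constrained)) / rec$K_constrained[1], 1e-10)
  expect_equal(length(rec$J_fine), as.integer(round(16 / 0.1)))
  expect_equal(rec$final_state$time, st$time + 1)

  spa <- small_active()
  sta <- equilibrated_state(spa, seed = 1)
  reca <- run_trajectory(sta, spa, duration = 0.5, seed = 1)
  expect_lte(reca$max_constraint_drift, 1e-10)

  spo <- small_obstacle()
  sto <- equilibrated_state(spo, seed = 1)
  reco <- run_trajectory(sto, spo, duration = 0.5, seed = 1)
  expect_lt(max(abs(reco$H - reco$H[1])) / abs(reco$H[1]), 1e-9)
})

test_that("run_trajectory rejects bad durations and handles zero steps", {
  sp <- small_active()
  st <- make_initial_state(sp, seed = 1)
  expect_error(run_trajectory(st, sp, duration = 0.0031), "multiple of dt")
  rec0 <- run_trajectory(st, sp, duration = 0)
  expect_equal(rec0$duration, 0)
  expect_equal(rec0$J_global, 0)
  expect_equal(rec0$max_constraint_drift, 0)
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  sp <- small_active()
  st <- equilibrated_state(sp, seed = 4)
  r1 <- run_trajectory(st, sp, duration = 0.2, seed = 10)
  r2 <- run_trajectory(st, sp, duration = 0.2, seed = 10)
  expect_identical(r1$J_fine, r2$J_fine)
  expect_identical(r1$final_state$x, r2$final_state$x)
  r3 <- run_trajectory(st, sp, duration = 0.2, seed = 11)
  expect_false(identical(r1$final_state$x, r3$final_state$x))
})

test_that("equilibrate returns decorrelated equilibrium configurations", {
  sp <- small_active()
  out <- equilibrate(sp, 4, spacing = 1, burn_in = 5, seed = 6,
                     cfg = integrator_config(dt = 0.005))
  expect_length(out, 4)
  expect_s3_class(out[[1]], "sim_state")
  expect_true(all(vapply(out, function(s) s$time, 1) == 0))
  expect_length(attr(out, "potential_energy"), 4)
  # configurations differ between samples
  expect_false(identical(out[[1]]$x, out[[2]]$x))
  # deterministic in the seed
  out2 <- equilibrate(sp, 4, spacing = 1, burn_in = 5, seed = 6,
                      cfg = integrator_config(dt = 0.005))
  expect_identical(out[[1]]$x, out2[[1]]$x)
  # pooled momenta are at temperature ~1 and propulsions at ~sigma
  pp <- unlist(lapply(out, function(s) c(s$px, s$py)))
  expect_lt(abs(mean(pp^2) - 1), 0.2)
  xi <- unlist(lapply(out, function(s) s$xi))
  expect_lt(abs(sd(xi) - sp$params$ou_amplitude), 0.05)
})
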