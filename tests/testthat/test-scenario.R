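test_that("make_scenario builds the three documented model systems", {
  ch <- make_scenario("channel")
  expect_s3_class(ch, "scenario_spec")
  expect_equal(ch$params$field_strength, 0.3)
  expect_equal(ch$params$box_lengths, c(50.6, 14))
  expect_identical(ch$thermostat_scope, "walls_only")
  expect_false(ch$activity_enabled)
  expect_equal(ch$default_duration, 5)

  ob <- make_scenario("obstacle")
  expect_equal(ob$geometry$R, 5)
  expect_equal(ob$params$box_lengths, c(26, 26))
  expect_identical(ob$thermostat_scope, "all_fluid")

  ac <- make_scenario("active")
  expect_equal(ac$params$field_strength, 0.05)
  expect_equal(ac$params$ou_amplitude, 2 * ac$params$field_strength)
  expect_equal(ac$params$ou_relaxation, 0.1)
  expect_true(ac$activity_enabled)
  expect_equal(ac$default_duration, 3)
  # density 0.5 in a 22 x 22 box
  expect_equal(ac$n_fluid, round(0.5 * 22 * 22))
})

test_that("overrides are applied and unknown fields rejected", {
  sp <- make_scenario("channel", list(field_strength = 0.1, width = 7))
  expect_equal(sp$params$field_strength, 0.1)
  expect_equal(sp$geometry$width, 7)
  sp <- make_scenario("obstacle", list(density = 0.4))
  expect_equal(sp$density, 0.4)
  expect_error(make_scenario("active", list(nonsense = 1)), "unknown override")
  expect_error(make_scenario("channel", list(0.1)), "named")
})

test_that("validate_scenario rejects structural violations by name", {
  expect_error(make_scenario("channel", list(field_strength = -1)),
               "field_strength")
  expect_error(make_scenario("channel", list(timestep = 0.02)), "timestep")
  expect_error(make_scenario("channel", list(amplitude = 4)), "amplitude")
  expect_error(make_scenario("channel", list(width = 12)), "box_lengths")
  expect_error(make_scenario("obstacle", list(R = 13)), "R")
  expect_error(make_scenario("active", list(box_lengths = 10)), "box_lengths")
  expect_error(make_scenario("active", list(ou_relaxation = 0)),
               "ou_relaxation")
  expect_error(validate_scenario(list()), "scenario_spec")
  # field_strength = 0 (passive control) is valid
  expect_s3_class(make_scenario("channel", list(field_strength = 0)),
                  "scenario_spec")
})

test_that("scenario YAML roundtrip preserves every field", {
  sp <- make_scenario("active", list(field_strength = 0.07))
  f <- tempfile(fileext = ".yaml")
  write_scenario(sp, f)
  sp2 <- read_scenario(f)
  expect_equal(unclass(sp2), unclass(sp))
})

test_that("region_partition tiles the box with a remainder-absorbing last cell", {
  p <- region_partition(50.6, 4.6)
  expect_equal(p$n_cells, 11L)
  expect_equal(p$edges[1], 0)
  expect_equal(tail(p$edges, 1), 50.6)
  # last cell absorbs the remainder
  p2 <- region_partition(22, 4)
  expect_equal(p2$n_cells, 5L)
  expect_equal(diff(p2$edges), c(4, 4, 4, 4, 6))
  # L >= box collapses to a single cell
  expect_equal(region_partition(22, 30)$n_cells, 1L)
  expect_error(region_partition(NULL, 2), "box")
  expect_error(region_partition(22, -1), "positive")
  g <- region_partition(c(26, 26), 2, mode = "grid2d")
  expect_equal(g$n_cells, c(13L, 13L))
})

test_that("assign_bins wraps positions and partitions the particle set exactly", {
  p <- region_partition(10, 2)
  st <- sim_state(x = c(0, 1.99, 2, -0.5, 10.5, 9.99),
                  y = numeric(6), c = rep(c(1L, -1L), 3))
  expect_equal(assign_bins(st, p), c(1L, 1L, 2L, 5L, 1L, 5L))
  # every particle lands in exactly one cell
  set.seed(1)
  st2 <- sim_state(x = runif(200, -20, 40), y = runif(200, -5, 5),
                   c = rep(c(1L, -1L), 100))
  idx <- assign_bins(st2, p)
  expect_true(all(idx >= 1 & idx <= p$n_cells))
  expect_equal(length(idx), 200L)
  # grid2d row-major indexing
  g <- region_partition(c(10, 10), 5, mode = "grid2d")
  stg <- sim_state(x = c(1, 6, 1, 6), y = c(-4, -4, 1, 1),
                   c = c(1L, -1L, 1L, -1L))
  expect_equal(assign_bins(stg, g), c(1L, 2L, 3L, 4L))
})

test_that("sim_state and validate_state enforce the per-particle invariants", {
  expect_error(sim_state(x = 1:3, y = 1:2), "mismatched")
  expect_error(sim_state(x = 0, y = 0, c = 2L), "color charges")
  expect_silent(sim_state(x = c(0, 1), y = c(0, 0), c = c(1L, 0L),
                          wall = c(0L, 1L)))
  expect_error(sim_state(x = c(0, 1), y = c(0, 0), c = c(1L, 1L)),
               "alternate")
  expect_error(sim_state(x = c(0, 1), y = c(0, 0), c = c(0L, 1L),
                         wall = c(1L, 1L)), "zero color charge")
  expect_error(sim_state(x = NaN, y = 0), "non-finite")
})

test_that("make_initial_state places fluid on a lattice and walls on anchors", {
  for (kind in c("channel", "obstacle", "active")) {
    sp <- make_scenario(kind)
    st <- make_initial_state(sp)
    expect_silent(validate_state(st, sp))
    nf <- sum(st$wall == 0L)
    expect_equal(nf, sp$n_fluid)
    # alternating color charges, net charge in {-1, 0, 1}
    expect_lte(abs(sum(st$c)), 1)
    if (kind == "channel") {
      w <- st$wall == 1L
      expect_gt(sum(w), 0)
      expect_equal(st$x[w], st$ax[w])
      expect_equal(st$y[w], st$ay[w])
      # fluid starts strictly inside the channel
      hw <- build_channel_walls(sp$geometry, sp$params$box_lengths)$halfwidth
      expect_true(all(abs(st$y[!w]) < hw(st$x[!w])))
    }
    if (kind == "obstacle") {
      d <- sqrt((st$x - 13)^2 + st$y^2)
      expect_true(all(d > sp$geometry$R))
    }
  }
  # seeded momenta are at temperature 1/beta
  st <- make_initial_state(make_scenario("active"), seed = 4)
  expect_lt(abs(mean(c(st$px, st$py)^2) - 1), 0.15)
})
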