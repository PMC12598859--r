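test_that("WCA pair interaction matches the closed form for an isolated pair", {
  box <- c(20, 20)
  for (r in c(0.9, 1.0, 1.05)) {
    st <- sim_state(x = c(5, 5 + r), y = c(0, 0), c = c(1L, -1L))
    out <- wca_pair(st, box)
    expect_equal(out$energy, wca_energy(r), tolerance = 1e-12)
    expect_equal(out$forces[1, 1], -wca_fmag(r), tolerance = 1e-12)
    expect_equal(out$forces[2, 1], wca_fmag(r), tolerance = 1e-12)
    expect_equal(out$forces[, 2], c(0, 0))
  }
  # continuous truncation: energy and force vanish approaching the cutoff ...
  st <- sim_state(x = c(5, 5 + 2^(1 / 6) - 1e-9), y = c(0, 0), c = c(1L, -1L))
  out <- wca_pair(st, box)
  expect_lt(abs(out$energy), 1e-12)
  expect_lt(max(abs(out$forces)), 1e-6)
  # ... and are exactly zero at and beyond it
  st <- sim_state(x = c(5, 5 + 2^(1 / 6)), y = c(0, 0), c = c(1L, -1L))
  out <- wca_pair(st, box)
  expect_equal(out$energy, 0)
  expect_equal(out$forces, matrix(0, 2, 2))
})

test_that("WCA forces use minimum-image separations and obey Newton's third law", {
  box <- c(10, 8)
  # pair interacting only across the x boundary
  st <- sim_state(x = c(0.3, 9.8), y = c(0, 0), c = c(1L, -1L))
  out <- wca_pair(st, box)
  expect_equal(out$energy, wca_energy(0.5), tolerance = 1e-10)
  # and across y when periodic_y
  st2 <- sim_state(x = c(5, 5), y = c(-3.7, 3.7), c = c(1L, -1L))
  expect_gt(wca_pair(st2, box)$energy, 0)
  expect_equal(wca_pair(st2, box, periodic_y = FALSE)$energy, 0)
  # random overlap-free configuration: forces sum to zero
  set.seed(2)
  xs <- ys <- numeric(0)
  while (length(xs) < 40) {
    cx <- runif(1, 0, 10); cy <- runif(1, -4, 4)
    if (length(xs)) {
      dx <- abs(xs - cx); dx <- pmin(dx, 10 - dx)
      dy <- abs(ys - cy); dy <- pmin(dy, 8 - dy)
      if (min(dx^2 + dy^2) < 0.85^2) next
    }
    xs <- c(xs, cx); ys <- c(ys, cy)
  }
  st3 <- sim_state(x = xs, y = ys, c = rep(c(1L, -1L), 20))
  f <- wca_pair(st3, box)$forces
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("wall-wall pairs do not interact", {
  st <- sim_state(x = c(3, 3.5), y = c(0, 0), c = c(0L, 0L), wall = c(1L, 1L),
                  ax = c(3, 3.5), ay = c(0, 0))
  out <- wca_pair(st, c(20, 20))
  expect_equal(out$energy, 0)
  expect_equal(out$forces, matrix(0, 2, 2))
  # but wall-fluid pairs do
  st2 <- sim_state(x = c(3, 3.5), y = c(0, 0), c = c(0L, 1L), wall = c(1L, 0L),
                   ax = c(3, 0), ay = c(0, 0))
  expect_gt(wca_pair(st2, c(20, 20))$energy, 0)
})

test_that("every force term equals minus the numerical gradient of its energy", {
  box <- c(12, 10)
  set.seed(7)
  # random configuration with a floor on pair distances (rejection placement)
  xs <- ys <- numeric(0)
  while (length(xs) < 25) {
    cx <- runif(1, 0, 12); cy <- runif(1, -4.4, 4.4)
    if (length(xs)) {
      dx <- abs(xs - cx); dx <- pmin(dx, 12 - dx)
      dy <- abs(ys - cy); dy <- pmin(dy, 10 - dy)
      if (min(dx^2 + dy^2) < 0.92^2) next
    }
    xs <- c(xs, cx); ys <- c(ys, cy)
  }
  wall <- as.integer(seq_along(xs) <= 5)
  st <- sim_state(x = xs, y = ys, c = ifelse(wall == 1L, 0L,
                                             rep_len(c(1L, -1L), 25)),
                  wall = wall, ax = xs + 0.1, ay = ys - 0.2)

  f_pair <- wca_pair(st, box)$forces
  n_pair <- num_force(function(s) wca_pair(s, box)$energy, st)
  expect_lt(max(abs(f_pair - n_pair)), 1e-6 * max(1, max(abs(f_pair))))

  f_teth <- tether_force(st, k = 50, box)$forces
  n_teth <- num_force(function(s) tether_force(s, 50, box)$energy, st)
  expect_lt(max(abs(f_teth - n_teth)), 1e-6 * max(1, max(abs(f_teth))))

  obst <- list(center = c(6, 0), R = 2)
  ok <- sqrt((xs - 6)^2 + ys^2) > 2 + 0.9
  sto <- sim_state(x = xs[ok], y = ys[ok],
                   c = rep_len(c(1L, -1L), sum(ok)))
  f_obs <- obstacle_force(sto, obst$center, obst$R, box)$forces
  n_obs <- num_force(function(s) obstacle_force(s, obst$center, obst$R,
                                                box)$energy, sto)
  expect_lt(max(abs(f_obs - n_obs)), 1e-6 * max(1, max(abs(f_obs))))
})

test_that("tether forces are harmonic on wall atoms and zero on fluid", {
  st <- sim_state(x = c(1, 2), y = c(0.5, 0), c = c(0L, 1L), wall = c(1L, 0L),
                  ax = c(1.3, 0), ay = c(0.1, 0))
  out <- tether_force(st, k = 50, c(20, 20))
  expect_equal(out$forces[1, ], -50 * c(1 - 1.3, 0.5 - 0.1))
  expect_equal(out$forces[2, ], c(0, 0))
  expect_equal(out$energy, 0.5 * 50 * ((1 - 1.3)^2 + (0.5 - 0.1)^2))
  st_bad <- st
  st_bad$ax[1] <- NA_real_
  expect_error(tether_force(st_bad, 50, c(20, 20)), "anchor")
})

test_that("obstacle force is radial, repulsive, and errors inside the core", {
  st <- sim_state(x = c(8.5, 2), y = c(0, 0), c = c(1L, -1L))
  out <- obstacle_force(st, center = c(6, 0), R = 2, box = c(20, 20))
  # surface distance 0.5 < 2^(1/6): repulsive, pointing away from the center
  expect_gt(out$forces[1, 1], 0)
  expect_equal(out$forces[1, 2], 0)
  expect_equal(out$energy, wca_energy(0.5), tolerance = 1e-10)
  # particle beyond the surface cutoff feels nothing
  expect_equal(out$forces[2, ], c(0, 0))
  expect_error(obstacle_force(st, c(6, 0), R = -1, c(20, 20)), "positive")
  st_in <- sim_state(x = 6.5, y = 0, c = 1L)
  expect_error(obstacle_force(st_in, c(6, 0), R = 2, c(20, 20)), "penetrated")
})

test_that("color force couples charge to the field along x only", {
  st <- sim_state(x = 1:4, y = numeric(4), c = c(1L, -1L, 1L, 0L),
                  wall = c(0L, 0L, 0L, 1L))
  f <- color_force(st, 0.3)
  expect_equal(f[, 1], c(0.3, -0.3, 0.3, 0))
  expect_equal(f[, 2], numeric(4))
})

test_that("channel walls follow the modulated profile", {
  box <- c(50.6, 14)
  w <- build_channel_walls(list(width = 8, amplitude = 2, wall_spacing = 0.9),
                           box)
  expect_equal(w$n_wall, 2 * round(50.6 / 0.9))
  expect_equal(sort(unique(abs(w$anchors[, 2]) + 0)),
               sort(unique(w$halfwidth(w$anchors[, 1]))))
  # widest at the box edge, narrowest at the center
  expect_equal(w$halfwidth(0), 4)
  expect_equal(w$halfwidth(50.6 / 2), 2)
  expect_error(build_channel_walls(list(width = 4, amplitude = 2,
                                        wall_spacing = 0.9), box), "pinches")
})

test_that("write_xyz emits a parseable extended-XYZ frame", {
  st <- sim_state(x = c(1, 2), y = c(0, 0.5), px = c(0.1, -0.2),
                  c = c(1L, 0L), wall = c(0L, 1L), ax = c(0, 2), ay = c(0, 0.5))
  f <- tempfile(fileext = ".xyz")
  write_xyz(st, f, c(10, 10), comment = "frame=0")
  lines <- readLines(f)
  expect_equal(lines[1], "2")
  expect_match(lines[2], "Lattice=")
  expect_match(lines[2], "frame=0")
  expect_equal(length(lines), 4)
  expect_match(lines[3], "^F ")
  expect_match(lines[4], "^W ")
})
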