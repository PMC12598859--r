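test_that("run_ensemble is reproducible in the seed and satisfies the bin identities", {
  sp <- small_active()
  e1 <- run_ensemble(sp, 12, t = 0.5, base_seed = 7, burn_in = 5, spacing = 1)
  expect_s3_class(e1, "dissipation_ensemble")
  expect_equal(dim(e1$J_fine), c(12L, as.integer(round(8 / 0.1))))
  expect_length(e1$J_global, 12)
  expect_length(e1$A_global, 12)
  expect_lte(max(e1$max_constraint_drift), 1e-10)

  e2 <- run_ensemble(sp, 12, t = 0.5, base_seed = 7, burn_in = 5, spacing = 1)
  expect_identical(e1$J_fine, e2$J_fine)
  expect_identical(e1$A_global, e2$A_global)
  e3 <- run_ensemble(sp, 12, t = 0.5, base_seed = 8, burn_in = 5, spacing = 1)
  expect_false(identical(e1$J_global, e3$J_global))

  om <- omega_ensemble(e1, region_partition(8, 2))
  rel <- abs(rowSums(om$omega_bins) - om$omega) / pmax(1, abs(om$omega))
  expect_lt(max(rel), 1e-9)
  expect_equal(om$omega, om$omega_fe + om$omega_xi)
  expect_equal(sum(om$n_bins), sp$n_fluid, tolerance = 1e-6)
  expect_error(run_ensemble(sp, 2, t = 0.5, equil_dt = 0.05), "equil_dt")
  expect_error(run_ensemble(sp, 2, t = 0.0013), "multiple of dt")
})

test_that("2D grid accumulation partitions the box exactly", {
  sp <- small_obstacle()
  grid <- region_partition(sp$params$box_lengths, 2, mode = "grid2d")
  ens <- run_ensemble(sp, 6, t = 0.5, base_seed = 3, burn_in = 5, spacing = 1,
                      grid = grid)
  expect_equal(dim(ens$J_grid), c(6L, prod(grid$n_cells)))
  # grid cells partition the box: per-trajectory grid sums equal the global
  rel <- abs(rowSums(ens$J_grid) - ens$J_global) / pmax(1, abs(ens$J_global))
  expect_lt(max(rel), 1e-9)
  expect_equal(sum(ens$ngrid_mean), sp$n_fluid, tolerance = 1e-6)
  m <- dissipation_map(0.3 * ens$J_grid, ens$ngrid_mean, grid)
  expect_equal(dim(m$mean), grid$n_cells)
  expect_equal(dim(m$n_avg), grid$n_cells)
})

test_that("experiments resume from chunks to a byte-identical ensemble", {
  sp <- small_active()
  dir <- file.path(tempfile("exp"))
  plan <- experiment_plan(sp, 12, t = 0.5, base_seed = 9, out_dir = dir,
                          chunk_size = 4L)
  expect_s3_class(plan, "experiment_plan")
  expect_error(experiment_plan(sp, 0), ">= 1")
  run_experiment(plan, quiet = TRUE)
  files <- list.files(dir)
  expect_true(all(c("manifest.json", "scenario.yaml",
                    "chunk_0001.csv", "chunk_0002.csv",
                    "chunk_0003.csv") %in% files))
  md5_before <- tools::md5sum(file.path(dir, "chunk_0002.csv"))
  # interrupting after chunk 1: deleting later chunks and re-running
  # regenerates them byte-identically, without touching finished chunks
  file.remove(file.path(dir, "chunk_0002.csv"))
  mtime1 <- file.mtime(file.path(dir, "chunk_0001.csv"))
  run_experiment(plan, quiet = TRUE)
  expect_identical(unname(tools::md5sum(file.path(dir, "chunk_0002.csv"))),
                   unname(md5_before))
  expect_identical(file.mtime(file.path(dir, "chunk_0001.csv")), mtime1)

  # analysis reads the chunked ensemble back
  s <- analyze_experiment(dir, L_values = c(2, 8), n_boot = 50)
  expect_s3_class(s, "experiment_summary")
  expect_equal(s$n_traj, 12)
  expect_named(s$per_L, c("2", "8"))
  # whole-box L: kappa is identically zero
  expect_identical(s$per_L[["8"]]$kappa, 0)
  # tiny ensembles are in the "no negative events" regime: reported, not faked
  expect_true(is.character(s$per_L[["2"]]$asymmetry) ||
                is.numeric(s$per_L[["2"]]$slope))
  f <- tempfile(fileext = ".json")
  write_summary(s, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$n_traj, 12)
})

test_that("the CLI returns documented exit codes", {
  expect_equal(cli(character(0)), 2L)
  expect_equal(cli("frobnicate"), 2L)
  expect_equal(cli(c("run", "--ntraj", "3")), 2L)
  expect_equal(cli(c("run", "--scenario", "active", "--badflag")), 2L)
  # analyze before run is an error
  expect_equal(suppressMessages(
    cli(c("analyze", "--out", tempfile("nope")))), 2L)
})

test_that("the CLI fixture path reproduces a known slope end-to-end", {
  dir <- tempfile("fix")
  code <- suppressMessages(
    cli(c("fixture", "--kappa", "0.5", "--n", "100000", "--seed", "7",
          "--out", dir)))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(dir, "fixture.csv")))
  s <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_lt(abs(s$slope - 1.5), 3 * s$slope_err)
  expect_lt(abs(s$kappa - 0.5), 4 * s$kappa_err)
})

test_that("the CLI run/analyze pipeline works on a small ensemble", {
  dir <- tempfile("cli")
  code <- suppressMessages(
    cli(c("run", "--scenario", "active", "--ntraj", "12", "--t", "0.5",
          "--seed", "3", "--out", dir)))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(dir, "chunk_0001.csv")))
  code2 <- suppressMessages(
    cli(c("analyze", "--out", dir, "--L", "2.2", "--L", "22")))
  expect_equal(code2, 0L)
  s <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(s$scenario, "active")
  expect_equal(s$n_traj, 12)
})
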