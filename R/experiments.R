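# Scenario orchestration: ensemble generation, analysis, file I/O, CLI.

#' Generate a trajectory ensemble
#'
#' The core driver: one equilibration chain (burn-in, then `spacing` reduced
#' time units between starts, with periodic Maxwell momentum refreshes);
#' after each spacing segment a driven trajectory of duration `t` is launched
#' from the current configuration with fresh Maxwell momenta (and stationary
#' propulsions for the active scenario) drawn from an independent
#' per-trajectory noise stream, then the chain resumes.  Per-trajectory
#' dissipation integrals are accumulated on a fine x-grid (cells of ~0.1
#' sigma) from which any slab partition is aggregated afterwards.
#'
#' @param spec A `scenario_spec`.
#' @param n_traj Number of trajectories.
#' @param t Trajectory duration (default: the scenario default, 5 for
#'   channel/obstacle, 3 for active).
#' @param base_seed Integer seed; fully determines the ensemble.
#' @param cfg An `integrator_config`.
#' @param spacing,burn_in Equilibration chain times (reduced units).
#' @param equil_dt Timestep of the field-free equilibration chain (its
#'   sampling only needs stability, not trajectory accuracy; must be
#'   <= 0.01).  Driven trajectories always use `cfg$dt`.
#' @param n_fine Fine-grid cell count (default ~0.1 sigma resolution).
#' @param grid Optional `region_partition` (`grid2d`) for 2D maps.
#' @param keep_series Accumulate the ensemble-mean global current time series.
#' @return A `dissipation_ensemble`: per-trajectory fine-grid integrals
#'   (`J_fine`, `A_fine` matrices), global integrals (`J_global`,
#'   `A_global`), ensemble-mean fine-grid particle counts (`navg_fine`),
#'   optional per-trajectory 2D-grid integrals, the ensemble-mean current
#'   relaxation `j_mean_series`, and per-trajectory `max_constraint_drift`.
#' @export
run_ensemble <- function(spec, n_traj, t = NULL, base_seed = 1,
                         cfg = integrator_config(), spacing = 5, burn_in = 50,
                         equil_dt = 0.005, n_fine = NULL, grid = NULL,
                         keep_series = TRUE) {
  validate_scenario(spec)
  if (is.null(t)) t <- spec$default_duration
  if (is.null(n_fine)) n_fine <- .default_n_fine(spec)
  dt <- cfg$dt
  if (!is.numeric(equil_dt) || equil_dt <= 0 || equil_dt > 0.01)
    stop("equil_dt must be in (0, 0.01]")
  traj_steps <- as.integer(round(t / dt))
  if (abs(traj_steps * dt - t) > 1e-9) stop("duration must be a multiple of dt")
  st <- make_initial_state(spec)
  gx <- if (is.null(grid)) 0L else grid$n_cells[1]
  gy <- if (is.null(grid)) 0L else grid$n_cells[2]
  r <- cpp_run_ensemble(.state_for_cpp(st), .spec_to_par(spec),
                        as.integer(n_traj), traj_steps, dt, equil_dt,
                        as.integer(round(burn_in / equil_dt)),
                        as.integer(round(spacing / equil_dt)),
                        as.integer(round(0.5 / equil_dt)),
                        as.integer(n_fine), as.numeric(base_seed),
                        as.integer(gx), as.integer(gy), isTRUE(keep_series))
  structure(list(
    spec = spec, n_traj = n_traj, duration = t, dt = dt, n_fine = n_fine,
    base_seed = base_seed,
    J_fine = r$J_fine,
    A_fine = if (spec$activity_enabled) r$A_fine else NULL,
    J_global = r$J_global,
    A_global = if (spec$activity_enabled) r$A_global else NULL,
    navg_fine = r$navg_fine / (n_traj * t),
    j_mean_series = if (isTRUE(keep_series)) r$j_series_sum / n_traj else NULL,
    grid = grid,
    J_grid = if (!is.null(grid)) r$J_grid else NULL,
    ngrid_mean = if (!is.null(grid)) r$ngrid_sum / (n_traj * t) else NULL,
    max_constraint_drift = r$max_constraint_drift
  ), class = "dissipation_ensemble")
}

#' @export
print.dissipation_ensemble <- function(x, ...) {
  cat("<dissipation_ensemble>", x$spec$kind, ":", x$n_traj,
      "trajectories of t =", x$duration, "\n")
  om <- omega_ensemble(x, region_partition(x$spec$params$box_lengths[1],
                                           x$spec$params$box_lengths[1]))
  cat("  <Omega_t> =", signif(mean(om$omega), 4), "+/-",
      signif(sd(om$omega) / sqrt(x$n_traj), 3), "\n")
  invisible(x)
}

#' Per-trajectory dissipation for a slab partition
#'
#' Aggregates an ensemble's fine-grid integrals into the slabs of `part` and
#' applies \eqn{\Omega_{L,t} = \beta F_e J_{x,L,t}} (plus the active
#' component \eqn{\beta \int \sum_{i\in bin} \xi_i p_{x,i} dt}).
#'
#' @param ens A `dissipation_ensemble`.
#' @param part A `region_partition` (slabs).
#' @return List with per-trajectory vectors/matrices: `omega` (global),
#'   `omega_bins`, `omega_star_bins`, `omega_fe`, `omega_fe_bins`,
#'   `omega_xi`, `omega_xi_bins`, `n_bins` (ensemble-mean counts per bin).
#' @export
omega_ensemble <- function(ens, part) {
  p <- ens$spec$params
  beta <- p$inverse_temperature
  Fe <- p$field_strength
  nb <- part$n_cells
  centers <- (seq_len(ens$n_fine) - 0.5) * (part$box[1] / ens$n_fine)
  idx <- pmin.int(pmax.int(findInterval(centers, part$edges), 1L), nb)
  agg <- function(M) {
    out <- matrix(0, nrow(M), nb)
    for (b in seq_len(nb))
      out[, b] <- rowSums(M[, idx == b, drop = FALSE])
    out
  }
  omega_fe_bins <- beta * Fe * agg(ens$J_fine)
  omega_fe <- beta * Fe * ens$J_global
  if (!is.null(ens$A_fine)) {
    omega_xi_bins <- beta * agg(ens$A_fine)
    omega_xi <- beta * ens$A_global
  } else {
    omega_xi_bins <- matrix(0, nrow(omega_fe_bins), nb)
    omega_xi <- numeric(length(omega_fe))
  }
  omega_bins <- omega_fe_bins + omega_xi_bins
  omega <- omega_fe + omega_xi
  list(omega = omega, omega_bins = omega_bins,
       omega_star_bins = omega - omega_bins,
       omega_fe = omega_fe, omega_fe_bins = omega_fe_bins,
       omega_xi = omega_xi, omega_xi_bins = omega_xi_bins,
       n_bins = as.numeric(rowsum(ens$navg_fine,
                                  factor(idx, levels = seq_len(nb)))))
}

#' Define an experiment plan
#'
#' @param scenario A `scenario_spec`.
#' @param n_trajectories Ensemble size (>= 1).
#' @param t Trajectory duration; default the scenario default (5 for
#'   channel/obstacle, 3 for active).
#' @param L_values Slab widths to analyze (the partitions all tile the same
#'   box).
#' @param base_seed Integer seed.
#' @param out_dir Output directory.
#' @param bin_width,min_count Asymmetry-function analysis options.
#' @param chunk_size Trajectories per output chunk (resumption granularity).
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(scenario, n_trajectories, t = NULL,
                            L_values = NULL, base_seed = 1,
                            out_dir = tempfile("experiment"),
                            bin_width = NULL, min_count = 10,
                            chunk_size = 1000L) {
  validate_scenario(scenario)
  if (n_trajectories < 1) stop("n_trajectories must be >= 1")
  if (is.null(t)) t <- scenario$default_duration
  box <- scenario$params$box_lengths[1]
  if (is.null(L_values)) L_values <- signif(box / 10, 3)
  structure(list(scenario = scenario, n_trajectories = as.integer(n_trajectories),
                 t = t, L_values = L_values, base_seed = base_seed,
                 out_dir = out_dir, bin_width = bin_width,
                 min_count = min_count,
                 chunk_size = as.integer(chunk_size)),
            class = "experiment_plan")
}

.plan_header <- function(plan) {
  jsonlite::toJSON(list(
    package = "dissipmap",
    version = as.character(utils::packageVersion("dissipmap")),
    scenario = unclass(plan$scenario),
    n_trajectories = plan$n_trajectories,
    t = plan$t, L_values = plan$L_values, base_seed = plan$base_seed
  ), auto_unbox = TRUE, digits = NA)
}

#' Run an experiment plan to disk
#'
#' Generates the ensemble in chunks (each chunk an independent equilibration
#' chain seeded from `(base_seed, chunk)`), writing one CSV per chunk with
#' per-trajectory global and per-fine-cell integrated currents, plus a JSON
#' manifest embedding the resolved scenario.  Completed chunks are skipped on
#' re-run, so an interrupted run resumes to a byte-identical ensemble.
#'
#' @param plan An `experiment_plan`.
#' @param quiet Suppress progress messages.
#' @return The output directory, invisibly.
#' @export
run_experiment <- function(plan, quiet = FALSE) {
  dir.create(plan$out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(.plan_header(plan), file.path(plan$out_dir, "manifest.json"))
  write_scenario(plan$scenario, file.path(plan$out_dir, "scenario.yaml"))
  n_chunks <- ceiling(plan$n_trajectories / plan$chunk_size)
  for (ch in seq_len(n_chunks)) {
    f <- file.path(plan$out_dir, sprintf("chunk_%04d.csv", ch))
    if (file.exists(f)) next
    n_this <- min(plan$chunk_size,
                  plan$n_trajectories - (ch - 1) * plan$chunk_size)
    ens <- run_ensemble(plan$scenario, n_this, t = plan$t,
                        base_seed = .chunk_seed(plan$base_seed, ch),
                        keep_series = FALSE)
    dt_out <- data.table::data.table(
      trajectory = (ch - 1) * plan$chunk_size + seq_len(n_this),
      chunk = ch, J_global = ens$J_global)
    if (!is.null(ens$A_global)) dt_out$A_global <- ens$A_global
    jf <- data.table::as.data.table(ens$J_fine)
    data.table::setnames(jf, paste0("J", seq_len(ncol(jf))))
    dt_out <- cbind(dt_out, jf)
    if (!is.null(ens$A_fine)) {
      af <- data.table::as.data.table(ens$A_fine)
      data.table::setnames(af, paste0("A", seq_len(ncol(af))))
      dt_out <- cbind(dt_out, af)
    }
    tmp <- paste0(f, ".tmp")
    data.table::fwrite(dt_out, tmp)
    file.rename(tmp, f)
    if (!quiet) message("chunk ", ch, "/", n_chunks, " written")
  }
  invisible(plan$out_dir)
}

.chunk_seed <- function(base_seed, chunk) {
  (as.numeric(base_seed) * 2654435761 + chunk * 40503) %% 2^31
}

.read_experiment <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  spec <- read_scenario(file.path(dir, "scenario.yaml"))
  files <- sort(list.files(dir, pattern = "^chunk_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no ensemble chunks found in ", dir)
  tab <- data.table::rbindlist(lapply(files, data.table::fread))
  jcols <- grep("^J\\d+$", names(tab), value = TRUE)
  acols <- grep("^A\\d+$", names(tab), value = TRUE)
  structure(list(
    spec = spec, n_traj = nrow(tab), duration = man$t, dt = spec$params$timestep,
    n_fine = length(jcols), base_seed = man$base_seed,
    J_fine = as.matrix(tab[, jcols, with = FALSE]),
    A_fine = if (length(acols)) as.matrix(tab[, acols, with = FALSE]) else NULL,
    J_global = tab$J_global,
    A_global = if ("A_global" %in% names(tab)) tab$A_global else NULL,
    navg_fine = rep(NA_real_, length(jcols)),
    manifest = man
  ), class = "dissipation_ensemble")
}

#' Analyze an ensemble: histograms, asymmetry slopes, kappa, FT checks
#'
#' For every slab width in `L_values`, computes per-trajectory local
#' dissipation in the reference slab (by default the slab containing the box
#' center, where the channel is narrowest and the obstacle sits), its
#' complement, the kappa estimate with bootstrap errors, the asymmetry curve
#' with origin-constrained slope, and the local-FT consistency report; for
#' the active scenario the deterministic and stochastic components get their
#' own slopes.  An L spanning the whole box reports kappa = 0 exactly and
#' (as expected for global dissipation under strong driving) may report the
#' asymmetry function as unavailable.
#'
#' @param ens A `dissipation_ensemble` or an output directory written by
#'   [run_experiment()].
#' @param L_values Slab widths.
#' @param slab Which slab to analyze: `"center"` (default) or an index.
#' @param bin_width,min_count Asymmetry options.
#' @param n_boot,seed Bootstrap settings.
#' @return An `experiment_summary` list (JSON-serializable): per-L results
#'   plus global statistics.
#' @export
analyze_experiment <- function(ens, L_values = NULL, slab = "center",
                               bin_width = NULL, min_count = 10,
                               n_boot = 500, seed = 1) {
  if (is.character(ens)) ens <- .read_experiment(ens)
  box <- ens$spec$params$box_lengths[1]
  if (is.null(L_values)) L_values <- signif(box / 10, 3)
  beta <- ens$spec$params$inverse_temperature
  Fe <- ens$spec$params$field_strength
  om_glob <- beta * Fe * ens$J_global +
    if (!is.null(ens$A_global)) beta * ens$A_global else 0
  res <- list()
  for (L in L_values) {
    part <- region_partition(box, L)
    om <- omega_ensemble(ens, part)
    b <- if (identical(slab, "center"))
      max(1L, min(part$n_cells, findInterval(box / 2, part$edges))) else
      as.integer(slab)
    local <- om$omega_bins[, b]
    compl <- om$omega_star_bins[, b]
    entry <- list(L = L, slab = b, n = length(local),
                  omega_mean = mean(local),
                  omega_sd = sd(local),
                  neg_fraction = mean(local < 0))
    if (part$n_cells == 1L) {
      entry$kappa <- 0; entry$kappa_err <- 0
    } else {
      k <- kappa(local, compl, n_boot = n_boot, seed = seed)
      entry$kappa <- k$kappa; entry$kappa_err <- k$stderr
    }
    curve <- tryCatch(asymmetry_function(local, bin_width = bin_width,
                                         min_count = min_count),
                      error = function(e) e)
    if (inherits(curve, "error")) {
      entry$asymmetry <- "global-FT regime, asymmetry unavailable"
      entry$asymmetry_error <- conditionMessage(curve)
    } else {
      entry$slope <- curve$slope
      entry$slope_err <- curve$slope_err
      chk <- local_ft_check(curve, entry$kappa, entry$kappa_err)
      entry$ft_consistent <- chk$consistent
      entry$ft_discrepancy_sigma <- chk$discrepancy_sigma
      entry$curve <- data.frame(A = curve$A, log_ratio = curve$log_ratio,
                                stderr = curve$stderr)
    }
    if (!is.null(ens$A_fine)) {
      fe_loc <- om$omega_fe_bins[, b]
      xi_loc <- om$omega_xi_bins[, b]
      entry$slope_fe <- tryCatch(
        asymmetry_function(fe_loc, min_count = min_count)$slope,
        error = function(e) NA_real_)
      cx <- tryCatch(asymmetry_function(xi_loc, min_count = min_count),
                     error = function(e) NULL)
      if (!is.null(cx)) {
        entry$slope_xi <- cx$slope
        entry$slope_xi_err <- cx$slope_err
      }
      kx <- kappa(xi_loc, (om$omega_xi - xi_loc), n_boot = n_boot, seed = seed)
      entry$kappa_xi <- kx$kappa
    }
    res[[as.character(L)]] <- entry
  }
  structure(list(
    scenario = ens$spec$kind,
    n_traj = length(om_glob),
    duration = ens$duration,
    omega_global_mean = mean(om_glob),
    omega_global_sd = sd(om_glob),
    omega_global_neg_fraction = mean(om_glob < 0),
    per_L = res
  ), class = "experiment_summary")
}

#' Write an experiment summary as JSON
#'
#' @param summary An `experiment_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Command-line interface
#'
#' Subcommands: `run` (generate an ensemble to disk), `analyze` (summarize an
#' ensemble directory), `fixture` (write a synthetic Gaussian ensemble CSV),
#' `map` (2D dissipation map CSV).  Returns the exit status (0 success, 2
#' validation/usage error) instead of quitting, so it can be driven
#' programmatically; the installed `inst/cli/dissipmap` script wraps it.
#'
#' @param argv Character vector of arguments.
#' @return Integer exit status.
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dissipmap <run|analyze|map|fixture> [options]",
    "  run     --scenario {channel,obstacle,active} --ntraj N [--t T]",
    "          [--L W]... [--seed S] [--out DIR] [--dump-xyz]",
    "  analyze --out DIR [--L W]... [--min-count M]",
    "  map     --out DIR --scenario KIND --ntraj N [--cell W] [--seed S]",
    "  fixture --kappa K --n N [--seed S] --out DIR",
    sep = "\n")
  fail <- function(...) { message(...); message(usage); return(2L) }
  if (length(argv) < 1) return(fail("no subcommand given"))
  cmd <- argv[1]
  opts <- list(L = numeric(0))
  i <- 2
  while (i <= length(argv)) {
    a <- argv[i]
    take <- function() { i <<- i + 1; if (i > length(argv)) stop("missing value for ", a); argv[i] }
    ok <- TRUE
    tryCatch(switch(a,
      "--scenario" = opts$scenario <- take(),
      "--ntraj" = opts$ntraj <- as.integer(take()),
      "--t" = opts$t <- as.numeric(take()),
      "--L" = opts$L <- c(opts$L, as.numeric(take())),
      "--seed" = opts$seed <- as.numeric(take()),
      "--out" = opts$out <- take(),
      "--config" = opts$config <- take(),
      "--kappa" = opts$kappa <- as.numeric(take()),
      "--n" = opts$n <- as.integer(take()),
      "--cell" = opts$cell <- as.numeric(take()),
      "--min-count" = opts$min_count <- as.integer(take()),
      "--dump-xyz" = opts$dump_xyz <- TRUE,
      ok <- FALSE), error = function(e) ok <<- FALSE)
    if (!ok) return(fail("unknown or malformed flag: ", a))
    i <- i + 1
  }
  seed <- if (is.null(opts$seed)) 1 else opts$seed
  out <- tryCatch({
    switch(cmd,
      run = {
        if (is.null(opts$scenario) || is.null(opts$ntraj))
          stop("run needs --scenario and --ntraj")
        spec <- if (!is.null(opts$config)) read_scenario(opts$config)
                else make_scenario(opts$scenario)
        plan <- experiment_plan(spec, opts$ntraj, t = opts$t,
                                L_values = if (length(opts$L)) opts$L else NULL,
                                base_seed = seed,
                                out_dir = if (is.null(opts$out)) "." else opts$out)
        run_experiment(plan, quiet = TRUE)
        if (isTRUE(opts$dump_xyz))
          write_xyz(make_initial_state(spec),
                    file.path(plan$out_dir, "initial.xyz"),
                    spec$params$box_lengths)
        message("ensemble written to ", plan$out_dir)
        0L
      },
      analyze = {
        if (is.null(opts$out)) stop("analyze needs --out DIR")
        if (!file.exists(file.path(opts$out, "manifest.json")))
          stop("no ensemble found in ", opts$out, " (run `run` first)")
        s <- analyze_experiment(opts$out,
                                L_values = if (length(opts$L)) opts$L else NULL,
                                min_count = if (is.null(opts$min_count)) 10
                                            else opts$min_count)
        write_summary(s, file.path(opts$out, "summary.json"))
        message("summary written to ", file.path(opts$out, "summary.json"))
        0L
      },
      map = {
        if (is.null(opts$out) || is.null(opts$scenario) || is.null(opts$ntraj))
          stop("map needs --out, --scenario, --ntraj")
        spec <- make_scenario(opts$scenario)
        cell <- if (is.null(opts$cell)) 2 else opts$cell
        grid <- region_partition(spec$params$box_lengths, cell, mode = "grid2d")
        ens <- run_ensemble(spec, opts$ntraj, base_seed = seed, grid = grid)
        beta <- spec$params$inverse_temperature
        Fe <- spec$params$field_strength
        m <- dissipation_map(beta * Fe * ens$J_grid, ens$ngrid_mean, grid)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        data.table::fwrite(data.table::as.data.table(m$mean),
                           file.path(opts$out, "map_omega.csv"))
        data.table::fwrite(data.table::as.data.table(m$n_avg),
                           file.path(opts$out, "map_navg.csv"))
        message("maps written to ", opts$out)
        0L
      },
      fixture = {
        if (is.null(opts$kappa) || is.null(opts$n))
          stop("fixture needs --kappa and --n")
        fx <- gaussian_fixture(opts$n, kappa_true = opts$kappa, seed = seed,
                               ft_consistent = TRUE)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        f <- file.path(opts$out, "fixture.csv")
        data.table::fwrite(data.table::data.table(local = fx$local,
                                                  complement = fx$complement), f)
        curve <- asymmetry_function(fx$local)
        k <- kappa(fx$local, fx$complement, n_boot = 200)
        write_summary(structure(list(slope = curve$slope,
                                     slope_err = curve$slope_err,
                                     kappa = k$kappa, kappa_err = k$stderr),
                                class = "experiment_summary"),
                      file.path(opts$out, "summary.json"))
        message("fixture written to ", f)
        0L
      },
      stop("unknown subcommand: ", cmd))
  }, error = function(e) { message("error: ", conditionMessage(e)); 2L })
  if (is.null(out)) 0L else out
}
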