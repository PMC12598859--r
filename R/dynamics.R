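# Time integration of the three equation sets.
#
# All three scenarios are integrated with a velocity-Verlet-style symmetric
# splitting in which the Gaussian-thermostatted momentum kick is solved in
# closed form (the isokinetic kick with frozen forces has an exact solution
# that conserves the constrained kinetic energy to machine precision), and
# the constrained quantity is restored by exact projection every step:
#   channel  - walls-only isokinetic thermostat (wall kinetic energy fixed),
#   obstacle - Gaussian ergostat (total internal energy H fixed),
#   active   - all-particle isokinetic thermostat + exact Ornstein-Uhlenbeck
#              refresh of the propulsion between half-kicks.

#' Integrator configuration
#'
#' @param dt Timestep in reduced time (default 0.002, standard for a WCA
#'   fluid at T = 1; must be < 0.01).
#' @param stride Recording stride (steps between stored samples; the
#'   dissipation integrals always use every step).
#' @param constraint_tolerance Per-step bound on the relative drift of the
#'   constrained quantity; exceeding it is an integration failure.
#' @return An `integrator_config` list.
#' @export
integrator_config <- function(dt = 0.002, stride = 1L,
                              constraint_tolerance = 1e-10) {
  if (dt <= 0 || dt >= 0.01) stop("dt must be in (0, 0.01)")
  if (constraint_tolerance <= 0) stop("constraint_tolerance must be positive")
  structure(list(dt = dt, stride = as.integer(stride),
                 constraint_tolerance = constraint_tolerance),
            class = "integrator_config")
}

#' Gaussian isokinetic thermostat multiplier
#'
#' \eqn{\alpha = \sum_i p_i \cdot F_i / \sum_i p_i^2} over the thermostatted
#' subset; with this multiplier the subset kinetic energy is analytically
#' conserved, \eqn{d(\sum p^2)/dt = 0}.
#'
#' @param p n x 2 momenta of the thermostatted subset.
#' @param f n x 2 total forces on that subset.
#' @return The scalar multiplier.
#' @export
isokinetic_alpha <- function(p, f) {
  p <- rbind(p); f <- rbind(f)
  den <- sum(p^2)
  if (den <= 0) stop("isokinetic constraint undefined: zero kinetic energy")
  sum(p * f) / den
}

#' Gaussian ergostat multiplier
#'
#' \eqn{\alpha = \sum_i c_i F_e p_{x,i} / \sum_i p_i^2}; with this multiplier
#' the driven dynamics conserves the total internal energy H, so the work
#' done by the color field is removed at exactly the rate it is injected and
#' dissipation equals entropy production.
#'
#' @param state A `sim_state`.
#' @param F_e Field strength.
#' @return The scalar multiplier.
#' @export
ergostat_alpha <- function(state, F_e) {
  den <- sum(state$px^2 + state$py^2)
  if (den <= 0) stop("ergostat undefined: zero total kinetic energy")
  sum(state$c * F_e * state$px) / den
}

#' Exact Ornstein-Uhlenbeck update
#'
#' One step of \eqn{\dot\xi = -\xi/\tau + \eta} with noise covariance
#' \eqn{\langle \eta(t)\eta(t+s)\rangle = 2\sigma^2\delta(s)/\tau}, using the
#' exact discretization
#' \eqn{\xi' = \xi e^{-dt/\tau} + \sigma\sqrt{1 - e^{-2dt/\tau}}\, G}.
#' The stationary distribution is \eqn{N(0, \sigma^2)} and the stationary
#' autocorrelation is \eqn{e^{-s/\tau}} for any `dt`.
#'
#' @param xi Current propulsion values.
#' @param tau Relaxation time (> 0).
#' @param sigma_noise Stationary standard deviation \eqn{\sigma}.
#' @param dt Timestep.
#' @return Updated propulsion vector (uses R's RNG).
#' @export
ou_update <- function(xi, tau, sigma_noise, dt) {
  if (tau <= 0) stop("ou_relaxation tau must be positive")
  if (dt < 0) stop("dt must be non-negative")
  e <- exp(-dt / tau)
  xi * e + sigma_noise * sqrt(1 - e^2) * rnorm(length(xi))
}

#' Advance a state by one timestep
#'
#' Runs one step of the scenario's equations of motion (see the module
#' header); equivalent to `run_trajectory` over a single step.
#'
#' @param state A `sim_state`.
#' @param spec A `scenario_spec`.
#' @param cfg An `integrator_config`.
#' @param seed Integer seed for the noise stream (active scenario only).
#' @return The advanced `sim_state`.
#' @export
step <- function(state, spec, cfg = integrator_config(), seed = 1) {
  rec <- run_trajectory(state, spec, duration = cfg$dt, cfg = cfg, seed = seed)
  rec$final_state
}

#' Generate a driven or active trajectory
#'
#' Integrates the scenario's dynamics for `duration`, recording at every step
#' the instantaneous color current (globally, per cell of a fine x-grid used
#' for trapezoidal time integration, and per bin of `partition` at the
#' recording stride), the active products \eqn{\sum_i \xi_i p_{x,i}}, and a
#' conserved-quantity log (constrained kinetic energy or total energy H, and
#' the instantaneous thermostat multiplier).
#'
#' @param state Starting `sim_state` (typically from [equilibrate()]).
#' @param spec A `scenario_spec`.
#' @param duration Trajectory duration t (a multiple of `cfg$dt`).
#' @param cfg An `integrator_config`.
#' @param seed Integer seed; the noise stream is derived deterministically
#'   from it, so identical (seed, spec, cfg, state) give identical records.
#' @param partition Optional `region_partition` for strided per-bin series.
#' @param n_fine Number of fine cells for the integrated current profile
#'   (default: cells of about 0.1 sigma).
#' @return A `trajectory_record` with fields `t`, `j_global`, `a_global`,
#'   `j_bins`, `a_bins`, `K_constrained`, `H`, `alpha`, fine-grid integrals
#'   `J_fine`, `A_fine`, `navg_fine`, totals `J_global`, `A_global`,
#'   `max_constraint_drift`, and `final_state`.
#' @export
run_trajectory <- function(state, spec, duration, cfg = integrator_config(),
                           seed = 1, partition = NULL, n_fine = NULL) {
  validate_state(state)
  validate_scenario(spec)
  dt <- cfg$dt
  n_steps <- as.integer(round(duration / dt))
  if (abs(n_steps * dt - duration) > 1e-9)
    stop("duration must be a multiple of dt")
  if (is.null(n_fine)) n_fine <- .default_n_fine(spec)
  edges <- if (is.null(partition)) numeric(0) else partition$edges
  if (n_steps == 0L) {
    return(structure(list(
      t = 0, j_global = instantaneous_current(state, NULL),
      duration = 0, dt = dt, final_state = state, spec = spec,
      J_fine = numeric(n_fine), A_fine = numeric(n_fine),
      navg_fine = numeric(n_fine), J_global = 0, A_global = 0,
      max_constraint_drift = 0, n_fine = n_fine, partition = partition),
      class = "trajectory_record"))
  }
  r <- cpp_run_trajectory(.state_for_cpp(state), .spec_to_par(spec),
                          n_steps, dt, cfg$stride, edges,
                          as.integer(n_fine), as.numeric(seed))
  if (r$max_constraint_drift > cfg$constraint_tolerance * n_steps)
    stop(sprintf("constraint drift %.3e exceeds tolerance over %d steps",
                 r$max_constraint_drift, n_steps))
  fin <- r$final_state
  fin$time <- state$time + duration
  r$final_state <- structure(fin, class = "sim_state")
  r$duration <- duration
  r$dt <- dt
  r$n_fine <- n_fine
  r$partition <- partition
  r$spec <- spec
  structure(r, class = "trajectory_record")
}

#' Sample equilibrium starting configurations
#'
#' Runs field-free (no drive, no activity) thermostatted dynamics from the
#' lattice state, discards a burn-in, then collects configurations separated
#' by `spacing` reduced time units along the chain; momentum thermalization
#' uses periodic Maxwell redraws, and each returned sample carries fresh
#' Maxwell momenta (and, for the active scenario, stationary propulsions), so
#' samples are equilibrium phase-space points at temperature \eqn{1/\beta}.
#'
#' @param spec A `scenario_spec`.
#' @param n_samples Number of configurations to return.
#' @param spacing Chain time between samples (reduced units).
#' @param burn_in Discarded initial chain time.
#' @param seed Integer seed (fully determines the output).
#' @param cfg An `integrator_config`.
#' @return List of `sim_state` objects with attribute `potential_energy`.
#' @export
equilibrate <- function(spec, n_samples, spacing = 5, burn_in = 50, seed = 1,
                        cfg = integrator_config()) {
  validate_scenario(spec)
  st <- make_initial_state(spec)
  r <- cpp_equilibrate(.state_for_cpp(st), .spec_to_par(spec),
                       as.integer(n_samples), cfg$dt,
                       as.integer(round(burn_in / cfg$dt)),
                       as.integer(round(spacing / cfg$dt)),
                       as.integer(round(0.5 / cfg$dt)),
                       as.numeric(seed))
  u <- r$potential_energy
  drift <- if (n_samples >= 4) {
    half <- seq_len(floor(n_samples / 2))
    abs(mean(u[half]) - mean(u[-half])) / max(1, sd(u))
  } else 0
  if (is.finite(drift) && drift > 3)
    warning("potential energy drifting across samples: possibly not equilibrated")
  out <- lapply(r$states, function(s) {
    s$time <- 0
    structure(s, class = "sim_state")
  })
  attr(out, "potential_energy") <- u
  out
}
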