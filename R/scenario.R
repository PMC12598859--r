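#' @useDynLib dissipmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd var cov quantile IQR coef lm setNames
#' @importFrom utils head tail
NULL

# WCA cutoff 2^(1/6) sigma, in reduced units
.wca_cutoff <- 2^(1/6)

.scenario_kinds <- c("channel", "obstacle", "active")

.default_params <- function(kind) {
  p <- list(
    field_strength = 0.3,
    inverse_temperature = 1.0,
    spring_constant = 50.0,
    ou_relaxation = 0.1,
    ou_amplitude = 0.1,
    timestep = 0.002,
    wca_epsilon = 1.0,
    wca_sigma = 1.0,
    box_lengths = c(50.6, 14.0)
  )
  if (kind == "obstacle") p$box_lengths <- c(26.0, 26.0)
  if (kind == "active") {
    p$field_strength <- 0.05
    p$ou_amplitude <- 0.1          # sigma = 2 Fe
    p$box_lengths <- c(22.0, 22.0)
  }
  p
}

.default_geometry <- function(kind) {
  switch(kind,
    channel = list(width = 8.0, amplitude = 2.0, wall_spacing = 0.9),
    obstacle = list(R = 5.0),
    active = list()
  )
}

#' Build a validated scenario specification
#'
#' Constructs the full parameter set for one of the three model systems:
#' \describe{
#'   \item{channel}{A two-dimensional WCA fluid driven by a color field
#'     (\eqn{F_e = 0.3} by default) through a channel of varying width whose
#'     tethered wall atoms are held at constant kinetic temperature by a
#'     Gaussian isokinetic thermostat.  Periodic in x only.}
#'   \item{obstacle}{A fully periodic driven WCA fluid flowing past a static
#'     disk-shaped obstacle of radius \eqn{R = 5}; a Gaussian ergostat keeps
#'     the total internal energy constant, so dissipation equals entropy
#'     production.}
#'   \item{active}{A fully periodic driven active fluid: each particle carries
#'     an Ornstein-Uhlenbeck self-propulsion \eqn{\xi_i} along x (relaxation
#'     time \eqn{\tau = 0.1}, stationary amplitude \eqn{\sigma = 2 F_e}) on
#'     top of a weak color field \eqn{F_e = 0.05}, with an all-particle
#'     Gaussian isokinetic thermostat.}
#' }
#'
#' All quantities are in reduced Lennard-Jones units with \eqn{T = 1}
#' (\eqn{\beta = 1}) by default.  The fluid density defaults to
#' \eqn{\rho = 0.5}; the particle count follows from the geometry.
#'
#' @param kind One of `"channel"`, `"obstacle"`, `"active"`.
#' @param overrides Named list of parameter or geometry overrides.  Recognised
#'   names are the fields of `params` (`field_strength`,
#'   `inverse_temperature`, `spring_constant`, `ou_relaxation`,
#'   `ou_amplitude`, `timestep`, `box_lengths`), the geometry fields of the
#'   chosen kind (`width`, `amplitude`, `wall_spacing` for the channel; `R`
#'   for the obstacle), and `density`.
#' @return An object of class `scenario_spec`.
#' @examples
#' sp <- make_scenario("active")
#' sp$params$field_strength   # 0.05
#' @export
make_scenario <- function(kind = c("channel", "obstacle", "active"),
                          overrides = list()) {
  kind <- match.arg(kind)
  params <- .default_params(kind)
  geometry <- .default_geometry(kind)
  density <- 0.5

  if (length(overrides)) {
    nms <- names(overrides)
    if (is.null(nms) || any(nms == ""))
      stop("overrides must be a fully named list")
    for (nm in nms) {
      if (nm %in% names(params)) params[[nm]] <- overrides[[nm]]
      else if (nm %in% names(geometry)) geometry[[nm]] <- overrides[[nm]]
      else if (nm == "density") density <- overrides[[nm]]
      else stop("unknown override field: '", nm, "'")
    }
  }

  spec <- structure(list(
    kind = kind,
    params = params,
    geometry = geometry,
    density = density,
    thermostat_scope = if (kind == "channel") "walls_only" else "all_fluid",
    activity_enabled = (kind == "active"),
    default_duration = if (kind == "active") 3 else 5
  ), class = "scenario_spec")
  validate_scenario(spec)
  spec$n_fluid <- nrow(.fluid_lattice(spec))
  spec
}

#' Validate a scenario specification
#'
#' Checks every structural invariant (positivity of parameters, timestep
#' bound, thermostat-scope consistency, non-degenerate geometry) and fails
#' with an error naming the offending field.
#'
#' @param spec A `scenario_spec`.
#' @return The spec, invisibly, if valid.
#' @export
validate_scenario <- function(spec) {
  if (!inherits(spec, "scenario_spec")) stop("not a scenario_spec")
  p <- spec$params
  chk_pos <- function(v, nm) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("invalid scenario field '", nm, "': must be strictly positive")
  }
  if (!is.numeric(p$field_strength) || !is.finite(p$field_strength) ||
      p$field_strength < 0)
    stop("invalid scenario field 'field_strength': must be >= 0")
  chk_pos(p$inverse_temperature, "inverse_temperature")
  chk_pos(p$spring_constant, "spring_constant")
  chk_pos(p$ou_relaxation, "ou_relaxation")
  chk_pos(p$ou_amplitude, "ou_amplitude")
  chk_pos(p$timestep, "timestep")
  if (p$timestep >= 0.01)
    stop("invalid scenario field 'timestep': must be < 0.01")
  chk_pos(p$box_lengths, "box_lengths")
  if (length(p$box_lengths) != 2)
    stop("invalid scenario field 'box_lengths': need (Lx, Ly)")
  chk_pos(spec$density, "density")
  if (spec$kind == "channel") {
    g <- spec$geometry
    chk_pos(g$width, "width")
    chk_pos(g$wall_spacing, "wall_spacing")
    if (!is.numeric(g$amplitude) || g$amplitude < 0)
      stop("invalid scenario field 'amplitude': must be >= 0")
    if (g$amplitude >= g$width / 2)
      stop("invalid scenario field 'amplitude': channel pinches closed ",
           "(amplitude must be < width/2)")
    if (g$width + 4 > p$box_lengths[2])
      stop("invalid scenario field 'box_lengths': Ly too small for channel width")
    if (spec$thermostat_scope != "walls_only" || spec$activity_enabled)
      stop("channel scenario requires walls_only thermostat and no activity")
  } else if (spec$kind == "obstacle") {
    chk_pos(spec$geometry$R, "R")
    if (2 * (spec$geometry$R + .wca_cutoff) >= min(p$box_lengths))
      stop("invalid scenario field 'R': obstacle does not fit in the box")
    if (spec$thermostat_scope != "all_fluid" || spec$activity_enabled)
      stop("obstacle scenario requires all_fluid ergostat and no activity")
  } else {
    if (spec$thermostat_scope != "all_fluid" || !spec$activity_enabled)
      stop("active scenario requires all_fluid thermostat and activity on")
  }
  invisible(spec)
}

#' @export
print.scenario_spec <- function(x, ...) {
  p <- x$params
  cat("<scenario_spec>", x$kind, "\n")
  cat("  Fe =", p$field_strength, " beta =", p$inverse_temperature,
      " dt =", p$timestep, "\n")
  cat("  box =", paste(p$box_lengths, collapse = " x "),
      " density =", x$density, " n_fluid =", x$n_fluid, "\n")
  if (x$kind == "channel")
    cat("  channel width", x$geometry$width, "modulation", x$geometry$amplitude,
        "spring k =", p$spring_constant, "\n")
  if (x$kind == "obstacle")
    cat("  obstacle R =", x$geometry$R, "(ergostat)\n")
  if (x$kind == "active")
    cat("  tau =", p$ou_relaxation, " sigma_noise =", p$ou_amplitude, "\n")
  invisible(x)
}

#' Serialize a scenario to YAML
#'
#' @param spec A `scenario_spec`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [read_scenario()]
#' @export
write_scenario <- function(spec, path) {
  validate_scenario(spec)
  obj <- unclass(spec)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' Read a scenario from YAML
#'
#' @param path File written by [write_scenario()].
#' @return A validated `scenario_spec`.
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$params$box_lengths <- as.numeric(obj$params$box_lengths)
  spec <- structure(obj, class = "scenario_spec")
  validate_scenario(spec)
  spec
}

# ---------------------------------------------------------------------------
# Spatial partitions
# ---------------------------------------------------------------------------

#' Spatial partition of the box into slabs or a 2D grid
#'
#' Slab partitions tile `[0, box)` with half-open cells `[x0, x0 + L)`; the
#' number of cells is `floor(box / L)` and the last cell absorbs any
#' remainder, so every wrapped position maps to exactly one cell.
#'
#' @param box Box length along x (slabs) or lengths `(Lx, Ly)` (grid).
#' @param L Cell size (slab width, or `(lx, ly)` for a grid).
#' @param mode `"slabs_x"` or `"grid2d"`.
#' @param origin Left edge of cell 0 (slabs only; default 0).
#' @return An object of class `region_partition`.
#' @examples
#' part <- region_partition(50.6, 4.6)
#' part$n_cells   # 11
#' @export
region_partition <- function(box, L, mode = c("slabs_x", "grid2d"),
                             origin = 0) {
  mode <- match.arg(mode)
  if (length(box) < 1 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be positive")
  if (length(L) < 1 || any(!is.finite(L)) || any(L <= 0))
    stop("cell size L must be positive")
  if (mode == "slabs_x") {
    box <- box[1]
    L <- min(L[1], box)
    n <- max(1L, as.integer(floor(box / L + 1e-9)))
    edges <- origin + c(seq(0, by = L, length.out = n), box - origin)
    structure(list(mode = mode, origin = origin, cell_size = L,
                   n_cells = n, edges = edges, box = box),
              class = "region_partition")
  } else {
    if (length(box) != 2) stop("grid2d needs box = (Lx, Ly)")
    if (length(L) == 1) L <- c(L, L)
    n <- pmax(1L, as.integer(floor(box / L + 1e-9)))
    structure(list(mode = mode, origin = c(0, 0), cell_size = box / n,
                   n_cells = n, box = box),
              class = "region_partition")
  }
}

#' Assign particles to partition cells
#'
#' Positions are wrapped into the periodic box before assignment; the
#' half-open cell convention makes the assignment deterministic, and the
#' multiset of assigned particles over all cells is exactly the particle set.
#'
#' @param state A `sim_state`.
#' @param part A `region_partition`.
#' @return Integer cell indices (1-based; row-major `iy * nx + ix` for grids).
#' @export
assign_bins <- function(state, part) {
  if (any(!is.finite(state$x)) || any(!is.finite(state$y)))
    stop("non-finite particle position")
  xw <- state$x %% part$box[1]
  if (part$mode == "slabs_x") {
    idx <- findInterval(xw, part$edges, rightmost.closed = FALSE,
                        left.open = FALSE)
    pmin.int(pmax.int(idx, 1L), part$n_cells)
  } else {
    nx <- part$n_cells[1]; ny <- part$n_cells[2]
    ix <- pmin.int(pmax.int(floor(xw / part$cell_size[1]), 0), nx - 1)
    yw <- (state$y + part$box[2] / 2) %% part$box[2]
    iy <- pmin.int(pmax.int(floor(yw / part$cell_size[2]), 0), ny - 1)
    as.integer(iy * nx + ix + 1)
  }
}

# ---------------------------------------------------------------------------
# States
# ---------------------------------------------------------------------------

#' Construct a simulation state
#'
#' @param x,y,px,py Numeric per-particle coordinates and momenta.
#' @param c Integer color charges in `{-1, 0, 1}` (0 for wall atoms).
#' @param wall Integer 0/1 wall flags.
#' @param ax,ay Tether anchor coordinates (wall atoms; `NA`-free zeros for
#'   fluid particles, whose anchors are ignored).
#' @param xi Ornstein-Uhlenbeck propulsion values (active scenario).
#' @param time Simulation time of the snapshot.
#' @return A `sim_state`.
#' @export
sim_state <- function(x, y, px = numeric(length(x)), py = numeric(length(x)),
                      c = integer(length(x)), wall = integer(length(x)),
                      ax = numeric(length(x)), ay = numeric(length(x)),
                      xi = numeric(length(x)), time = 0) {
  st <- structure(list(x = as.numeric(x), y = as.numeric(y),
                       px = as.numeric(px), py = as.numeric(py),
                       c = as.integer(c), wall = as.integer(wall),
                       ax = as.numeric(ax), ay = as.numeric(ay),
                       xi = as.numeric(xi), time = time),
                  class = "sim_state")
  validate_state(st)
  st
}

#' Validate a simulation state
#'
#' Checks the shared per-particle array length, charge values, the rule that
#' wall atoms carry no color charge, and that fluid charges alternate so the
#' net charge is in `{-1, 0, 1}`.
#'
#' @param state A `sim_state`.
#' @param spec Optional `scenario_spec`; if given, positions are additionally
#'   checked to lie inside the (wrapped) box.
#' @return The state, invisibly.
#' @export
validate_state <- function(state, spec = NULL) {
  n <- length(state$x)
  if (n < 1) stop("state must contain at least one particle")
  lens <- vapply(state[c("y", "px", "py", "c", "wall", "ax", "ay", "xi")],
                 length, 1L)
  if (any(lens != n)) stop("per-particle arrays have mismatched lengths")
  if (!all(state$c %in% c(-1L, 0L, 1L))) stop("color charges must be -1, 0, or 1")
  if (!all(state$wall %in% c(0L, 1L))) stop("wall flags must be 0/1")
  if (any(state$c[state$wall == 1L] != 0L))
    stop("wall particles must have zero color charge")
  if (abs(sum(state$c[state$wall == 0L])) > 1L)
    stop("fluid color charges must alternate (net charge in {-1, 0, +1})")
  if (any(!is.finite(state$x)) || any(!is.finite(state$y)))
    stop("non-finite particle position")
  if (!is.null(spec)) {
    b <- spec$params$box_lengths
    if (any(state$x < 0) || any(state$x >= b[1]))
      stop("x positions outside the periodic box [0, Lx)")
    if (any(abs(state$y) > b[2] / 2))
      stop("y positions outside the box")
  }
  invisible(state)
}

# candidate fluid lattice sites for a scenario (positions only)
.fluid_lattice <- function(spec) {
  b <- spec$params$box_lengths
  s <- 1 / sqrt(spec$density)
  if (spec$kind == "channel") {
    g <- spec$geometry
    nx <- max(1L, floor(b[1] / s))
    sx <- b[1] / nx
    xs <- (seq_len(nx) - 0.5) * sx
    pts <- NULL
    for (x0 in xs) {
      h <- .channel_halfwidth(x0, g$width, g$amplitude, b[1]) - 1.0
      if (h <= s / 4) next
      nyr <- max(1L, floor(2 * h / s) + 1L)
      ys <- if (nyr == 1L) 0 else seq(-h, h, length.out = nyr)
      pts <- rbind(pts, cbind(x0, ys))
    }
    pts
  } else if (spec$kind == "obstacle") {
    nx <- max(1L, floor(b[1] / s)); ny <- max(1L, floor(b[2] / s))
    gx <- (seq_len(nx) - 0.5) * (b[1] / nx)
    gy <- (seq_len(ny) - 0.5) * (b[2] / ny) - b[2] / 2
    pts <- as.matrix(expand.grid(gx, gy))
    cx <- b[1] / 2
    keep <- sqrt((pts[, 1] - cx)^2 + pts[, 2]^2) > spec$geometry$R + 1.0
    pts[keep, , drop = FALSE]
  } else {
    ntar <- round(spec$density * b[1] * b[2])
    k <- ceiling(sqrt(ntar))
    gx <- (seq_len(k) - 0.5) * (b[1] / k)
    gy <- (seq_len(k) - 0.5) * (b[2] / k) - b[2] / 2
    pts <- as.matrix(expand.grid(gx, gy))
    pts[seq_len(min(ntar, nrow(pts))), , drop = FALSE]
  }
}

.channel_halfwidth <- function(x, width, amplitude, Lx) {
  width / 2 - amplitude * sin(pi * x / Lx)^2
}

#' Build an initial (lattice) state for a scenario
#'
#' Fluid particles start on a lattice at the scenario density with alternating
#' color charges \eqn{c_i = (-1)^i}; channel wall atoms sit on their tether
#' anchors.  Momenta are zero (the equilibration stage draws them from the
#' Maxwell distribution) unless `seed` is given, in which case they are drawn
#' at temperature \eqn{1/\beta}.
#'
#' @param spec A `scenario_spec`.
#' @param seed Optional integer seed for Maxwell momenta.
#' @return A `sim_state`.
#' @export
make_initial_state <- function(spec, seed = NULL) {
  validate_scenario(spec)
  pts <- .fluid_lattice(spec)
  nf <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]
  cc <- rep_len(c(1L, -1L), nf)
  wallf <- rep(0L, nf)
  ax <- numeric(nf); ay <- numeric(nf)
  if (spec$kind == "channel") {
    w <- build_channel_walls(spec$geometry, spec$params$box_lengths)
    x <- c(x, w$anchors[, 1]); y <- c(y, w$anchors[, 2])
    cc <- c(cc, rep(0L, w$n_wall))
    wallf <- c(wallf, rep(1L, w$n_wall))
    ax <- c(ax, w$anchors[, 1]); ay <- c(ay, w$anchors[, 2])
  }
  n <- length(x)
  px <- py <- numeric(n)
  if (!is.null(seed)) {
    set.seed(seed)
    sdv <- sqrt(1 / spec$params$inverse_temperature)
    px <- rnorm(n, 0, sdv); py <- rnorm(n, 0, sdv)
  }
  xi <- if (spec$activity_enabled && !is.null(seed))
    rnorm(n, 0, spec$params$ou_amplitude) else numeric(n)
  sim_state(x = x %% spec$params$box_lengths[1], y = y, px = px, py = py,
            c = cc, wall = wallf, ax = ax, ay = ay, xi = xi)
}

# scenario -> flat parameter list for the C++ kernels
.spec_to_par <- function(spec) {
  b <- spec$params$box_lengths
  list(
    kind = match(spec$kind, .scenario_kinds) - 1L,
    Fe = spec$params$field_strength,
    beta = spec$params$inverse_temperature,
    k = spec$params$spring_constant,
    tau = spec$params$ou_relaxation,
    sigma_noise = spec$params$ou_amplitude,
    Lx = b[1], Ly = b[2],
    periodic_y = (spec$kind != "channel"),
    has_obstacle = (spec$kind == "obstacle"),
    obstacle_R = if (spec$kind == "obstacle") spec$geometry$R else 0,
    obstacle_cx = b[1] / 2,
    obstacle_cy = 0
  )
}

# default fine recording resolution: ~0.1 sigma cells
.default_n_fine <- function(spec) as.integer(round(spec$params$box_lengths[1] / 0.1))
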