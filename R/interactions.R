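# Force-field wrappers.  The actual kernels live in src/simulator.cpp; these
# entry points expose each contribution separately so it can be checked
# against finite differences and closed forms.

.state_for_cpp <- function(state) {
  state[c("x", "y", "px", "py", "c", "wall", "ax", "ay", "xi")]
}

.par_for_forces <- function(box, k = 0, Fe = 0, obstacle = NULL,
                            periodic_y = TRUE) {
  list(kind = 1L, Fe = Fe, beta = 1, k = k, tau = 0.1, sigma_noise = 0.1,
       Lx = box[1], Ly = if (length(box) > 1) box[2] else box[1],
       periodic_y = periodic_y,
       has_obstacle = !is.null(obstacle),
       obstacle_R = if (is.null(obstacle)) 0 else obstacle$R,
       obstacle_cx = if (is.null(obstacle)) 0 else obstacle$center[1],
       obstacle_cy = if (is.null(obstacle)) 0 else obstacle$center[2])
}

#' WCA pair forces and energy
#'
#' Purely repulsive Weeks-Chandler-Andersen interaction,
#' \eqn{U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma} and zero beyond, with minimum-image distances
#' (periodic in x; in y only if `periodic_y`).  Pairs of wall atoms do not
#' interact (tethered wall atoms confine the fluid but are anchored to a
#' lattice whose spacing is below the WCA cutoff).
#'
#' @param state A `sim_state`.
#' @param box Box lengths `(Lx, Ly)`.
#' @param periodic_y Apply minimum image along y (FALSE for the channel).
#' @return `list(forces = N x 2 matrix, energy = scalar)`.  Forces obey
#'   Newton's third law pairwise and sum to zero.
#' @export
wca_pair <- function(state, box, periodic_y = TRUE) {
  r <- cpp_eval_forces(.state_for_cpp(state),
                       .par_for_forces(box, periodic_y = periodic_y))
  list(forces = r$pair_forces, energy = r$pair_energy)
}

#' Harmonic tether forces on wall atoms
#'
#' \eqn{F_i = -k (q_i - q_{0,i})} for wall atoms; zero for fluid particles.
#' The displacement is taken with the minimum-image convention along x so a
#' tether never spans the periodic boundary.
#'
#' @param state A `sim_state`; wall atoms must carry anchors in `ax`, `ay`.
#' @param k Spring constant.
#' @param box Box lengths.
#' @return `list(forces, energy)`.
#' @export
tether_force <- function(state, k, box) {
  if (any(state$wall == 1L & (!is.finite(state$ax) | !is.finite(state$ay))))
    stop("wall particle without a tether anchor")
  r <- cpp_eval_forces(.state_for_cpp(state),
                       .par_for_forces(box, k = k, periodic_y = FALSE))
  list(forces = r$tether_forces, energy = r$tether_energy)
}

#' Repulsive disk-obstacle forces
#'
#' WCA interaction applied to the surface distance \eqn{d = |q - c| - R}
#' (cutoff \eqn{d < 2^{1/6}}), radial and purely repulsive, continuous at the
#' cutoff.  A particle at or inside the obstacle surface is an error.
#'
#' @param state A `sim_state`.
#' @param center Obstacle center `(x, y)`.
#' @param R Obstacle radius (> 0).
#' @param box Box lengths.
#' @return `list(forces, energy)`.
#' @export
obstacle_force <- function(state, center, R, box) {
  if (!is.numeric(R) || R <= 0) stop("obstacle radius R must be positive")
  r <- cpp_eval_forces(.state_for_cpp(state),
                       .par_for_forces(box, obstacle = list(center = center,
                                                            R = R)))
  list(forces = r$obstacle_forces, energy = r$obstacle_energy)
}

#' Color-field forces
#'
#' \eqn{F_i = c_i F_e e_x}: the driving couples to the per-particle color
#' charge along x; charges do not interact with each other, and wall atoms
#' (charge 0) feel no drive.
#'
#' @param state A `sim_state`.
#' @param F_e Field strength (>= 0).
#' @return N x 2 force matrix.
#' @export
color_force <- function(state, F_e) {
  cbind(state$c * F_e, numeric(length(state$x)))
}

#' Construct tethered channel walls
#'
#' Two single-layer rows of wall-atom anchor sites follow the channel profile
#' \eqn{y_{wall}(x) = \pm[W_0/2 - a \sin^2(\pi x / L_x)]}: the channel is
#' widest at the box edges and narrowest at the center \eqn{x = L_x/2}.
#'
#' @param profile List with `width` (\eqn{W_0}), `amplitude` (\eqn{a}, must be
#'   `< width/2`), `wall_spacing` (target anchor spacing along x, ~1).
#' @param box Box lengths `(Lx, Ly)`.
#' @return `list(anchors = n x 2 matrix, n_wall, halfwidth = function(x))`.
#' @export
build_channel_walls <- function(profile, box) {
  W0 <- profile$width; a <- profile$amplitude
  if (a >= W0 / 2) stop("channel pinches closed: amplitude must be < width/2")
  if (a < 0) stop("amplitude must be >= 0")
  Lx <- box[1]
  nw <- max(2L, round(Lx / profile$wall_spacing))
  xs <- (seq_len(nw) - 1) * (Lx / nw)
  h <- .channel_halfwidth(xs, W0, a, Lx)
  anchors <- rbind(cbind(xs, h), cbind(xs, -h))
  list(anchors = anchors, n_wall = nrow(anchors),
       halfwidth = function(x) .channel_halfwidth(x, W0, a, Lx))
}

#' Write a configuration as extended XYZ
#'
#' One frame with per-atom columns: species (F fluid / W wall), position,
#' momentum, color charge, wall flag and propulsion value.
#'
#' @param state A `sim_state`.
#' @param path Output file.
#' @param box Box lengths for the lattice header.
#' @param comment Extra key-value string appended to the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(state, path, box, comment = "") {
  n <- length(state$x)
  hdr <- sprintf(
    'Lattice="%g 0.0 0.0 0.0 %g 0.0 0.0 0.0 1.0" Properties=species:S:1:pos:R:2:momenta:R:2:color:I:1:wall:I:1:xi:R:1 %s',
    box[1], if (length(box) > 1) box[2] else box[1], comment)
  lines <- sprintf("%s %.10g %.10g %.10g %.10g %d %d %.10g",
                   ifelse(state$wall == 1L, "W", "F"),
                   state$x, state$y, state$px, state$py,
                   state$c, state$wall, state$xi)
  writeLines(c(as.character(n), hdr, lines), path)
  invisible(path)
}
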