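# Trajectory-ensemble statistics for the local fluctuation theorem.
#
# The local fluctuation theorem states
#     ln[ p(Omega_{L,t} = A) / p(Omega_{L,t} = -A) ] = (1 + kappa_{L,t}) A,
# where kappa is the regression coefficient of the surroundings' dissipation
# Omega* on the local dissipation Omega_L:
#     kappa = Cov(Omega*, Omega_L) / Var(Omega_L).
# kappa -> 0 as the local region grows to the whole system (global theorem);
# for small regions correlations with the surroundings tilt the slope.

#' Local-surroundings correlation coefficient kappa
#'
#' \eqn{\kappa_{L,t} = [\langle\Omega^*\Omega_L\rangle -
#' \langle\Omega^*\rangle\langle\Omega_L\rangle] /
#' [\langle\Omega_L^2\rangle - \langle\Omega_L\rangle^2]}, i.e. the sample
#' covariance of the complement with the local dissipation divided by the
#' local variance.  The standard error is estimated by a seeded bootstrap
#' over trajectories.
#'
#' @param local Per-trajectory local dissipation \eqn{\Omega_{L,t}}.
#' @param complement Per-trajectory complement \eqn{\Omega^*_{L,t}}.
#' @param n_boot Bootstrap resamples (0 to skip).
#' @param seed Bootstrap seed.
#' @return `list(kappa, stderr, n)`.
#' @export
kappa <- function(local, complement, n_boot = 1000, seed = 1) {
  n <- length(local)
  if (length(complement) != n) stop("local and complement lengths differ")
  if (n < 10) stop("need at least 10 trajectories")
  v <- var(local)
  if (!is.finite(v) || v <= 0) stop("zero variance of local dissipation")
  k <- cov(complement, local) / v
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    ks <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      vv <- var(local[i])
      if (vv <= 0) return(NA_real_)
      cov(complement[i], local[i]) / vv
    }, 1.0)
    se <- sd(ks, na.rm = TRUE)
  }
  list(kappa = k, stderr = se, n = n)
}

# Freedman-Diaconis width on pooled |x|, forced symmetric about 0
.fd_width <- function(x) {
  ax <- abs(x)
  w <- 2 * IQR(ax) / length(ax)^(1/3)
  if (!is.finite(w) || w <= 0) w <- diff(range(x)) / 50
  w
}

#' Asymmetry function of a dissipation ensemble
#'
#' Histograms the samples in bins of width `bin_width` symmetric about zero
#' (edges at integer multiples of the width) and, for every positive bin
#' center A whose +A and -A bins both hold at least `min_count` samples,
#' forms \eqn{\ln[count(A)/count(-A)]} with Poisson-propagated standard error
#' \eqn{\sqrt{1/n_+ + 1/n_-}}.  The slope of the predicted line through the
#' origin is fitted by inverse-variance weighted least squares.
#'
#' When negative events are rare (wide bins / strong driving) the
#' Freedman-Diaconis width can leave the negative tail below `min_count`; in
#' that regime a default-width fit doubles the bin width (at most six times)
#' until the tail supports at least one pairable bin.  An explicitly supplied
#' `bin_width` is never widened.
#'
#' @param samples Per-trajectory dissipation values.
#' @param bin_width Histogram bin width; default: Freedman-Diaconis on the
#'   pooled absolute values, adaptively doubled for rare negative tails.
#' @param min_count Minimum count per side for a usable point.
#' @return An `asymmetry_curve` with fields `A`, `log_ratio`, `stderr`,
#'   `slope`, `slope_err`, `n_points`, `bin_width`.
#' @export
asymmetry_function <- function(samples, bin_width = NULL, min_count = 10) {
  samples <- samples[is.finite(samples)]
  adaptive <- is.null(bin_width)
  if (adaptive) bin_width <- .fd_width(samples)
  if (bin_width <= 0) stop("bin_width must be positive")
  neg <- sum(samples < 0)
  if (neg < min_count)
    stop("insufficient negative events to form the asymmetry function ",
         "(", neg, " samples below zero); the ensemble is in the ",
         "global-FT regime where negative dissipation is essentially unobserved")
  if (adaptive) {
    tries <- 0L
    while (sum(samples < 0 & samples >= -bin_width) < min_count &&
           tries < 6L) {
      bin_width <- 2 * bin_width
      tries <- tries + 1L
    }
  }
  # bin index: k in Z, bin k covers [k*w, (k+1)*w); center (k + 1/2) * w
  k <- floor(samples / bin_width)
  tab <- table(k)
  kk <- as.integer(names(tab))
  counts <- as.integer(tab)
  names(counts) <- kk
  kpos <- kk[kk >= 0]
  A <- lr <- se <- numeric(0)
  for (kp in kpos) {
    cpos <- counts[as.character(kp)]
    cneg <- counts[as.character(-kp - 1L)]
    if (is.na(cneg)) next
    if (cpos < min_count || cneg < min_count) next
    A <- c(A, (kp + 0.5) * bin_width)
    lr <- c(lr, log(cpos / cneg))
    se <- c(se, sqrt(1 / cpos + 1 / cneg))
  }
  if (length(A) == 0)
    stop("no bin pair reaches min_count on both sides")
  w <- 1 / se^2
  slope <- sum(w * A * lr) / sum(w * A^2)
  slope_err <- 1 / sqrt(sum(w * A^2))
  structure(list(A = A, log_ratio = lr, stderr = se,
                 slope = slope, slope_err = slope_err,
                 n_points = length(A), bin_width = bin_width,
                 n_samples = length(samples)),
            class = "asymmetry_curve")
}

#' @export
print.asymmetry_curve <- function(x, ...) {
  cat("<asymmetry_curve>", x$n_points, "points, bin width",
      signif(x$bin_width, 3), "\n")
  cat("  slope =", signif(x$slope, 4), "+/-", signif(x$slope_err, 3), "\n")
  invisible(x)
}

#' Bootstrap standard error of the asymmetry slope
#'
#' Resamples trajectories with replacement and refits the origin-constrained
#' weighted slope, keeping the bin width of the original fit.
#'
#' @param samples The ensemble passed to [asymmetry_function()].
#' @param curve The fitted `asymmetry_curve`.
#' @param n_boot Number of resamples.
#' @param seed Seed.
#' @param min_count Minimum count per side.
#' @return Standard error of the slope (NA if too few resamples succeed).
#' @export
asymmetry_slope_boot <- function(samples, curve, n_boot = 1000, seed = 1,
                                 min_count = 10) {
  set.seed(seed)
  n <- length(samples)
  sl <- vapply(seq_len(n_boot), function(b) {
    s <- samples[sample.int(n, n, replace = TRUE)]
    out <- tryCatch(
      asymmetry_function(s, bin_width = curve$bin_width,
                         min_count = min_count)$slope,
      error = function(e) NA_real_)
    out
  }, 1.0)
  if (mean(is.na(sl)) > 0.5) return(NA_real_)
  sd(sl, na.rm = TRUE)
}

#' Check the local fluctuation theorem
#'
#' Compares the fitted asymmetry slope with the prediction
#' \eqn{1 + \kappa_{L,t}} and reports the discrepancy in combined standard
#' errors, flagging consistency at the 3-sigma level.
#'
#' @param curve An `asymmetry_curve`.
#' @param kappa Estimated correlation coefficient.
#' @param kappa_err Its standard error.
#' @return `list(slope, slope_err, predicted, predicted_err, discrepancy_sigma,
#'   consistent)`.
#' @export
local_ft_check <- function(curve, kappa, kappa_err) {
  pred <- 1 + kappa
  comb <- sqrt(curve$slope_err^2 + kappa_err^2)
  z <- abs(curve$slope - pred) / comb
  list(slope = curve$slope, slope_err = curve$slope_err,
       predicted = pred, predicted_err = kappa_err,
       discrepancy_sigma = z, consistent = (z <= 3))
}

#' kappa as a function of the local region size L
#'
#' @param ensembles Named list; each element is `list(local=, complement=)`
#'   per-trajectory dissipation vectors for one L (names are the L values).
#' @param n_boot,seed Bootstrap settings passed to [kappa()].
#' @param fit Optional generic parametric fit: a function `f(L, par)` plus
#'   starting values, passed as `list(f=, start=)`; fitted by unweighted
#'   least squares with [stats::optim()].  No functional form is built in.
#' @return A `kappa_scan` data frame with columns `L`, `kappa`, `stderr`,
#'   `n`, and optionally an attribute `fit` with the fitted parameters.
#' @export
kappa_scan <- function(ensembles, n_boot = 1000, seed = 1, fit = NULL) {
  if (length(ensembles) < 2) stop("kappa scan needs at least 2 distinct L values")
  Ls <- as.numeric(names(ensembles))
  if (any(!is.finite(Ls))) stop("ensemble names must be the L values")
  rows <- lapply(seq_along(ensembles), function(i) {
    k <- kappa(ensembles[[i]]$local, ensembles[[i]]$complement,
               n_boot = n_boot, seed = seed + i)
    data.frame(L = Ls[i], kappa = k$kappa, stderr = k$stderr, n = k$n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$L), ]
  class(out) <- c("kappa_scan", "data.frame")
  if (!is.null(fit)) {
    obj <- function(par) sum((out$kappa - fit$f(out$L, par))^2)
    attr(out, "fit") <- stats::optim(fit$start, obj)
  }
  out
}

#' Spatial map of local dissipation or entropy production
#'
#' Per-cell ensemble means and standard errors of the integrated dissipation
#' (or entropy production), the integrated current, and the time-averaged
#' particle count, on a 2D grid.  Cells that never contain a particle are
#' reported as missing, not zero.
#'
#' @param cell_omega n_traj x n_cells matrix of per-trajectory per-cell
#'   integrated dissipation.
#' @param cell_navg Per-cell ensemble-mean time-averaged particle counts.
#' @param grid A `region_partition` with `mode = "grid2d"`.
#' @return A `dissipation_map`: `list(grid, mean, stderr, n_avg, count)` where
#'   the matrices are nx x ny (row index = x cell).
#' @export
dissipation_map <- function(cell_omega, cell_navg, grid) {
  if (grid$mode != "grid2d") stop("dissipation_map needs a grid2d partition")
  nx <- grid$n_cells[1]; ny <- grid$n_cells[2]
  if (ncol(cell_omega) != nx * ny) stop("cell matrix does not match grid")
  mu <- colMeans(cell_omega)
  se <- apply(cell_omega, 2, sd) / sqrt(nrow(cell_omega))
  empty <- cell_navg < 1e-9
  mu[empty] <- NA_real_
  se[empty] <- NA_real_
  list(grid = grid,
       mean = matrix(mu, nx, ny),
       stderr = matrix(se, nx, ny),
       n_avg = matrix(cell_navg, nx, ny),
       count = matrix(ifelse(empty, 0, nrow(cell_omega)), nx, ny))
}

#' Synthetic Gaussian dissipation fixture
#'
#' MD-free test harness for the statistics layer: draws
#' \eqn{\Omega_L \sim N(\mu_L, v_L)} and a complement
#' \eqn{\Omega^* = \kappa_{true}(\Omega_L - \mu_L) + \mu^* + noise} so the
#' population \eqn{Cov(\Omega^*, \Omega_L)/Var(\Omega_L) = \kappa_{true}}.
#' With `ft_consistent = TRUE` the mean is set to
#' \eqn{\mu_L = v_L (1 + \kappa_{true}) / 2}, which makes the ensemble
#' satisfy the local fluctuation theorem exactly in distribution (a Gaussian
#' has \eqn{\ln p(A)/p(-A) = 2\mu A / v}).
#'
#' @param n Number of trajectories.
#' @param mu_L Mean of the local dissipation (ignored if `ft_consistent`).
#' @param v_L Variance of the local dissipation (> 0).
#' @param kappa_true Target correlation coefficient.
#' @param seed Seed.
#' @param ft_consistent Enforce \eqn{2\mu_L/v_L = 1 + \kappa_{true}}.
#' @param mu_star Mean of the complement (default \eqn{\kappa_{true}\mu_L}).
#' @param noise_sd Standard deviation of the independent noise added to the
#'   complement (default \eqn{\sqrt{v_L}}).
#' @return `list(local, complement, mu_L, v_L, kappa_true)`.
#' @export
gaussian_fixture <- function(n, mu_L = 1, v_L = 2, kappa_true = 0, seed = 1,
                             ft_consistent = FALSE, mu_star = NULL,
                             noise_sd = NULL) {
  if (!is.finite(v_L) || v_L <= 0) stop("variance v_L must be positive")
  if (ft_consistent) mu_L <- v_L * (1 + kappa_true) / 2
  if (is.null(mu_star)) mu_star <- kappa_true * mu_L
  if (is.null(noise_sd)) noise_sd <- sqrt(v_L)
  set.seed(seed)
  local <- rnorm(n, mu_L, sqrt(v_L))
  complement <- kappa_true * (local - mu_L) + mu_star + rnorm(n, 0, noise_sd)
  list(local = local, complement = complement,
       mu_L = mu_L, v_L = v_L, kappa_true = kappa_true)
}
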