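#' Monte Carlo ensemble simulation of the network SDE
#'
#' Ground-truth reference for the closure: Euler-Maruyama integration of
#' \deqn{\tau_j dx_j = (-x_j + \tilde\mu_j(t) + \textstyle\sum_k g_{jk}
#'   F_k(x_k))\,dt + \tilde\sigma_j(t)\,dW_j,}
#' where the Wiener increments are instantaneously correlated,
#' \eqn{\langle dW_j dW_k\rangle = c_{jk}\,dt} (realized through a symmetric
#' square-root factor of \eqn{Cr}, with round-off-negative eigenvalues
#' clipped at zero). Realizations start from the uncoupled Gaussian steady
#' state at the initial-time inputs and are relaxed for \code{burn_in} time
#' units before the first recorded time, so recorded statistics start from a
#' genuinely equilibrated ensemble. At each requested time all six statistic
#' families are computed across realizations (firing statistics from the
#' per-realization \eqn{F_j(x_j)}), together with the error-band half-width
#' \eqn{S}: the sample standard deviation, across disjoint groups of
#' \code{group_size} realizations, of the per-group statistic (see
#' \code{\link{error_bands}}).
#'
#' @param spec a \code{\link{network_spec}}.
#' @param times increasing times at which to record statistics; must lie on
#'   the \code{dt} grid.
#' @param n_realizations ensemble size; rounded down to a multiple of
#'   \code{group_size} (at least two groups).
#' @param dt Euler-Maruyama step; default \code{0.01 * min(tau)}, and must
#'   not exceed \code{min(tau)/10}.
#' @param seed integer seed; the estimate is deterministic given the seed.
#' @param group_size realizations per error-band group (default 1000).
#' @param burn_in relaxation time before \code{times[1]} (default
#'   \code{5 * max(tau)}).
#' @return An object of class \code{ensemble_estimate}: fields
#'   \code{trajectory} (a \code{\link{stat_trajectory}} with method
#'   \code{"monte_carlo"}), \code{bands} (a named list over
#'   \code{\link{stat_families}} of matrices of \eqn{S}, same shapes as the
#'   trajectory blocks), \code{n_realizations}, \code{n_groups},
#'   \code{group_size}, \code{dt}, \code{seed}, \code{burn_in}.
#' @export
simulate_ensemble <- function(spec, times, n_realizations, dt = NULL, seed,
                              group_size = 1000L, burn_in = NULL) {
  stopifnot(inherits(spec, "network_spec"), all(diff(times) > 0),
            n_realizations >= 2L, group_size >= 1L)
  n <- spec$n_cells
  if (is.null(dt)) dt <- 0.01 * min(spec$tau)
  if (dt > min(spec$tau) / 10)
    stop("simulate_ensemble: dt must be <= min(tau)/10")
  if (is.null(burn_in)) burn_in <- 5 * max(spec$tau)
  stopifnot(burn_in >= 0)
  n_groups <- n_realizations %/% group_size
  if (n_groups < 2L)
    stop("simulate_ensemble: need at least 2 groups of ", group_size,
         " realizations for error bands")
  n_real <- n_groups * group_size

  burn_steps <- as.integer(ceiling(burn_in / dt - 1e-9))
  t_start <- times[1] - burn_steps * dt
  burn_in <- burn_steps * dt
  n_steps <- as.integer(round((times[length(times)] - t_start) / dt))
  rec <- burn_steps + as.integer(round((times - times[1]) / dt))
  if (max(abs(t_start + rec * dt - times)) > 1e-6 * dt)
    stop("simulate_ensemble: 'times' must lie on the dt grid")

  step_t <- t_start + dt * (0:(n_steps - 1))
  mu_path <- matrix(0, n_steps, n)
  sigma_path <- matrix(0, n_steps, n)
  for (s in seq_len(n_steps)) {
    inp <- eval_input(spec, step_t[s])
    mu_path[s, ] <- inp$mu
    sigma_path[s, ] <- inp$sigma
  }

  L <- .psd_sqrt(spec$corr)
  inp0 <- eval_input(spec, t_start)
  cov0 <- spec$corr * outer(inp0$sigma, inp0$sigma) /
    outer(spec$tau, spec$tau, "+")
  L0 <- .psd_sqrt(cov0)

  set.seed(seed)
  x0 <- matrix(stats::rnorm(n_real * n), n_real, n) %*% t(L0)
  x0 <- sweep(x0, 2, inp0$mu, "+")

  fiv <- .fi_vectors(spec)
  raw <- .em_ensemble_cpp(x0, spec$tau, spec$coupling, L, fiv$x_rev,
                          fiv$x_sp, mu_path, sigma_path, dt, rec,
                          as.integer(group_size))

  pr <- pair_index(n)
  nt <- length(times)
  mean_x <- raw$sum_x / n_real
  mean_nu <- raw$sum_F / n_real
  var_x <- var_nu <- matrix(0, nt, n)
  cov_x <- cov_nu <- matrix(0, nt, nrow(pr))
  for (i in seq_len(nt)) {
    Cx <- raw$sum_xx[, , i] / n_real - outer(mean_x[i, ], mean_x[i, ])
    Cf <- raw$sum_FF[, , i] / n_real - outer(mean_nu[i, ], mean_nu[i, ])
    var_x[i, ] <- diag(Cx)
    var_nu[i, ] <- diag(Cf)
    if (nrow(pr)) {
      cov_x[i, ] <- Cx[pr]
      cov_nu[i, ] <- Cf[pr]
    }
  }
  traj <- stat_trajectory(times, mean_x, var_x, cov_x, mean_nu, var_nu,
                          cov_nu, method = "monte_carlo")

  band_of <- function(gcube, n_items) {
    # gcube: n_groups x items x n_out; S per (time, item)
    out <- matrix(0, nt, n_items)
    if (n_items == 0L) return(out)
    for (i in seq_len(nt))
      out[i, ] <- apply(gcube[, seq_len(n_items), i, drop = FALSE], 2,
                        stats::sd)
    out
  }
  bands <- list(mean_x = band_of(raw$gmean_x, n),
                var_x = band_of(raw$gvar_x, n),
                cov_x = band_of(raw$gcov_x, nrow(pr)),
                mean_nu = band_of(raw$gmean_F, n),
                var_nu = band_of(raw$gvar_F, n),
                cov_nu = band_of(raw$gcov_F, nrow(pr)))

  structure(list(trajectory = traj, bands = bands,
                 n_realizations = n_real, n_groups = n_groups,
                 group_size = as.integer(group_size), dt = dt, seed = seed,
                 burn_in = burn_in),
            class = "ensemble_estimate")
}

#' @export
print.ensemble_estimate <- function(x, ...) {
  cat(sprintf("<ensemble_estimate> %d realizations (%d groups of %d), dt=%g, burn_in=%g\n",
              x$n_realizations, x$n_groups, x$group_size, x$dt, x$burn_in))
  print(x$trajectory)
  invisible(x)
}

# symmetric PSD square root with round-off clipping
.psd_sqrt <- function(M, tol = 1e-10) {
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) < -tol)
    stop("matrix factorization failed: eigenvalue ", min(ev$values),
         " below -", tol)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Error-band half-width
#'
#' The sample standard deviation over per-group statistic values,
#' \deqn{S = \sqrt{\frac{1}{n_g - 1}\sum_{j=1}^{n_g} (X(j) - \bar X)^2},}
#' where \eqn{X(j)} is the statistic computed from group \eqn{j} and
#' \eqn{\bar X} the grand mean; bands are reported as \eqn{\bar X \pm S}
#' (one standard deviation above and below).
#'
#' @param per_group_means numeric vector of at least two group values.
#' @return nonnegative scalar \eqn{S}.
#' @export
error_bands <- function(per_group_means) {
  if (length(per_group_means) < 2L)
    stop("error_bands: need at least 2 groups")
  xbar <- mean(per_group_means)
  sqrt(sum((per_group_means - xbar)^2) / (length(per_group_means) - 1))
}
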