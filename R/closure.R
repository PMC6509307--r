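#' Moment-closure state
#'
#' The state of the reduced system: per-cell means \eqn{\mu_j} and the full
#' symmetric matrix of raw second moments \eqn{E_{j,k} = \langle x_j x_k
#' \rangle} (diagonal \eqn{E_{j^2}}), i.e.
#' \eqn{N_c + N_c(N_c+1)/2} free variables.
#'
#' @param mu numeric vector of means.
#' @param second_moments symmetric matrix of raw second moments.
#' @return An object of class \code{moment_state}.
#' @export
moment_state <- function(mu, second_moments) {
  n <- length(mu)
  second_moments <- as.matrix(second_moments)
  stopifnot(all(is.finite(mu)), all(dim(second_moments) == c(n, n)),
            all(is.finite(second_moments)),
            max(abs(second_moments - t(second_moments))) < 1e-10)
  second_moments <- (second_moments + t(second_moments)) / 2
  v <- diag(second_moments) - mu^2
  if (any(v < -1e-8))
    warning("moment_state: derived variance negative beyond -1e-8 for cell(s) ",
            paste(which(v < -1e-8), collapse = ", "))
  structure(list(mu = as.numeric(mu), second_moments = second_moments),
            class = "moment_state")
}

# flat layout: c(mu, upper triangle of E incl. diagonal, column-major)
.ms_pack <- function(state) {
  E <- state$second_moments
  c(state$mu, E[upper.tri(E, diag = TRUE)])
}

.ms_unpack <- function(y, n) {
  mu <- y[seq_len(n)]
  E <- matrix(0, n, n)
  E[upper.tri(E, diag = TRUE)] <- y[-seq_len(n)]
  E <- E + t(E) - diag(diag(E), n)
  list(mu = mu, E = E)
}

#' Solver and closure configuration
#'
#' @param quad_order Gauss-Hermite order used wherever a plain
#'   \code{\link{gauss_hermite}} rule is requested (diagnostics); the
#'   production closure kernels use the adaptive panel scheme of
#'   \code{\link{e1}}, which has no tunable order.
#' @param rtol,atol relative/absolute tolerances of the adaptive RK45
#'   stepper.
#' @param init_mode \code{"steady_state_at_t0"} (default: start from the
#'   self-consistent equilibrium at the \eqn{t = 0} input values, so
#'   transients reflect only the time-varying drive) or
#'   \code{"user_supplied"}.
#' @param firing_corr correlation used in the output change of variables for
#'   the firing covariance: \code{"dynamic"} (default)
#'   \eqn{\rho_{jk}(t) = Cov_{jk}(t)/(\sigma_j\sigma_k)}, or
#'   \code{"static_input"} \eqn{\rho_{jk} = c_{jk}} (the closure's internal
#'   convention, selectable for ablation). The ODE right-hand side always
#'   uses the static input correlation \eqn{c_{jk}}, which is the method
#'   itself, not an option.
#' @return An object of class \code{closure_config}.
#' @export
closure_config <- function(quad_order = 40L, rtol = 1e-8, atol = 1e-10,
                           init_mode = c("steady_state_at_t0",
                                         "user_supplied"),
                           firing_corr = c("dynamic", "static_input")) {
  stopifnot(quad_order >= 1L, rtol > 0, atol > 0)
  structure(list(quad_order = as.integer(quad_order), rtol = rtol,
                 atol = atol, init_mode = match.arg(init_mode),
                 firing_corr = match.arg(firing_corr)),
            class = "closure_config")
}

# core derivative; fiv precomputed by callers
.closure_deriv <- function(mu, E, t, spec, fiv) {
  if (!all(is.finite(mu)) || !all(is.finite(E))) {
    bad <- if (all(is.finite(mu))) which(!is.finite(diag(E)))[1] else
      which(!is.finite(mu))[1]
    stop("closure_rhs: non-finite state (cell index ", bad, ") at t = ", t)
  }
  v <- diag(E) - mu^2
  if (any(v < -1e-8))
    stop("closure_rhs: variance below -1e-8 for cell ",
         which.min(v), " at t = ", t, " (closure breakdown)")
  sigma <- sqrt(pmax(v, 0))
  inp <- eval_input(spec, t)
  ex <- .closure_expectations(fiv, mu, sigma)
  tau <- spec$tau
  G <- spec$coupling
  Cr <- spec$corr
  gE1 <- as.numeric(G %*% ex$E1)
  H <- G %*% (ex$M1 * Cr)              # H[j,k] = sum_l g_jl M1_l c_lk
  dmu <- (-mu + inp$mu + gE1) / tau
  # A[j,k] = -E_jk + mu~_j(t) mu_k + mu_k (G E1)_j + sigma_k H_jk;
  # Eq. for E is (Cr s~_j s~_k + tau_k A_jk + tau_j A_kj) / (tau_j tau_k),
  # whose diagonal is exactly the second-moment equation (c_jj = 1).
  A <- -E + outer(inp$mu, mu) + outer(gE1, mu) +
    sweep(H, 2, sigma, "*")
  dE <- (Cr * outer(inp$sigma, inp$sigma) +
           sweep(A, 2, tau, "*") + sweep(t(A), 1, tau, "*")) / outer(tau, tau)
  list(dmu = dmu, dE = dE)
}

#' Right-hand side of the closure ODE system
#'
#' Implements the coupled kinetic equations for the means and raw second
#' moments under the pairwise-Gaussian closure:
#' \deqn{\dot\mu_j = (-\mu_j + \tilde\mu_j(t) + \sum_k g_{jk} E_1(k))/\tau_j,}
#' \deqn{\tau_j\tau_k \dot E_{j,k} = c_{jk}\tilde\sigma_j(t)\tilde\sigma_k(t)
#'   + \tau_k[-E_{j,k} + \tilde\mu_j(t)\mu_k + \sum_l g_{jl}(\mu_k E_1(l) +
#'     \sigma_k M_F(k,l))]
#'   + \tau_j[-E_{j,k} + \tilde\mu_k(t)\mu_j + \sum_l g_{kl}(\mu_j E_1(l) +
#'     \sigma_j M_F(j,l))],}
#' whose \eqn{j = k} case is the second-moment (variance-channel) equation.
#' The kernels \eqn{E_1}, \eqn{M_F} are evaluated at the instantaneous
#' \eqn{(\mu(t), \sigma(t))} with the static input correlation \eqn{c_{jk}}.
#'
#' @param state a \code{\link{moment_state}}.
#' @param t time.
#' @param spec a \code{\link{network_spec}}.
#' @param config a \code{\link{closure_config}}.
#' @return a \code{moment_state}-shaped list \code{(mu, second_moments)} of
#'   time derivatives.
#' @export
closure_rhs <- function(state, t, spec, config = closure_config()) {
  stopifnot(inherits(state, "moment_state"), inherits(spec, "network_spec"))
  d <- .closure_deriv(state$mu, state$second_moments, t, spec,
                      .fi_vectors(spec))
  list(mu = d$dmu, second_moments = d$dE)
}

#' Integrate the moment-closure ODE system
#'
#' Integrates \code{\link{closure_rhs}} over \code{times} with the adaptive
#' RK45 stepper (each unordered second-moment pair is integrated once, so
#' symmetry is exact by construction) and converts the resulting activity
#' statistics to firing statistics via \code{\link{activity_to_firing}}.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param config a \code{\link{closure_config}}.
#' @param times strictly increasing time grid; \code{times[1]} is the
#'   initial time.
#' @param init optional \code{\link{moment_state}} initial condition;
#'   default is the steady state at the \code{times[1]} input values.
#' @return a \code{\link{stat_trajectory}} with method tag
#'   \code{"closure"}.
#' @export
integrate_closure <- function(spec, config = closure_config(), times,
                              init = NULL) {
  stopifnot(inherits(spec, "network_spec"), all(diff(times) > 0))
  n <- spec$n_cells
  fiv <- .fi_vectors(spec)
  if (is.null(init)) {
    inp0 <- eval_input(spec, times[1])
    ss <- solve_steady_state(spec, mu_tilde = inp0$mu,
                             sigma_tilde = inp0$sigma)
    if (!ss$converged)
      stop("integrate_closure: default initial condition failed ",
           "(steady-state solve did not converge; supply 'init')")
    init <- moment_state(ss$mu, ss$cov + outer(ss$mu, ss$mu))
  }
  stopifnot(inherits(init, "moment_state"), length(init$mu) == n)
  rhs <- function(t, y) {
    s <- .ms_unpack(y, n)
    d <- .closure_deriv(s$mu, s$E, t, spec, fiv)
    c(d$dmu, d$dE[upper.tri(d$dE, diag = TRUE)])
  }
  sol <- .ode_rk45(rhs, .ms_pack(init), times,
                   rtol = config$rtol, atol = config$atol)
  mu <- sol[, seq_len(n), drop = FALSE]
  pr <- pair_index(n)
  var_x <- matrix(0, length(times), n)
  cov_x <- matrix(0, length(times), nrow(pr))
  for (i in seq_along(times)) {
    s <- .ms_unpack(sol[i, ], n)
    var_x[i, ] <- diag(s$E) - s$mu^2
    if (nrow(pr))
      cov_x[i, ] <- s$E[pr] - s$mu[pr[, 1]] * s$mu[pr[, 2]]
  }
  activity_to_firing(list(times = times, mean_x = mu, var_x = var_x,
                          cov_x = cov_x),
                     spec, config, method = "closure")
}

#' Convert activity statistics to firing statistics
#'
#' The change of variables \eqn{\nu_j = F_j(x_j)} under the Gaussian
#' closure: \eqn{\nu_j = E_1(j)}, \eqn{Var(\nu_j) = E_2(j) - \nu_j^2}, and
#' \eqn{Cov(\nu_j, \nu_k) = \langle F_j F_k\rangle(\rho_{jk}) -
#' \nu_j\nu_k} with \eqn{\rho_{jk}} chosen per
#' \code{config$firing_corr} (dynamic activity correlation by default).
#'
#' @param activity a \code{\link{stat_trajectory}} or a list with fields
#'   \code{times}, \code{mean_x}, \code{var_x}, \code{cov_x}.
#' @param spec a \code{\link{network_spec}}.
#' @param config a \code{\link{closure_config}}.
#' @param method provenance tag for the returned trajectory.
#' @return a complete \code{\link{stat_trajectory}}.
#' @export
activity_to_firing <- function(activity, spec, config = closure_config(),
                               method = "closure") {
  stopifnot(inherits(spec, "network_spec"))
  times <- activity$times
  mean_x <- rbind(activity$mean_x)
  var_x <- rbind(activity$var_x)
  cov_x <- rbind(activity$cov_x)
  n <- spec$n_cells
  pr <- pair_index(n)
  if (any(var_x < -1e-8))
    stop("activity_to_firing: negative activity variance beyond -1e-8")
  var_x_c <- pmax(var_x, 0)
  fiv <- .fi_vectors(spec)
  nt <- length(times)
  mean_nu <- var_nu <- matrix(0, nt, n)
  cov_nu <- matrix(0, nt, nrow(pr))
  for (i in seq_len(nt)) {
    sigma <- sqrt(var_x_c[i, ])
    ex <- .closure_expectations(fiv, mean_x[i, ], sigma, want_e2 = TRUE)
    mean_nu[i, ] <- ex$E1
    var_nu[i, ] <- pmax(ex$E2 - ex$E1^2, 0)
    if (nrow(pr)) {
      # one Hermite-coefficient set per cell serves every pair at this time
      bm <- vapply(seq_len(n), function(j)
        .hermite_coefs(spec$fi[[j]], mean_x[i, j], sigma[j]),
        numeric(.MEHLER_M + 1L))
      for (q in seq_len(nrow(pr))) {
        j <- pr[q, 1]; k <- pr[q, 2]
        if (config$firing_corr == "static_input") {
          rho <- spec$corr[j, k]
        } else {
          sjk <- sigma[j] * sigma[k]
          if (sjk == 0) {
            if (abs(cov_x[i, q]) > 1e-10)
              stop("activity_to_firing: sigma = 0 with nonzero covariance ",
                   "for pair (", j, ",", k, ") — inconsistent moments")
            rho <- 0
          } else rho <- cov_x[i, q] / sjk
        }
        rho <- max(min(rho, 1 - 1e-12), -1 + 1e-12)
        cov_nu[i, q] <- if (abs(rho) <= 0.9)
          sum(rho^(1:.MEHLER_M) * bm[-1L, j] * bm[-1L, k])
        else
          bivariate_rate_expectation(spec$fi[[j]], spec$fi[[k]],
                                     mean_x[i, j], mean_x[i, k],
                                     sigma[j], sigma[k], rho) -
            ex$E1[j] * ex$E1[k]
      }
    }
  }
  stat_trajectory(times, mean_x, var_x, cov_x, mean_nu, var_nu, cov_nu,
                  method = method)
}
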