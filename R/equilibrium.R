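#' Self-consistent steady state of the closure system
#'
#' With constant background parameters the closure ODEs settle to the fixed
#' point
#' \deqn{\mu_j = \tilde\mu_j + \sum_k g_{jk} E_1(k), \qquad
#'       \sigma_j^2 = \tilde\sigma_j^2/(2\tau_j) +
#'         \sigma_j \sum_k g_{jk} M_F(j,k),}
#' \deqn{Cov_{j,k}\frac{\tau_j + \tau_k}{2} =
#'   c_{jk}\frac{\tilde\sigma_j\tilde\sigma_k}{2}
#'   + \frac{\sigma_j \tau_j}{2}\sum_l g_{kl} M_F(j,l)
#'   + \frac{\sigma_k \tau_k}{2}\sum_l g_{jl} M_F(k,l).}
#' The implicit \eqn{(\mu, \sigma)} system is solved by damped fixed-point
#' iteration (relaxation 0.5; \eqn{\sigma_j} from the positive root of its
#' scalar quadratic), with a finite-difference Newton fallback if the
#' iteration stalls; the covariance relation is then explicit. Absence of a
#' positive \eqn{\sigma} root is reported as non-convergence (closure
#' breakdown at strong coupling), never silently patched.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param mu_tilde,sigma_tilde background parameters to use; default the
#'   static fields of \code{spec} (pass values from
#'   \code{\link{eval_input}} for the quasi-steady-state method).
#' @param tol residual tolerance (default \code{1e-12}).
#' @param max_iter maximum fixed-point iterations.
#' @param start optional warm start, a list with \code{mu}, \code{sigma}.
#' @return An object of class \code{steady_state}: fields \code{mu},
#'   \code{sigma}, \code{cov} (full symmetric covariance matrix, diagonal
#'   \eqn{\sigma_j^2}), \code{converged}, \code{residual_norm},
#'   \code{iterations}.
#' @export
solve_steady_state <- function(spec, mu_tilde = NULL, sigma_tilde = NULL,
                               tol = 1e-12, max_iter = 500L,
                               start = NULL) {
  stopifnot(inherits(spec, "network_spec"), tol > 0, max_iter >= 1L)
  n <- spec$n_cells
  if (is.null(mu_tilde)) mu_tilde <- spec$mu_bg
  if (is.null(sigma_tilde)) sigma_tilde <- spec$sigma_bg
  stopifnot(length(mu_tilde) == n, length(sigma_tilde) == n,
            all(sigma_tilde > 0))
  fiv <- .fi_vectors(spec)
  tau <- spec$tau
  G <- spec$coupling
  Cr <- spec$corr
  A0 <- sigma_tilde^2 / (2 * tau)        # uncoupled variance

  # residual of the (mu, sigma) block at a point
  resid <- function(mu, sigma) {
    ex <- .closure_expectations(fiv, mu, sigma)
    B <- as.numeric((G * Cr) %*% ex$M1)  # sum_k g_jk c_jk M1_k = sum g M_F(j,k)
    c(mu - mu_tilde - as.numeric(G %*% ex$E1),
      sigma^2 - A0 - sigma * B)
  }

  mu <- if (is.null(start)) mu_tilde else start$mu
  sigma <- if (is.null(start)) sqrt(A0) else start$sigma
  ok <- TRUE
  iter <- 0L
  damp <- 0.5
  repeat {
    ex <- .closure_expectations(fiv, mu, sigma)
    B <- as.numeric((G * Cr) %*% ex$M1)
    mu_new <- mu_tilde + as.numeric(G %*% ex$E1)
    disc <- B^2 + 4 * A0
    if (any(disc < 0) || any((B + sqrt(disc)) / 2 <= 0)) { ok <- FALSE; break }
    sigma_new <- (B + sqrt(disc)) / 2
    mu <- (1 - damp) * mu + damp * mu_new
    sigma <- (1 - damp) * sigma + damp * sigma_new
    iter <- iter + 1L
    r <- resid(mu, sigma)
    if (max(abs(r)) <= tol || iter >= max_iter) break
  }
  if (ok && max(abs(resid(mu, sigma))) > tol) {
    # Newton fallback on the stacked residual
    z <- c(mu, sigma)
    for (it in seq_len(50L)) {
      r <- resid(z[1:n], z[(n + 1):(2 * n)])
      if (max(abs(r)) <= tol) break
      Jm <- matrix(0, 2 * n, 2 * n)
      h <- 1e-7
      for (q in seq_len(2 * n)) {
        zq <- z; zq[q] <- zq[q] + h
        sq <- pmax(zq[(n + 1):(2 * n)], 0)
        Jm[, q] <- (resid(zq[1:n], sq) - r) / h
      }
      step <- tryCatch(solve(Jm, r), error = function(e) NULL)
      if (is.null(step)) break
      z <- z - step
      iter <- iter + 1L
    }
    if (all(z[(n + 1):(2 * n)] > 0)) {
      mu <- z[1:n]; sigma <- z[(n + 1):(2 * n)]
    } else ok <- FALSE
  }
  rn <- max(abs(resid(mu, sigma)))
  converged <- ok && is.finite(rn) && rn <= tol

  # covariance block, explicit given (mu, sigma)
  ex <- .closure_expectations(fiv, mu, sigma)
  MF <- Cr * rep(ex$M1, each = n)        # MF[j,k] = c_jk M1_k (diag c=1)
  W <- MF %*% t(G)                       # W[j,k] = sum_l M_F(j,l) g_kl
  cov <- (Cr * outer(sigma_tilde, sigma_tilde) +
            sweep(W, 1, sigma * tau, "*") +
            t(sweep(W, 1, sigma * tau, "*"))) / outer(tau, tau, "+")
  cov <- (cov + t(cov)) / 2
  diag(cov) <- sigma^2
  structure(list(mu = mu, sigma = sigma, cov = cov, converged = converged,
                 residual_norm = rn, iterations = iter),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> %d cells, converged=%s, residual=%.3g, iterations=%d\n",
              length(x$mu), x$converged, x$residual_norm, x$iterations))
  invisible(x)
}

#' Quasi-steady-state (QSS) trajectory
#'
#' The baseline approximation that assumes the network equilibrates
#' instantaneously: at each requested time the inputs are evaluated and the
#' steady-state system is solved (warm-started from the previous time), and
#' firing statistics are derived exactly as in
#' \code{\link{activity_to_firing}}. Accurate for slow drives, it misses the
#' lag and overshoot of genuinely non-equilibrium transients.
#'
#' @param spec a \code{\link{network_spec}} (with inputs attached).
#' @param times finite time grid.
#' @param config a \code{\link{closure_config}}.
#' @param tol,max_iter passed to \code{\link{solve_steady_state}}.
#' @return a \code{\link{stat_trajectory}} with method tag \code{"qss"}.
#' @export
qss_trajectory <- function(spec, times, config = closure_config(),
                           tol = 1e-12, max_iter = 500L) {
  stopifnot(inherits(spec, "network_spec"), all(is.finite(times)),
            all(diff(times) > 0))
  n <- spec$n_cells
  pr <- pair_index(n)
  nt <- length(times)
  mean_x <- var_x <- matrix(0, nt, n)
  cov_x <- matrix(0, nt, nrow(pr))
  warm <- NULL
  for (i in seq_len(nt)) {
    inp <- eval_input(spec, times[i])
    ss <- solve_steady_state(spec, mu_tilde = inp$mu, sigma_tilde = inp$sigma,
                             tol = tol, max_iter = max_iter,
                             start = warm)
    if (!ss$converged)
      stop("qss_trajectory: steady-state solve failed at t = ", times[i],
           " (residual ", signif(ss$residual_norm, 3), ")")
    warm <- list(mu = ss$mu, sigma = ss$sigma)
    mean_x[i, ] <- ss$mu
    var_x[i, ] <- ss$sigma^2
    if (nrow(pr)) cov_x[i, ] <- ss$cov[pr]
  }
  activity_to_firing(list(times = times, mean_x = mean_x, var_x = var_x,
                          cov_x = cov_x),
                     spec, config, method = "qss")
}
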