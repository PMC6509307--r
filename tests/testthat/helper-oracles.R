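# Independent oracles used across test files. These deliberately avoid the
# package's production code paths: expectations via stats::integrate on the
# untransformed integrand, and the closure right-hand side as a literal
# loop-by-loop transcription of the kinetic equations.

oracle_gauss <- function(h, rel.tol = 1e-12) {
  stats::integrate(function(y) h(y) * stats::dnorm(y), -Inf, Inf,
                   rel.tol = rel.tol, abs.tol = 1e-13,
                   subdivisions = 500L)$value
}

oracle_e1 <- function(fi, mu, sigma)
  oracle_gauss(function(y) fi_eval(fi, sigma * y + mu))

oracle_e2 <- function(fi, mu, sigma)
  oracle_gauss(function(y) fi_eval(fi, sigma * y + mu)^2)

oracle_m1 <- function(fi, mu, sigma)
  oracle_gauss(function(y) y * fi_eval(fi, sigma * y + mu))

# analytic derivative of the sigmoid, for the Stein-identity check
fi_deriv <- function(fi, x) 0.5 / (fi$x_sp * cosh((x - fi$x_rev) / fi$x_sp)^2)

# naive dense 2-D grid integration of F_k(s y1 + m) * y2 over the bivariate
# standard normal with correlation c (cross-check for mf_2d_oracle)
dense_mf_2d <- function(c, fi_k, mu_k, sigma_k, half = 8.5, n = 3001L) {
  g <- seq(-half, half, length.out = n)
  h <- g[2] - g[1]
  den <- outer(g, g, function(y1, y2)
    exp(-(y1^2 - 2 * c * y1 * y2 + y2^2) / (2 * (1 - c^2))) /
      (2 * pi * sqrt(1 - c^2)))
  f1 <- fi_eval(fi_k, sigma_k * g + mu_k)
  sum((f1 * den) %*% g) * h^2
}

# literal transcription of the closure kinetic equations, scalar loops; the
# kernel implementations are injected so structure and quadrature can be
# tested independently
oracle_closure_rhs <- function(mu, E, t, spec,
                               e1_fun = oracle_e1, m1_fun = oracle_m1) {
  n <- spec$n_cells
  inp <- eval_input(spec, t)
  tau <- spec$tau
  G <- spec$coupling
  Cr <- spec$corr
  sig <- sqrt(pmax(diag(E) - mu^2, 0))
  E1v <- vapply(1:n, function(k) e1_fun(spec$fi[[k]], mu[k], sig[k]),
                numeric(1))
  M1v <- vapply(1:n, function(k) m1_fun(spec$fi[[k]], mu[k], sig[k]),
                numeric(1))
  MF <- function(j, k) if (j == k) M1v[k] else Cr[j, k] * M1v[k]
  dmu <- numeric(n)
  for (j in 1:n)
    dmu[j] <- (-mu[j] + inp$mu[j] + sum(G[j, ] * E1v)) / tau[j]
  # second-moment channel (diagonal equation transcribed separately)
  dE_diag <- numeric(n)
  for (j in 1:n) {
    s <- 0
    for (k in 1:n)
      s <- s + G[j, k] * (mu[j] * E1v[k] + sig[j] * MF(j, k))
    dE_diag[j] <- inp$sigma[j]^2 / tau[j]^2 +
      (2 / tau[j]) * (-E[j, j] + inp$mu[j] * mu[j] + s)
  }
  dE <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    s_j <- s_k <- 0
    for (l in 1:n) {
      s_j <- s_j + G[j, l] * (mu[k] * E1v[l] + sig[k] * MF(k, l))
      s_k <- s_k + G[k, l] * (mu[j] * E1v[l] + sig[j] * MF(j, l))
    }
    dE[j, k] <- (Cr[j, k] * inp$sigma[j] * inp$sigma[k] +
                   tau[k] * (-E[j, k] + inp$mu[j] * mu[k] + s_j) +
                   tau[j] * (-E[j, k] + inp$mu[k] * mu[j] + s_k)) /
      (tau[j] * tau[k])
  }
  list(dmu = dmu, dE = dE, dE_diag = dE_diag)
}

# literal transcription of the steady-state relations, for the residual
# certificate
oracle_steady_residual <- function(ss, spec, mu_tilde = spec$mu_bg,
                                   sigma_tilde = spec$sigma_bg) {
  n <- spec$n_cells
  tau <- spec$tau
  G <- spec$coupling
  Cr <- spec$corr
  M1v <- vapply(1:n, function(k)
    oracle_m1(spec$fi[[k]], ss$mu[k], ss$sigma[k]), numeric(1))
  E1v <- vapply(1:n, function(k)
    oracle_e1(spec$fi[[k]], ss$mu[k], ss$sigma[k]), numeric(1))
  MF <- function(j, k) if (j == k) M1v[k] else Cr[j, k] * M1v[k]
  r_mu <- r_sig <- numeric(n)
  for (j in 1:n) {
    r_mu[j] <- ss$mu[j] - mu_tilde[j] - sum(G[j, ] * E1v)
    r_sig[j] <- ss$sigma[j]^2 - sigma_tilde[j]^2 / (2 * tau[j]) -
      ss$sigma[j] * sum(G[j, ] * vapply(1:n, function(k) MF(j, k),
                                        numeric(1)))
  }
  r_cov <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    sj <- sum(G[k, ] * vapply(1:n, function(l) MF(j, l), numeric(1)))
    sk <- sum(G[j, ] * vapply(1:n, function(l) MF(k, l), numeric(1)))
    r_cov[j, k] <- ss$cov[j, k] * (tau[j] + tau[k]) / 2 -
      Cr[j, k] * sigma_tilde[j] * sigma_tilde[k] / 2 -
      ss$sigma[j] * tau[j] * sj / 2 - ss$sigma[k] * tau[k] * sk / 2
  }
  max(abs(c(r_mu, r_sig, r_cov[upper.tri(r_cov)])))
}

# small fully-specified networks for deterministic tests
toy_spec <- function(n = 3, coupled = TRUE, seed = 99, inputs = list(),
                     input_mode = NULL) {
  set.seed(seed)
  tau <- stats::runif(n, 0.8, 1.2)
  mu_bg <- stats::runif(n, -0.5, 0.5)
  sigma_bg <- stats::runif(n, 1, 2)
  corr <- build_correlation_matrix(n, seed = seed + 1)
  coupling <- if (coupled) sample_coupling(n, 1, seed = seed + 2)
              else matrix(0, n, n)
  fi <- Map(fi_params, stats::rnorm(n, 0, 0.1),
            0.35 * stats::runif(n) + 0.05)
  network_spec(tau, mu_bg, sigma_bg, corr, coupling, fi,
               inputs = inputs, input_mode = input_mode)
}

random_moment_state <- function(spec) {
  n <- spec$n_cells
  mu <- stats::rnorm(n, 0, 0.5)
  A <- matrix(stats::rnorm(n * n, sd = 0.4), n, n)
  cov <- crossprod(A) + diag(stats::runif(n, 0.2, 1))
  moment_state(mu, cov + outer(mu, mu))
}
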