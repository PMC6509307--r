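test_that("closure_rhs matches an independent literal transcription", {
  set.seed(21)
  spec <- toy_spec(3, coupled = TRUE, seed = 31)
  for (rep in 1:5) {
    st <- random_moment_state(spec)
    d <- closure_rhs(st, 0.7, spec)
    o <- oracle_closure_rhs(st$mu, st$second_moments, 0.7, spec)
    expect_lt(max(abs(d$mu - o$dmu)), 1e-8)
    expect_lt(max(abs(d$second_moments - o$dE)), 1e-8)
    expect_lt(max(abs(diag(d$second_moments) - o$dE_diag)), 1e-8)
  }
  st <- random_moment_state(spec)
  st$mu[2] <- NaN
  expect_error(closure_rhs(st, 0, spec), "cell index 2")
})

test_that("the pair equation recovers the second-moment equation at j = k", {
  # literal transcriptions (package kernels injected so only the structure
  # is under test), 100 random states/specs, 1e-10
  set.seed(22)
  for (rep in 1:100) {
    spec <- toy_spec(3, coupled = TRUE, seed = 1000 + rep)
    st <- random_moment_state(spec)
    o <- oracle_closure_rhs(st$mu, st$second_moments, 0, spec,
                            e1_fun = e1, m1_fun = m1)
    expect_lt(max(abs(diag(o$dE) - o$dE_diag)), 1e-10)
    # and the package assembles exactly that structure
    d <- closure_rhs(st, 0, spec)
    expect_lt(max(abs(d$second_moments - o$dE)), 1e-10)
    expect_lt(max(abs(d$second_moments - t(d$second_moments))), 1e-12)
  }
})

test_that("uncoupled closure derivative vanishes at the analytic fixed point", {
  spec <- toy_spec(4, coupled = FALSE, seed = 32)
  cov_inf <- spec$corr * outer(spec$sigma_bg, spec$sigma_bg) /
    outer(spec$tau, spec$tau, "+")
  st <- moment_state(spec$mu_bg, cov_inf + outer(spec$mu_bg, spec$mu_bg))
  d <- closure_rhs(st, 0, spec)
  expect_lt(max(abs(d$mu)), 1e-12)
  expect_lt(max(abs(d$second_moments)), 1e-12)
})

test_that("integrate_closure reproduces the uncoupled linear-SDE transients", {
  # single cell: mu(t) = mu~ (1 - e^{-t/tau}) from mu(0) = 0
  sp1 <- network_spec(1, 0.8, 1, matrix(1), matrix(0), list(fi_params(0, 0.2)))
  init <- moment_state(0, matrix(0.1))
  tms <- seq(0, 5, by = 0.25)
  tr <- integrate_closure(sp1, closure_config(), tms, init = init)
  expect_lt(max(abs(tr$mean_x[, 1] - 0.8 * (1 - exp(-tms)))), 1e-7)
  expect_lt(max(abs(tr$var_x[, 1] - (0.5 + (0.1 - 0.5) * exp(-2 * tms)))),
            1e-7)

  # uncoupled pair with distinct tau: variance and covariance transients
  spec <- toy_spec(2, coupled = FALSE, seed = 33)
  mu0 <- c(0.2, -0.1)
  cov0 <- matrix(c(0.3, 0.05, 0.05, 0.6), 2)
  st0 <- moment_state(mu0, cov0 + outer(mu0, mu0))
  tr <- integrate_closure(spec, closure_config(), tms, init = st0)
  v_inf <- spec$sigma_bg^2 / (2 * spec$tau)
  c_inf <- spec$corr[1, 2] * prod(spec$sigma_bg) / sum(spec$tau)
  for (j in 1:2) {
    mu_ex <- spec$mu_bg[j] + (mu0[j] - spec$mu_bg[j]) * exp(-tms / spec$tau[j])
    v_ex <- v_inf[j] + (cov0[j, j] - v_inf[j]) * exp(-2 * tms / spec$tau[j])
    expect_lt(max(abs(tr$mean_x[, j] - mu_ex)), 1e-7)
    expect_lt(max(abs(tr$var_x[, j] - v_ex)), 1e-7)
  }
  rate <- 1 / spec$tau[1] + 1 / spec$tau[2]
  c_ex <- c_inf + (cov0[1, 2] - c_inf) * exp(-rate * tms)
  expect_lt(max(abs(tr$cov_x[, 1] - c_ex)), 1e-7)

  # uncoupled pair long-time covariance: c sigma~^2 / (tau_j + tau_k)
  f2 <- replicate(2, fi_params(0, 0.2), simplify = FALSE)
  cr <- matrix(c(1, 0.5, 0.5, 1), 2)
  sp <- network_spec(c(1, 1), c(0, 0), c(1, 1), cr, matrix(0, 2, 2), f2)
  tr <- integrate_closure(sp, closure_config(), c(0, 30),
                          init = moment_state(c(1, -1), diag(2) + 0.2 +
                                                outer(c(1, -1), c(1, -1))))
  expect_equal(tr$cov_x[2, 1], 0.25, tolerance = 1e-6)
})

test_that("starting at the steady state keeps every statistic constant", {
  spec <- toy_spec(3, coupled = TRUE, seed = 34)
  tms <- seq(0, 8, by = 0.5)
  tr <- integrate_closure(spec, closure_config(), tms)   # default init
  for (fam in stat_families) {
    m <- ratemoments:::.traj_family(tr, fam)
    expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-6)
  }
})

test_that("long-time closure integration converges to solve_steady_state", {
  spec <- toy_spec(3, coupled = TRUE, seed = 35)
  ss <- solve_steady_state(spec)
  expect_true(ss$converged)
  # start away from equilibrium
  st0 <- moment_state(spec$mu_bg + 0.3,
                      diag(0.2, 3) + outer(spec$mu_bg + 0.3, spec$mu_bg + 0.3))
  tr <- integrate_closure(spec, closure_config(), c(0, 25, 50), init = st0)
  expect_lt(max(abs(tr$mean_x[3, ] - ss$mu)), 1e-6)
  expect_lt(max(abs(tr$var_x[3, ] - ss$sigma^2)), 1e-6)
  expect_lt(max(abs(tr$cov_x[3, ] - ss$cov[pair_index(3)])), 1e-6)
})

test_that("activity_to_firing implements the Gaussian change of variables", {
  spec <- toy_spec(3, coupled = TRUE, seed = 36)
  act <- list(times = c(0, 1), mean_x = rbind(c(0.2, -0.3, 0.1), c(0, 0, 0)),
              var_x = rbind(c(0.4, 0.2, 0.6), c(0.3, 0.3, 0.3)),
              cov_x = rbind(c(0.1, -0.05, 0.02), c(0, 0, 0)))
  tr <- activity_to_firing(act, spec, closure_config(), method = "closure")
  for (j in 1:3) {
    expect_equal(tr$mean_nu[1, j],
                 e1(spec$fi[[j]], act$mean_x[1, j], sqrt(act$var_x[1, j])),
                 tolerance = 1e-10)
    expect_equal(tr$var_nu[1, j],
                 e2(spec$fi[[j]], act$mean_x[1, j], sqrt(act$var_x[1, j])) -
                   tr$mean_nu[1, j]^2,
                 tolerance = 1e-10)
  }
  pr <- pair_index(3)
  for (q in 1:3) {
    j <- pr[q, 1]; k <- pr[q, 2]
    rho <- act$cov_x[1, q] / sqrt(act$var_x[1, j] * act$var_x[1, k])
    expect_equal(tr$cov_nu[1, q],
                 bivariate_rate_expectation(
                   spec$fi[[j]], spec$fi[[k]], act$mean_x[1, j],
                   act$mean_x[1, k], sqrt(act$var_x[1, j]),
                   sqrt(act$var_x[1, k]), rho) -
                   tr$mean_nu[1, j] * tr$mean_nu[1, k],
                 tolerance = 1e-8)
  }
  # zero activity correlation gives zero firing covariance
  expect_lt(max(abs(tr$cov_nu[2, ])), 1e-12)
  # bounds forced by F in [0, 1]
  expect_true(all(tr$mean_nu >= 0 & tr$mean_nu <= 1))
  expect_true(all(tr$var_nu >= 0 & tr$var_nu <= 0.25))
  # deterministic limit
  act0 <- list(times = 0, mean_x = rbind(c(0.2, -0.3, 0.1)),
               var_x = rbind(c(0, 0, 0)), cov_x = rbind(c(0, 0, 0)))
  tr0 <- activity_to_firing(act0, spec, closure_config())
  for (j in 1:3)
    expect_equal(tr0$mean_nu[1, j], fi_eval(spec$fi[[j]], act0$mean_x[1, j]))
  expect_true(all(tr0$var_nu == 0))
  # inconsistent moments: sigma = 0 with nonzero covariance
  bad <- list(times = 0, mean_x = rbind(c(0, 0, 0)),
              var_x = rbind(c(0, 0.5, 0.5)), cov_x = rbind(c(0.1, 0, 0)))
  expect_error(activity_to_firing(bad, spec, closure_config()),
               "inconsistent")
  # static_input ablation mode uses c_jk
  trs <- activity_to_firing(act, spec,
                            closure_config(firing_corr = "static_input"))
  q <- 1; j <- pr[q, 1]; k <- pr[q, 2]
  expect_equal(trs$cov_nu[1, q],
               bivariate_rate_expectation(
                 spec$fi[[j]], spec$fi[[k]], act$mean_x[1, j],
                 act$mean_x[1, k], sqrt(act$var_x[1, j]),
                 sqrt(act$var_x[1, k]), spec$corr[j, k]) -
                 trs$mean_nu[1, j] * trs$mean_nu[1, k],
               tolerance = 1e-8)
})

test_that("moment_state flags negative derived variances and packs correctly", {
  expect_warning(moment_state(c(1, 0), diag(c(0.5, 1))), "variance")
  st <- moment_state(c(0.1, 0.2), matrix(c(1, 0.3, 0.3, 1), 2))
  y <- ratemoments:::.ms_pack(st)
  expect_length(y, 2 + 3)
  back <- ratemoments:::.ms_unpack(y, 2)
  expect_equal(back$mu, st$mu)
  expect_equal(back$E, st$second_moments)
})
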