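test_that("fi_eval implements the bounded tanh sigmoid", {
  f <- fi_params(0.3, 0.7)
  expect_equal(fi_eval(f, 0.3), 0.5)                     # midpoint
  expect_equal(fi_eval(fi_params(0, 1), 1), 0.5 * (1 + tanh(1)))
  expect_equal(fi_eval(f, 50), 1)
  expect_equal(fi_eval(f, -50), 0)
  expect_error(fi_eval(f, NaN), "finite")
  expect_error(fi_eval(f, Inf), "finite")
  expect_error(fi_params(0, 0), "x_sp")
  expect_error(fi_params(0, -1), "x_sp")
})

test_that("fi_eval stays in [0,1] and is nondecreasing across random params", {
  set.seed(41)
  for (rep in 1:200) {
    f <- fi_params(rnorm(1, 0, 0.5), runif(1, 0.01, 1))
    x <- sort(rnorm(5000, 0, 3))
    v <- fi_eval(f, x)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("correlation-matrix generator gives symmetric PSD unit-diagonal Cr", {
  for (n in c(3L, 50L)) {
    for (seed in 1:50) {
      cr <- build_correlation_matrix(n, seed = seed)
      expect_equal(dim(cr), c(n, n))
      expect_lt(max(abs(cr - t(cr))), 1e-12)
      expect_lt(max(abs(diag(cr) - 1)), 1e-12)
      expect_gte(min(eigen(cr, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
      if (n > 1) expect_lt(max(abs(cr[upper.tri(cr)])), 1)
    }
  }
  expect_identical(build_correlation_matrix(1, seed = 4), matrix(1, 1, 1))
})

test_that("coupling sampler matches its stated normal distribution", {
  g <- sample_coupling(500, 1, seed = 8)
  expect_equal(dim(g), c(500L, 500L))
  # E|g| = l/(5 sqrt(2 pi)) in the infinite limit; 3 standard errors
  m <- mean(abs(g))
  target <- 1 / (5 * sqrt(2 * pi))
  se <- stats::sd(abs(g)) / 500
  expect_lt(abs(m - target), 3 * se)
  # variance at l = 2 is (2/10)^2
  g2 <- sample_coupling(317, 2, seed = 9)   # ~1e5 draws
  v <- stats::var(as.numeric(g2))
  se_v <- sqrt(2 / (length(g2) - 1)) * 0.04
  expect_lt(abs(v - 0.04), 3 * se_v)
  expect_identical(sample_coupling(10, 1, seed = 3),
                   sample_coupling(10, 1, seed = 3))
})

test_that("sample_network draws from the stated heterogeneity distributions", {
  spec <- sample_network(10000, coupling_scale = 1, seed = 123)
  expect_true(all(spec$tau > 0))
  expect_lt(abs(mean(spec$tau) - 1), 3 * 0.1 / sqrt(10000))
  expect_true(all(spec$sigma_bg >= 1 & spec$sigma_bg <= 2))
  expect_true(all(spec$mu_bg >= -0.5 & spec$mu_bg <= 0.5))
  fiv <- vapply(spec$fi, `[[`, numeric(1), "x_sp")
  expect_true(all(fiv >= 0.05 & fiv <= 0.40))
  expect_lt(abs(mean(vapply(spec$fi, `[[`, numeric(1), "x_rev"))),
            4 * 0.1 / sqrt(10000))
  # pure function of the seed
  s1 <- sample_network(5, 2, seed = 77)
  s2 <- sample_network(5, 2, seed = 77)
  expect_identical(s1, s2)
  expect_false(identical(s1$coupling, sample_network(5, 2, seed = 78)$coupling))
})

test_that("network_spec validates its invariants", {
  f3 <- replicate(3, fi_params(0, 0.2), simplify = FALSE)
  cr <- diag(3)
  expect_error(network_spec(c(1, 1), 0:2, rep(1, 3), cr, cr * 0, f3))
  expect_error(network_spec(rep(1, 3), rep(0, 3), rep(-1, 3), cr, cr * 0, f3))
  bad <- cr; bad[1, 2] <- 0.5                     # asymmetric
  expect_error(network_spec(rep(1, 3), rep(0, 3), rep(1, 3), bad, cr * 0, f3),
               "symmetric")
  bad <- matrix(1, 3, 3)                          # |c_jk| = 1 off-diagonal
  expect_error(network_spec(rep(1, 3), rep(0, 3), rep(1, 3), bad, cr * 0, f3),
               "c_jk")
  bad <- cr; bad[1, 2] <- bad[2, 1] <- 0.99; bad[1, 3] <- bad[3, 1] <- 0.99
  bad[2, 3] <- bad[3, 2] <- -0.99                 # indefinite
  expect_error(network_spec(rep(1, 3), rep(0, 3), rep(1, 3), bad, cr * 0, f3),
               "semidefinite")
  expect_equal(diffusion_matrix(toy_spec(3)),
               with(toy_spec(3), corr * outer(sigma_bg / tau, sigma_bg / tau)))
})

test_that("input signals evaluate as documented and modulate eval_input", {
  con <- input_signal("constant", baseline = 0.4)
  expect_equal(signal_eval(con, c(-5, 0, 100)), rep(0.4, 3))
  pul <- input_signal("pulse", baseline = 0.1, amplitude = 1, t_on = 2,
                      t_off = 5, ramp = 0.05)
  expect_lt(abs(signal_eval(pul, 3.5) - 1.1), 1e-10)  # mid-pulse plateau
  expect_lt(abs(signal_eval(pul, -10) - 0.1), 1e-10)
  expect_lt(abs(signal_eval(pul, 20) - 0.1), 1e-10)
  sin0 <- input_signal("sinusoid", baseline = 0.3, amplitude = 0)
  expect_equal(signal_eval(sin0, seq(0, 9)), rep(0.3, 10))
  sin1 <- default_sinusoid(period = 4)
  expect_equal(signal_eval(sin1, 1), 1)               # quarter period peak

  spec <- toy_spec(3)
  for (t in c(-1, 0, 2.5, 10)) {
    inp <- eval_input(spec, t)
    expect_identical(inp$mu, spec$mu_bg)              # no signals attached
    expect_identical(inp$sigma, spec$sigma_bg)
  }
  sp <- set_inputs(spec, list(mu_bg = pul))           # common replacement
  inp <- eval_input(sp, 3.5)
  expect_true(all(abs(inp$mu - signal_eval(pul, 3.5)) < 1e-12))
  expect_identical(inp$sigma, spec$sigma_bg)
  spa <- set_inputs(spec, list(mu_bg = pul), input_mode = c(mu_bg = "add"))
  expect_equal(eval_input(spa, -10)$mu, spec$mu_bg + 0.1)
  # sigma modulation must stay positive
  spb <- set_inputs(spec, list(sigma_bg = input_signal("constant",
                                                       baseline = -1)))
  expect_error(eval_input(spb, 0), "sigma")
})
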