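test_that("Gauss-Hermite rule reproduces standard-normal moments exactly", {
  for (ord in c(5L, 12L, 40L)) {
    r <- gauss_hermite(ord)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    # odd moments vanish, even moments are double factorials, up to 2*ord-1
    for (deg in 0:min(2L * ord - 1L, 19L)) {
      exact <- if (deg %% 2 == 1) 0 else
        if (deg == 0) 1 else prod(seq(1, deg - 1, by = 2))
      expect_lt(abs(sum(r$weights * r$nodes^deg) - exact),
                1e-12 * max(1, exact))
    }
  }
})

test_that("e1/e2/m1 match adaptive dense integration to 1e-8", {
  f <- fi_params(0, 0.2)
  expect_lt(abs(e1(f, 0.3, 0.7) - oracle_e1(f, 0.3, 0.7)), 1e-8)
  expect_lt(abs(e2(f, 0.3, 0.7) - oracle_e2(f, 0.3, 0.7)), 1e-8)
  set.seed(5)
  for (rep in 1:25) {
    f <- fi_params(rnorm(1, 0, 0.1), runif(1, 0.05, 0.40))
    mu <- runif(1, -1, 1)
    sigma <- runif(1, 0.05, 1.5)
    expect_lt(abs(e1(f, mu, sigma) - oracle_e1(f, mu, sigma)), 1e-8)
    expect_lt(abs(e2(f, mu, sigma) - oracle_e2(f, mu, sigma)), 1e-8)
    expect_lt(abs(m1(f, mu, sigma) - oracle_m1(f, mu, sigma)), 1e-8)
  }
})

test_that("degenerate and symmetric cases of the expectation kernels", {
  f <- fi_params(-0.2, 0.3)
  expect_identical(e1(f, 0.4, 0), fi_eval(f, 0.4))
  expect_identical(e2(f, 0.4, 0), fi_eval(f, 0.4)^2)
  expect_identical(m1(f, 0.4, 0), 0)
  # mu at the midpoint: the sigmoid's point symmetry forces E1 = 1/2
  for (s in c(0.1, 0.5, 1.3))
    expect_equal(e1(f, -0.2, s), 0.5, tolerance = 1e-12)
  # identity-map plug-in: m1 = sigma exactly
  expect_equal(m1(function(x) x, 1.7, 0.6), 0.6, tolerance = 1e-12)
})

test_that("e1 is monotone in mu and all kernels respect their bounds", {
  f <- fi_params(0.1, 0.15)
  for (s in c(0, 0.2, 1.0)) {
    v <- vapply(seq(-2, 2, by = 0.05), function(m) e1(f, m, s), numeric(1))
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v >= 0 & v <= 1))
  }
  set.seed(6)
  for (rep in 1:50) {
    f <- fi_params(rnorm(1, 0, 0.1), runif(1, 0.05, 0.4))
    mu <- runif(1, -1, 1); s <- runif(1, 0, 1.5)
    a <- e1(f, mu, s); b <- e2(f, mu, s)
    expect_gte(b, a^2 - 1e-12)
    expect_lte(b, a + 1e-12)
    expect_gte(m1(f, mu, s), -1e-12)   # nondecreasing F
  }
})

test_that("m1 satisfies Stein's identity against the analytic derivative", {
  set.seed(7)
  for (rep in 1:100) {
    f <- fi_params(rnorm(1, 0, 0.1), runif(1, 0.05, 0.40))
    mu <- runif(1, -1, 1)
    sigma <- runif(1, 0.05, 1.5)
    stein <- sigma * oracle_gauss(function(y)
      fi_deriv(f, sigma * y + mu), rel.tol = 1e-11)
    expect_lt(abs(m1(f, mu, sigma) - stein), 1e-8)
  }
})

test_that("mf reduces the bivariate integral exactly", {
  f <- fi_params(0.05, 0.25)
  expect_identical(mf(2, 3, 0, f, 0.3, 0.6), 0)
  expect_identical(mf(2, 2, 0.4, f, 0.3, 0.6), m1(f, 0.3, 0.6))
  expect_error(mf(1, 2, 1, f, 0, 1), "c_jk")
  expect_error(mf_2d_oracle(-1, f, 0, 1), "\\|c\\|")
  # reduction identity against the literal 2-D integral, randomized sweep
  set.seed(8)
  for (rep in 1:1000) {
    f <- fi_params(rnorm(1, 0, 0.1), runif(1, 0.05, 0.40))
    cjk <- runif(1, -0.95, 0.95)
    mu <- runif(1, -1, 1)
    sigma <- runif(1, 0, 1.5)
    expect_lt(abs(mf(1, 2, cjk, f, mu, sigma) -
                    mf_2d_oracle(cjk, f, mu, sigma)), 1e-8)
  }
  # the oracle itself cross-checked against naive dense grid integration
  expect_lt(abs(mf_2d_oracle(0.6, f, 0.3, 0.7) -
                  dense_mf_2d(0.6, f, 0.3, 0.7)), 1e-6)
  expect_lt(abs(mf_2d_oracle(0.5, function(x) rep(0.7, length(x)), 0, 1)),
            1e-13)                         # constant F: E[Y2] = 0
})

test_that("bivariate rate expectation factorizes, degenerates and matches a dense grid", {
  fj <- fi_params(0, 0.2)
  fk <- fi_params(-0.1, 0.25)
  # independence
  expect_equal(bivariate_rate_expectation(fj, fk, 0.3, -0.2, 0.7, 0.5, 0),
               e1(fj, 0.3, 0.7) * e1(fk, -0.2, 0.5), tolerance = 1e-12)
  # perfectly correlated identical marginals: <F^2>
  expect_lt(abs(bivariate_rate_expectation(fj, fj, 0.3, 0.3, 0.7, 0.7, 1) -
                  e2(fj, 0.3, 0.7)), 1e-12)
  # dense 2-D oracle at moderate and strong correlation
  g <- seq(-9, 9, length.out = 4001)
  h <- g[2] - g[1]
  for (rho in c(0.5, -0.7, 0.95)) {
    den <- outer(g, g, function(a, b)
      exp(-(a^2 - 2 * rho * a * b + b^2) / (2 * (1 - rho^2))) /
        (2 * pi * sqrt(1 - rho^2)))
    val <- sum(fi_eval(fj, 0.7 * g + 0.3) *
                 (den %*% fi_eval(fk, 0.5 * g - 0.2))) * h^2
    expect_lt(abs(bivariate_rate_expectation(fj, fk, 0.3, -0.2, 0.7, 0.5,
                                             rho) - val), 1e-8)
  }
  # bounds on a random sweep
  set.seed(9)
  for (rep in 1:100) {
    v <- bivariate_rate_expectation(
      fi_params(rnorm(1, 0, 0.1), runif(1, 0.05, 0.4)),
      fi_params(rnorm(1, 0, 0.1), runif(1, 0.05, 0.4)),
      runif(1, -1, 1), runif(1, -1, 1), runif(1, 0, 1.5), runif(1, 0, 1.5),
      runif(1, -1, 1))
    expect_gte(v, -1e-12)
    expect_lte(v, 1 + 1e-12)
  }
})
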