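#' Gauss-Hermite quadrature against the standard normal density
#'
#' Probabilists' normalization: the rule integrates
#' \eqn{\int f(y)\,\varrho_1(y)\,dy} with
#' \eqn{\varrho_1(y) = e^{-y^2/2}/\sqrt{2\pi}} as
#' \eqn{\sum_i w_i f(y_i)}, exactly for polynomials up to degree
#' \eqn{2\,\mathrm{order} - 1}. Nodes and weights come from the
#' Golub-Welsch eigendecomposition of the Jacobi matrix of the monic
#' Hermite polynomials, so the weights sum to 1 exactly.
#'
#' Gauss-Hermite converges spectrally only while the integrand is smooth on
#' the unit (noise) scale; a sigmoid with slope scale \code{x_sp} much
#' smaller than the activity spread \eqn{\sigma} is nearly a step on that
#' scale, and a fixed-order rule stalls around \eqn{10^{-4}}. The package's
#' production kernels therefore use a panel scheme adapted to both length
#' scales (see \code{\link{e1}}); the plain rule is kept for polynomial
#' exactness, for well-resolved integrands and for diagnostics.
#'
#' @param order positive integer number of abscissae (default 40).
#' @return An object of class \code{gh_rule} with fields \code{order},
#'   \code{nodes}, \code{weights}.
#' @export
gauss_hermite <- function(order = 40L) {
  order <- as.integer(order)
  stopifnot(order >= 1L)
  if (order == 1L)
    return(structure(list(order = 1L, nodes = 0, weights = 1),
                     class = "gh_rule"))
  off <- sqrt(seq_len(order - 1L))
  J <- matrix(0, order, order)
  J[cbind(seq_len(order - 1L), 2:order)] <- off
  J[cbind(2:order, seq_len(order - 1L))] <- off
  ev <- eigen(J, symmetric = TRUE)
  nodes <- sort(ev$values)
  # polish the eigenvalue roots with Newton steps on the orthonormal
  # Hermite recurrence (psi_n' = sqrt(n) psi_{n-1}), then use Christoffel
  # weights 1/sum_k psi_k^2 -- this recovers full double precision where
  # raw eigenvector weights stall around 1e-12 relative error
  psi_top <- function(x) {
    p_prev <- rep(1, length(x))
    p <- x
    if (order > 2L)
      for (m in seq_len(order - 2L) + 1L) {
        pn <- (x * p - sqrt(m - 1) * p_prev) / sqrt(m)
        p_prev <- p
        p <- pn
      }
    list(p = p, p_prev = p_prev)    # psi_{n-1} and psi_{n-2}
  }
  for (it in 1:3) {
    v <- psi_top(nodes)
    pn <- (nodes * v$p - sqrt(order - 1) * v$p_prev) / sqrt(order)  # psi_n
    nodes <- nodes - pn / (sqrt(order) * v$p)
  }
  nodes <- (nodes - rev(nodes)) / 2            # enforce symmetry
  S <- 1 + nodes^2                             # psi_0^2 + psi_1^2
  p_prev <- rep(1, order)
  p <- nodes
  if (order > 2L)
    for (m in seq_len(order - 2L) + 1L) {
      pn <- (nodes * p - sqrt(m - 1) * p_prev) / sqrt(m)
      p_prev <- p
      p <- pn
      S <- S + p^2
    }
  weights <- 1 / S
  weights <- (weights + rev(weights)) / 2
  weights <- weights / sum(weights)
  structure(list(order = order, nodes = nodes, weights = weights),
            class = "gh_rule")
}

# ---- adaptive panel quadrature --------------------------------------------
# Gauss-Legendre nodes on [-1, 1] (Golub-Welsch for Legendre weight)
.gl_rule <- function(n) {
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  ev <- eigen(J, symmetric = TRUE)
  ord <- order(ev$values)
  list(x = ev$values[ord], w = 2 * ev$vectors[1, ord]^2)
}
.GL16 <- .gl_rule(16L)

# nodes/weights for plain integration dy over consecutive panels
.panel_nodes <- function(breaks) {
  a <- breaks[-length(breaks)]
  b <- breaks[-1L]
  half <- (b - a) / 2
  y <- outer(.GL16$x, half) + rep((a + b) / 2, each = 16L)
  list(y = as.numeric(y), w = as.numeric(outer(.GL16$w, half)))
}

# breakpoints (standardized activity y) resolving both the Gaussian density
# (unit scale) and the sigmoid transition at y* with width w = x_sp/sigma
.gauss_breaks <- c(-9, -6, -4.5, -3.5, -2.5, -1.75, -1, -0.5, 0,
                   0.5, 1, 1.75, 2.5, 3.5, 4.5, 6, 9)
.feature_breaks <- function(center, width) {
  if (!is.finite(center) || width >= 5) return(numeric(0))
  center + width * c(-30, -16, -8, -4, -2, -1, 0, 1, 2, 4, 8, 16, 30)
}
.merge_breaks <- function(...) {
  br <- sort(unique(pmin(9, pmax(-9, c(...)))))
  br[c(TRUE, diff(br) > 1e-9)]
}
.sigmoid_breaks <- function(mu, sigma, fi) {
  if (is.function(fi)) return(.gauss_breaks)
  .merge_breaks(.gauss_breaks,
                .feature_breaks((fi$x_rev - mu) / sigma, fi$x_sp / sigma))
}

# E1/M1 (and optionally E2) of one cell by the panel scheme
.gauss_kernels <- function(fi, mu, sigma, want_e2 = FALSE) {
  if (sigma == 0) {
    f0 <- fi_eval(fi, mu)
    return(list(E1 = f0, M1 = 0, E2 = if (want_e2) f0^2 else NULL))
  }
  q <- .panel_nodes(.sigmoid_breaks(mu, sigma, fi))
  f <- fi_eval(fi, sigma * q$y + mu)
  wd <- q$w * stats::dnorm(q$y)
  list(E1 = sum(wd * f), M1 = sum(wd * q$y * f),
       E2 = if (want_e2) sum(wd * f^2) else NULL)
}

#' Gaussian expectations of the firing nonlinearity
#'
#' The three closure kernels, each an expectation over a Gaussian activity
#' with mean \code{mu} and standard deviation \code{sigma}:
#' \describe{
#'   \item{\code{e1}}{\eqn{E_1 = \int F(\sigma y + \mu)\varrho_1(y)dy},
#'     the mean firing rate.}
#'   \item{\code{e2}}{\eqn{E_2 = \int F^2(\sigma y + \mu)\varrho_1(y)dy};
#'     always \eqn{E_1^2 \le E_2 \le E_1} for \eqn{F \in [0,1]}.}
#'   \item{\code{m1}}{\eqn{M_1 = \int F(\sigma y + \mu)\,y\,\varrho_1(y)dy},
#'     the first Hermite coefficient; by Stein's identity it equals
#'     \eqn{\sigma E[F']}, hence is nonnegative for nondecreasing \eqn{F}.}
#' }
#' \code{sigma = 0} collapses to the point evaluation
#' (\code{e1 = F(mu)}, \code{e2 = F(mu)^2}, \code{m1 = 0}).
#'
#' By default the integral is evaluated by composite Gauss-Legendre panels
#' whose breakpoints resolve both the unit Gaussian scale and the sigmoid
#' transition (absolute accuracy near machine precision for the full
#' heterogeneity range, including near-step sigmoids). Passing an explicit
#' \code{\link{gauss_hermite}} rule forces that rule instead, which is
#' accurate only while \code{sigma} does not greatly exceed \code{x_sp}.
#'
#' @param fi an \code{\link{fi_params}} object (or a bare function of one
#'   argument, the plug-in point used by tests).
#' @param mu mean of the Gaussian activity.
#' @param sigma nonnegative standard deviation.
#' @param rule \code{NULL} (default, panel scheme) or a
#'   \code{\link{gauss_hermite}} rule.
#' @return a numeric scalar.
#' @export
e1 <- function(fi, mu, sigma, rule = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(fi_eval(fi, mu))
  if (is.null(rule)) return(.gauss_kernels(fi, mu, sigma)$E1)
  stopifnot(inherits(rule, "gh_rule"))
  sum(rule$weights * fi_eval(fi, sigma * rule$nodes + mu))
}

#' @rdname e1
#' @export
e2 <- function(fi, mu, sigma, rule = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(fi_eval(fi, mu)^2)
  if (is.null(rule)) return(.gauss_kernels(fi, mu, sigma, want_e2 = TRUE)$E2)
  stopifnot(inherits(rule, "gh_rule"))
  sum(rule$weights * fi_eval(fi, sigma * rule$nodes + mu)^2)
}

#' @rdname e1
#' @export
m1 <- function(fi, mu, sigma, rule = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(0)
  if (is.null(rule)) return(.gauss_kernels(fi, mu, sigma)$M1)
  stopifnot(inherits(rule, "gh_rule"))
  sum(rule$weights * rule$nodes * fi_eval(fi, sigma * rule$nodes + mu))
}

#' Mixed activity-firing kernel M_F(j, k)
#'
#' \eqn{M_F(j,k) = \iint F_k(\sigma_k y_1 + \mu_k)\, y_2\,
#' \varrho_{j,k}(y_1, y_2)\,dy_1 dy_2}, the expectation of cell \eqn{j}'s
#' standardized activity times cell \eqn{k}'s firing under the bivariate
#' standard normal with correlation \eqn{c_{jk}}. Argument order matters:
#' the F-I curve and moments always belong to the second index \eqn{k}.
#' When \eqn{j = k} the bivariate density is replaced by the univariate
#' \eqn{\varrho_1}, i.e. the kernel is \code{\link{m1}}. For \eqn{j \ne k}
#' the Gaussian conditional \eqn{E[Y_2 | Y_1] = c_{jk} Y_1} reduces the
#' double integral exactly to \eqn{c_{jk}\, M_1(k)}; the literal 2-D
#' integral is retained as \code{\link{mf_2d_oracle}} for testing.
#'
#' @param j,k cell indices (only their equality matters).
#' @param c_jk input correlation, in \eqn{(-1, 1)} when \code{j != k}.
#' @param fi_k,mu_k,sigma_k F-I parameters and Gaussian moments of cell k.
#' @param rule \code{NULL} or a \code{\link{gauss_hermite}} rule, as in
#'   \code{\link{e1}}.
#' @return a numeric scalar.
#' @export
mf <- function(j, k, c_jk, fi_k, mu_k, sigma_k, rule = NULL) {
  if (j == k) return(m1(fi_k, mu_k, sigma_k, rule))
  if (abs(c_jk) >= 1) stop("mf: |c_jk| must be < 1 for j != k")
  c_jk * m1(fi_k, mu_k, sigma_k, rule)
}

#' Literal 2-D evaluation of M_F (test oracle)
#'
#' Evaluates the double integral over the bivariate normal
#' \eqn{\varrho_{j,k}} directly by decorrelated tensor-product quadrature,
#' substituting \eqn{y_2 = c\,y_1 + \sqrt{1 - c^2}\,z}: panel quadrature
#' along \eqn{y_1} (where the sigmoid lives) and Gauss-Hermite along
#' \eqn{z} (where the integrand is linear). Used only to cross-check the
#' 1-D reduction in \code{\link{mf}}.
#'
#' @param c correlation in \eqn{(-1, 1)}.
#' @param fi_k,mu_k,sigma_k as in \code{\link{mf}}.
#' @param order Gauss-Hermite order for the \eqn{z} axis (default 40).
#' @return a numeric scalar.
#' @export
mf_2d_oracle <- function(c, fi_k, mu_k, sigma_k, order = 40L) {
  if (abs(c) >= 1) stop("mf_2d_oracle: |c| must be < 1")
  stopifnot(sigma_k >= 0)
  gh <- gauss_hermite(order)
  q <- .panel_nodes(.sigmoid_breaks(mu_k, max(sigma_k, 1e-300), fi_k))
  f1 <- fi_eval(fi_k, sigma_k * q$y + mu_k)
  y2 <- outer(c * q$y, sqrt(1 - c^2) * gh$nodes, "+")
  sum((q$w * stats::dnorm(q$y) * f1) * (y2 %*% gh$weights))
}

# ---- bivariate firing expectation -----------------------------------------
# Normalized Hermite (Mehler) coefficients b_m = <F, psi_m> under rho1;
# E[F_j(X_j) F_k(X_k)] = sum_m rho^m b_m(j) b_m(k). Tail energy is bounded
# by Var(F) <= 1/4, so truncation error <= rho^(M+1)/4.
.MEHLER_M <- 170L

.hermite_coefs <- function(fi, mu, sigma, M = .MEHLER_M) {
  if (sigma == 0) return(c(fi_eval(fi, mu), rep(0, M)))
  q <- .panel_nodes(.sigmoid_breaks(mu, sigma, fi))
  f <- fi_eval(fi, sigma * q$y + mu)
  wd <- q$w * stats::dnorm(q$y) * f
  b <- numeric(M + 1L)
  psi_prev <- rep(1, length(q$y))
  psi <- q$y
  b[1L] <- sum(wd)
  b[2L] <- sum(wd * q$y)
  for (m in 2:M) {
    psi_new <- (q$y * psi - sqrt(m - 1) * psi_prev) / sqrt(m)
    psi_prev <- psi
    psi <- psi_new
    b[m + 1L] <- sum(wd * psi)
  }
  b
}

# direct decorrelated 2-D panel integration, for |rho| close to 1
.biv_direct <- function(fi_j, fi_k, mu_j, mu_k, sigma_j, sigma_k, rho) {
  s_perp <- sigma_k * sqrt(max(0, 1 - rho^2))
  br <- .sigmoid_breaks(mu_j, sigma_j, fi_j)
  if (!is.function(fi_k)) {
    # inner mean crosses x_rev,k at y1 = yc, transition width wc in y1 units
    yc <- (fi_k$x_rev - mu_k) / (sigma_k * rho)
    wc <- (fi_k$x_sp + s_perp) / (sigma_k * abs(rho))
    br <- .merge_breaks(br, .feature_breaks(yc, wc))
  }
  q <- .panel_nodes(br)
  f1 <- fi_eval(fi_j, sigma_j * q$y + mu_j)
  inner <- vapply(q$y, function(y)
    e1(fi_k, mu_k + sigma_k * rho * y, s_perp), numeric(1))
  sum(q$w * stats::dnorm(q$y) * f1 * inner)
}

#' Expectation of a product of firing rates under a bivariate Gaussian
#'
#' \eqn{\langle F_j(x_j) F_k(x_k)\rangle} where \eqn{(x_j, x_k)} is
#' bivariate normal with the given marginals and correlation \code{rho}.
#' \code{rho = 0} (or a zero marginal spread) factorizes into
#' \code{e1(j) * e1(k)}; \eqn{|\rho| = 1} is computed as a 1-D integral
#' along the degenerate line; interior \eqn{|\rho|} is clipped to
#' \eqn{1 - 10^{-12}}. Moderate correlations (\eqn{|\rho| \le 0.9}) use the
#' Mehler expansion \eqn{\sum_m \rho^m b_m(j) b_m(k)} over normalized
#' Hermite coefficients (truncation error below \eqn{10^{-8}}); stronger
#' correlations fall back to direct decorrelated panel integration.
#'
#' @param fi_j,fi_k F-I parameters of the two cells.
#' @param mu_j,mu_k,sigma_j,sigma_k Gaussian marginal moments
#'   (\code{sigma >= 0}).
#' @param rho correlation in \eqn{[-1, 1]}.
#' @param rule \code{NULL} (default, accurate path) or a
#'   \code{\link{gauss_hermite}} rule forcing plain tensor quadrature
#'   (diagnostic use).
#' @return a numeric scalar in \eqn{[0, 1]}.
#' @export
bivariate_rate_expectation <- function(fi_j, fi_k, mu_j, mu_k,
                                       sigma_j, sigma_k, rho, rule = NULL) {
  stopifnot(abs(rho) <= 1, sigma_j >= 0, sigma_k >= 0)
  if (rho == 0 || sigma_j == 0 || sigma_k == 0)
    return(e1(fi_j, mu_j, sigma_j, rule) * e1(fi_k, mu_k, sigma_k, rule))
  if (abs(rho) == 1) {
    s <- sign(rho)
    br <- .merge_breaks(.sigmoid_breaks(mu_j, sigma_j, fi_j),
                        s * .sigmoid_breaks(mu_k, sigma_k, fi_k))
    q <- .panel_nodes(br)
    return(sum(q$w * stats::dnorm(q$y) *
                 fi_eval(fi_j, sigma_j * q$y + mu_j) *
                 fi_eval(fi_k, s * sigma_k * q$y + mu_k)))
  }
  rho <- max(min(rho, 1 - 1e-12), -1 + 1e-12)
  if (!is.null(rule)) {
    stopifnot(inherits(rule, "gh_rule"))
    fj <- fi_eval(fi_j, sigma_j * rule$nodes + mu_j)
    xk <- mu_k + sigma_k * outer(rho * rule$nodes,
                                 sqrt(1 - rho^2) * rule$nodes, "+")
    return(sum(rule$weights * fj * (fi_eval(fi_k, xk) %*% rule$weights)))
  }
  if (abs(rho) <= 0.9) {
    bj <- .hermite_coefs(fi_j, mu_j, sigma_j)
    bk <- .hermite_coefs(fi_k, mu_k, sigma_k)
    return(sum(rho^(0:.MEHLER_M) * bj * bk))
  }
  .biv_direct(fi_j, fi_k, mu_j, mu_k, sigma_j, sigma_k, rho)
}

# Vectorized E1 / M1 (optionally E2) across the cells of a spec.
.closure_expectations <- function(fiv, mu, sigma, want_e2 = FALSE) {
  n <- length(mu)
  E1 <- M1 <- numeric(n)
  E2 <- if (want_e2) numeric(n) else NULL
  for (j in seq_len(n)) {
    fi <- structure(list(x_rev = fiv$x_rev[j], x_sp = fiv$x_sp[j]),
                    class = "fi_params")
    kk <- .gauss_kernels(fi, mu[j], sigma[j], want_e2 = want_e2)
    E1[j] <- kk$E1
    M1[j] <- kk$M1
    if (want_e2) E2[j] <- kk$E2
  }
  list(E1 = E1, M1 = M1, E2 = E2)
}
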