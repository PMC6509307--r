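#' Network specification
#'
#' Bundles every static parameter of the stochastic firing-rate network
#' \deqn{\tau_j \dot x_j = -x_j + \tilde\mu_j + \tilde\sigma_j \eta_j(t)
#'       + \sum_k g_{jk} F_k(x_k),}
#' where the white noises \eqn{\eta_j} are uncorrelated in time but
#' instantaneously correlated across cells,
#' \eqn{\langle\eta_j(t)\eta_k(t')\rangle = c_{jk}\delta(t - t')}.
#'
#' @param tau positive numeric vector of membrane time constants
#'   \eqn{\tau_j}.
#' @param mu_bg numeric vector of background input means \eqn{\tilde\mu_j}.
#' @param sigma_bg positive numeric vector of background noise amplitudes
#'   \eqn{\tilde\sigma_j}.
#' @param corr input correlation matrix \eqn{Cr} (symmetric, unit diagonal,
#'   off-diagonal entries in \eqn{(-1, 1)}, positive semidefinite to
#'   \eqn{10^{-10}}).
#' @param coupling signed coupling matrix \eqn{G} (entry \eqn{g_{jk}} is the
#'   strength from presynaptic cell \eqn{k} onto cell \eqn{j}).
#' @param fi list of \code{\link{fi_params}}, one per cell.
#' @param inputs named list of \code{\link{input_signal}}s keyed by the
#'   parameter they drive (\code{"mu_bg"} and/or \code{"sigma_bg"}); the same
#'   signal is applied to every cell.
#' @param input_mode named character vector with entries \code{"replace"}
#'   (the signal replaces the static baseline, the default) or \code{"add"}
#'   (added to the heterogeneous baseline), one per attached input.
#' @return An object of class \code{network_spec}.
#' @seealso \code{\link{sample_network}} for the randomized generator,
#'   \code{\link{eval_input}} for the effective parameters at time \eqn{t}.
#' @export
network_spec <- function(tau, mu_bg, sigma_bg, corr, coupling, fi,
                         inputs = list(), input_mode = NULL) {
  n <- length(tau)
  stopifnot(n >= 1L, is.numeric(tau), all(is.finite(tau)), all(tau > 0),
            length(mu_bg) == n, all(is.finite(mu_bg)),
            length(sigma_bg) == n, all(is.finite(sigma_bg)),
            all(sigma_bg > 0))
  corr <- as.matrix(corr); coupling <- as.matrix(coupling)
  if (!all(dim(corr) == c(n, n)) || !all(dim(coupling) == c(n, n)))
    stop("corr and coupling must be ", n, "x", n, " matrices")
  if (max(abs(corr - t(corr))) > 1e-12) stop("corr must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-12) stop("corr must have unit diagonal")
  off <- corr[upper.tri(corr)]
  if (n > 1L && any(abs(off) >= 1)) stop("off-diagonal c_jk must lie in (-1, 1)")
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("corr must be positive semidefinite (min eigenvalue >= -1e-10)")
  if (length(fi) != n || !all(vapply(fi, inherits, logical(1), "fi_params")))
    stop("fi must be a list of ", n, " fi_params objects")
  if (length(inputs)) {
    if (is.null(names(inputs)) ||
        !all(names(inputs) %in% c("mu_bg", "sigma_bg")))
      stop("inputs must be named with 'mu_bg' and/or 'sigma_bg'")
    stopifnot(all(vapply(inputs, inherits, logical(1), "rm_signal")))
  }
  mode <- rep_len("replace", length(inputs))
  names(mode) <- names(inputs)
  if (!is.null(input_mode)) {
    stopifnot(all(input_mode %in% c("replace", "add")),
              all(names(input_mode) %in% names(inputs)))
    mode[names(input_mode)] <- input_mode
  }
  structure(list(n_cells = n, tau = as.numeric(tau),
                 mu_bg = as.numeric(mu_bg), sigma_bg = as.numeric(sigma_bg),
                 corr = corr, coupling = coupling, fi = fi,
                 inputs = inputs, input_mode = mode),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", x$n_cells, " cells, ",
      if (all(x$coupling == 0)) "uncoupled" else
        sprintf("mean |g| = %.4f", mean(abs(x$coupling))),
      ", inputs: ",
      if (length(x$inputs)) paste(names(x$inputs), collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Diffusion matrix of the associated Fokker-Planck operator
#'
#' \eqn{D_{jk} = c_{jk}\,\tilde\sigma_j\tilde\sigma_k / (\tau_j\tau_k)},
#' evaluated at the static background parameters.
#'
#' @param spec a \code{\link{network_spec}}.
#' @return an \code{n_cells} x \code{n_cells} symmetric matrix.
#' @export
diffusion_matrix <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  s <- spec$sigma_bg / spec$tau
  spec$corr * outer(s, s)
}

# fi parameter vectors, for vectorized quadrature
.fi_vectors <- function(spec) {
  list(x_rev = vapply(spec$fi, `[[`, numeric(1), "x_rev"),
       x_sp = vapply(spec$fi, `[[`, numeric(1), "x_sp"))
}

#' Effective background parameters at time t
#'
#' Applies any attached \code{\link{input_signal}}s to the static
#' \code{mu_bg} / \code{sigma_bg} fields. A common signal drives all cells
#' identically; in \code{"replace"} mode (default) the signal value is used
#' for every cell, in \code{"add"} mode it is added to the heterogeneous
#' baseline.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param t a single finite time.
#' @return \code{list(mu =, sigma =)} of per-cell effective parameters.
#' @export
eval_input <- function(spec, t) {
  stopifnot(inherits(spec, "network_spec"), length(t) == 1L, is.finite(t))
  mu <- spec$mu_bg
  sigma <- spec$sigma_bg
  for (field in names(spec$inputs)) {
    v <- signal_eval(spec$inputs[[field]], t)
    if (field == "mu_bg") {
      mu <- if (spec$input_mode[[field]] == "replace")
        rep_len(v, spec$n_cells) else mu + v
    } else {
      sigma <- if (spec$input_mode[[field]] == "replace")
        rep_len(v, spec$n_cells) else sigma + v
    }
  }
  if (any(sigma <= 0))
    stop("eval_input: sigma_bg(t) <= 0 at t = ", t,
         " (diffusion would be ill-defined)")
  list(mu = mu, sigma = sigma)
}

#' Attach input signals to a network
#'
#' @param spec a \code{\link{network_spec}}.
#' @param inputs,input_mode as in \code{\link{network_spec}}.
#' @return the modified \code{network_spec}.
#' @export
set_inputs <- function(spec, inputs, input_mode = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  network_spec(spec$tau, spec$mu_bg, spec$sigma_bg, spec$corr, spec$coupling,
               spec$fi, inputs = inputs, input_mode = input_mode)
}

#' Random input correlation matrix with approximately independent entries
#'
#' Three-step Gram construction: (i) draw \eqn{A} with i.i.d.
#' \eqn{N(0, sd^2)} entries; (ii) form \eqn{d_s(j) = 1/\sqrt{(A^TA)_{jj}}};
#' (iii) set \eqn{Cr = \Lambda_{d_s} A^T A \Lambda_{d_s}}. The result is
#' symmetric positive semidefinite with exact unit diagonal. Degenerate draws
#' (a zero Gram diagonal, or an off-diagonal entry within \eqn{10^{-6}} of
#' \eqn{\pm 1}) are rejected and resampled.
#'
#' @param n_cells positive integer.
#' @param entry_sd positive entry standard deviation (default 0.8).
#' @param seed integer RNG seed; the generator is a pure function of
#'   \code{(n_cells, entry_sd, seed)}.
#' @return an \code{n_cells} x \code{n_cells} correlation matrix.
#' @export
build_correlation_matrix <- function(n_cells, entry_sd = 0.8, seed) {
  stopifnot(n_cells >= 1L, entry_sd > 0)
  set.seed(seed)
  .build_corr(n_cells, entry_sd)
}

.build_corr <- function(n_cells, entry_sd) {
  repeat {
    A <- matrix(stats::rnorm(n_cells * n_cells, sd = entry_sd),
                n_cells, n_cells)
    gram <- crossprod(A)
    d <- diag(gram)
    if (any(d == 0)) next
    ds <- 1 / sqrt(d)
    cr <- gram * outer(ds, ds)
    cr <- (cr + t(cr)) / 2
    diag(cr) <- 1
    if (n_cells > 1L && max(abs(cr[upper.tri(cr)])) >= 1 - 1e-6) next
    return(cr)
  }
}

#' Random all-to-all coupling matrix
#'
#' All \code{n_cells^2} entries (self-coupling included) are i.i.d.
#' \eqn{N(0, (l/10)^2)}; \eqn{l} is the coupling-strength scale, so the mean
#' of \eqn{|g_{jk}|} tends to \eqn{l/(5\sqrt{2\pi})} for large networks.
#'
#' @param n_cells positive integer.
#' @param l positive coupling scale.
#' @param seed integer RNG seed.
#' @return an \code{n_cells} x \code{n_cells} matrix.
#' @export
sample_coupling <- function(n_cells, l, seed) {
  stopifnot(n_cells >= 1L, l > 0)
  set.seed(seed)
  .sample_coupling(n_cells, l)
}

.sample_coupling <- function(n_cells, l) {
  matrix(stats::rnorm(n_cells * n_cells, sd = l / 10), n_cells, n_cells)
}

#' Sample a heterogeneous network
#'
#' Draws every parameter from the reference heterogeneity distributions:
#' \eqn{\tau_j \sim N(1, 0.1^2)} (nonpositive draws rejected and resampled),
#' \eqn{\tilde\mu_j \sim U[0,1] - 0.5}, \eqn{\tilde\sigma_j \sim U[0,1] + 1},
#' \eqn{x_{rev,j} \sim N(0, 0.1^2)}, \eqn{x_{sp,j} \sim 0.35\,U[0,1] + 0.05};
#' the correlation matrix comes from
#' \code{\link{build_correlation_matrix}} and the coupling matrix from
#' \code{\link{sample_coupling}} at scale \code{coupling_scale}.
#'
#' @param n_cells positive integer \eqn{N_c}.
#' @param coupling_scale positive coupling scale \eqn{l} (default 1).
#' @param seed integer seed; identical seeds give identical networks.
#' @param inputs,input_mode optional input signals, see
#'   \code{\link{network_spec}}.
#' @return a \code{\link{network_spec}}.
#' @export
sample_network <- function(n_cells, coupling_scale = 1, seed,
                           inputs = list(), input_mode = NULL) {
  stopifnot(n_cells >= 1L, coupling_scale > 0)
  set.seed(seed)
  tau <- stats::rnorm(n_cells, 1, 0.1)
  while (any(bad <- tau <= 0)) tau[bad] <- stats::rnorm(sum(bad), 1, 0.1)
  mu_bg <- stats::runif(n_cells) - 0.5
  sigma_bg <- stats::runif(n_cells) + 1
  x_rev <- stats::rnorm(n_cells, 0, 0.1)
  x_sp <- 0.35 * stats::runif(n_cells) + 0.05
  corr <- .build_corr(n_cells, 0.8)
  coupling <- .sample_coupling(n_cells, coupling_scale)
  fi <- Map(fi_params, x_rev, x_sp)
  network_spec(tau, mu_bg, sigma_bg, corr, coupling, fi,
               inputs = inputs, input_mode = input_mode)
}
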