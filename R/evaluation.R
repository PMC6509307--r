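#' Average absolute error between two trajectories
#'
#' The accuracy metric used throughout the package: at each time, the mean
#' of \eqn{|X_{method} - X_{reference}|} over the \eqn{M} items of a
#' statistic family (\eqn{M = N_c} for means and variances,
#' \eqn{M = N_c(N_c - 1)/2} distinct pairs for covariances).
#'
#' @param method,reference \code{\link{stat_trajectory}} objects on
#'   identical time grids with identical cell counts.
#' @param family one of \code{\link{stat_families}}.
#' @return numeric vector over times of nonnegative errors.
#' @export
average_absolute_error <- function(method, reference, family) {
  stopifnot(inherits(method, "stat_trajectory"),
            inherits(reference, "stat_trajectory"))
  if (method$n_cells != reference$n_cells ||
      length(method$times) != length(reference$times) ||
      max(abs(method$times - reference$times)) > 1e-10)
    stop("average_absolute_error: time grid / cell count mismatch")
  a <- .traj_family(method, family)
  b <- .traj_family(reference, family)
  if (ncol(a) == 0L) return(rep(0, length(method$times)))
  rowMeans(abs(a - b))
}

#' Error report between a method and a reference
#'
#' Pools the per-family average absolute errors into the scalar summaries
#' used for method comparison: a time series and a time-averaged scalar per
#' family, and a grand scalar that weights every (statistic, item, time)
#' absolute deviation equally (so families with more items contribute
#' proportionally more terms; the per-family means let either weighting
#' convention be recovered).
#'
#' @param method,reference \code{\link{stat_trajectory}} objects.
#' @param meta optional named list of run metadata stored verbatim.
#' @return An object of class \code{error_report}: \code{per_family_ts}
#'   (list of time series), \code{per_family} (named scalars),
#'   \code{grand} (scalar), \code{times}, \code{meta}.
#' @export
error_report <- function(method, reference, meta = list()) {
  ts <- lapply(stat_families, function(f)
    average_absolute_error(method, reference, f))
  names(ts) <- stat_families
  n <- method$n_cells
  m_items <- c(n, n, n * (n - 1) / 2, n, n, n * (n - 1) / 2)
  names(m_items) <- stat_families
  per_family <- vapply(ts, mean, numeric(1))
  grand <- sum(per_family * m_items) / sum(m_items)
  structure(list(per_family_ts = ts, per_family = per_family,
                 grand = grand, times = method$times,
                 n_items = m_items, meta = meta),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report> grand average absolute error:",
      signif(x$grand, 4), "\n")
  print(signif(x$per_family, 4))
  invisible(x)
}

#' @export
as.data.frame.error_report <- function(x, ...) {
  do.call(rbind, lapply(stat_families, function(f)
    data.frame(family = f, time = x$times, error = x$per_family_ts[[f]])))
}

#' Coupling-strength sweep
#'
#' The accuracy-versus-coupling experiment: a single heterogeneous network
#' is sampled at coupling scale \code{l = 1} and its coupling matrix is
#' rescaled to each value in \code{l_values} (so only the overall strength
#' changes); for each scale the closure ODEs, the QSS baseline and a Monte
#' Carlo reference are run with the given input, and an
#' \code{\link{error_report}} is computed for closure-vs-MC and QSS-vs-MC.
#'
#' @param n_cells network size.
#' @param l_values increasing positive coupling scales.
#' @param input an \code{\link{input_signal}} applied to the background
#'   mean of every cell (replacement mode).
#' @param times recording time grid.
#' @param seed integer seed; fans out deterministically to network sampling
#'   and MC noise streams so the network does not change with MC settings.
#' @param n_realizations,dt,group_size Monte Carlo settings.
#' @param config a \code{\link{closure_config}}.
#' @return a list with one element per \code{l}: \code{list(l, closure,
#'   qss, noise_floor)}, where \code{closure}/\code{qss} are
#'   \code{error_report}s and \code{noise_floor} is the expected
#'   contribution of MC sampling noise to the grand error, estimated from
#'   the error bands as \eqn{\sqrt{2/\pi}\,\bar S/\sqrt{n_{groups}}}.
#' @export
coupling_sweep <- function(n_cells, l_values, input, times,
                           seed, n_realizations = 25000L, dt = 0.01,
                           group_size = 1000L, config = closure_config()) {
  stopifnot(all(l_values > 0))
  base <- sample_network(n_cells, coupling_scale = 1,
                         seed = derive_seed(seed, "network"),
                         inputs = list(mu_bg = input))
  lapply(seq_along(l_values), function(i) {
    l <- l_values[i]
    spec <- base
    spec$coupling <- base$coupling * l
    cl <- integrate_closure(spec, config, times)
    qs <- qss_trajectory(spec, times, config)
    mc <- simulate_ensemble(spec, times, n_realizations, dt = dt,
                            seed = derive_seed(seed, paste0("mc", i)),
                            group_size = group_size)
    list(l = l,
         closure = error_report(cl, mc$trajectory,
                                meta = list(n_cells = n_cells, l = l,
                                            input = input$kind, seed = seed,
                                            n_realizations = mc$n_realizations)),
         qss = error_report(qs, mc$trajectory,
                            meta = list(n_cells = n_cells, l = l,
                                        input = input$kind, seed = seed)),
         noise_floor = mc_noise_floor(mc))
  })
}

#' Expected MC-noise contribution to the grand average absolute error
#'
#' Even a perfect method shows a nonzero average absolute error against a
#' finite Monte Carlo reference. For a Gaussian estimator with standard
#' error \eqn{SE}, \eqn{E|noise| = \sqrt{2/\pi}\,SE}; the standard error of
#' each pooled statistic is \eqn{S/\sqrt{n_{groups}}} with \eqn{S} the
#' group-wise band half-width. This pools that floor over all statistics
#' and times with the same equal weighting as the grand error.
#'
#' @param ensemble an \code{\link{ensemble_estimate}}.
#' @return nonnegative scalar.
#' @export
mc_noise_floor <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_estimate"))
  s_all <- unlist(ensemble$bands, use.names = FALSE)
  sqrt(2 / pi) * mean(s_all) / sqrt(ensemble$n_groups)
}

#' Deterministic seed streams
#'
#' Fans one global seed out to named substreams (e.g. \code{"network"},
#' \code{"mc1"}) so enabling or disabling one consumer does not perturb the
#' draws of another. Pure integer arithmetic, result in
#' \eqn{[0, 2^{31} - 1)}.
#'
#' @param seed integer master seed.
#' @param purpose character tag of the substream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}
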