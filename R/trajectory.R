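#' Unordered cell-pair index
#'
#' @param n_cells number of cells.
#' @return a 2-column integer matrix with one row per unordered pair
#'   \eqn{j < k}, in column-major upper-triangle order — the order used by
#'   every covariance column block in the package.
#' @export
pair_index <- function(n_cells) {
  if (n_cells < 2L) return(matrix(integer(0), 0L, 2L,
                                  dimnames = list(NULL, c("j", "k"))))
  idx <- which(upper.tri(diag(n_cells)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("j", "k"))
  idx
}

#' Time-resolved statistic trajectory
#'
#' The common container for all three solution methods: a time grid plus the
#' six statistic families — mean, variance and pairwise covariance of the
#' activity \eqn{x_j} and of the firing \eqn{\nu_j = F_j(x_j)}.
#'
#' @param times increasing numeric vector of length \code{T}.
#' @param mean_x,var_x,mean_nu,var_nu \code{T x n_cells} matrices.
#' @param cov_x,cov_nu \code{T x P} matrices, columns ordered as
#'   \code{\link{pair_index}}.
#' @param method provenance tag: \code{"closure"}, \code{"qss"} or
#'   \code{"monte_carlo"}.
#' @return An object of class \code{stat_trajectory}.
#' @export
stat_trajectory <- function(times, mean_x, var_x, cov_x,
                            mean_nu = NULL, var_nu = NULL, cov_nu = NULL,
                            method = c("closure", "qss", "monte_carlo")) {
  method <- match.arg(method)
  times <- as.numeric(times)
  stopifnot(length(times) >= 1L, all(diff(times) > 0))
  mean_x <- rbind(mean_x); var_x <- rbind(var_x); cov_x <- rbind(cov_x)
  n <- ncol(mean_x)
  p <- n * (n - 1L) / 2L
  stopifnot(nrow(mean_x) == length(times),
            all(dim(var_x) == dim(mean_x)),
            nrow(cov_x) == length(times), ncol(cov_x) == p)
  check_nu <- function(m, nc) {
    if (is.null(m)) return(matrix(NA_real_, length(times), nc))
    m <- rbind(m)
    stopifnot(nrow(m) == length(times), ncol(m) == nc)
    m
  }
  structure(list(times = times, n_cells = n, pairs = pair_index(n),
                 mean_x = mean_x, var_x = var_x, cov_x = cov_x,
                 mean_nu = check_nu(mean_nu, n), var_nu = check_nu(var_nu, n),
                 cov_nu = check_nu(cov_nu, p), method = method),
            class = "stat_trajectory")
}

#' @export
print.stat_trajectory <- function(x, ...) {
  cat(sprintf("<stat_trajectory> method=%s, %d cells, %d pairs, %d times in [%g, %g]\n",
              x$method, x$n_cells, nrow(x$pairs), length(x$times),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
as.data.frame.stat_trajectory <- function(x, ...) {
  n <- x$n_cells
  pr <- x$pairs
  pair_nm <- if (nrow(pr)) paste0(pr[, 1], "_", pr[, 2]) else character(0)
  df <- data.frame(time = x$times)
  add <- function(df, m, stem, nm) {
    colnames(m) <- paste0(stem, "_", nm)
    cbind(df, m)
  }
  df <- add(df, x$mean_x, "mean_x", seq_len(n))
  df <- add(df, x$var_x, "var_x", seq_len(n))
  if (nrow(pr)) df <- add(df, x$cov_x, "cov_x", pair_nm)
  df <- add(df, x$mean_nu, "mean_nu", seq_len(n))
  df <- add(df, x$var_nu, "var_nu", seq_len(n))
  if (nrow(pr)) df <- add(df, x$cov_nu, "cov_nu", pair_nm)
  df
}

# family accessor used by the evaluation layer
.traj_family <- function(traj, family) {
  stopifnot(inherits(traj, "stat_trajectory"))
  switch(family,
         mean_x = traj$mean_x, var_x = traj$var_x, cov_x = traj$cov_x,
         mean_nu = traj$mean_nu, var_nu = traj$var_nu, cov_nu = traj$cov_nu,
         stop("unknown statistic family: ", family))
}

#' The six statistic families
#'
#' Column-block names used across trajectories and error reports: mean,
#' variance, pairwise covariance of activity and of firing, in this order.
#' @export
stat_families <- c("mean_x", "var_x", "cov_x", "mean_nu", "var_nu", "cov_nu")
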