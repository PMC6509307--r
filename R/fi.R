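#' Sigmoidal F-I curve parameters
#'
#' The firing-rate nonlinearity used throughout the package is the bounded
#' sigmoid \deqn{F(x) = 0.5\,(1 + \tanh((x - x_{rev})/x_{sp})) \in [0, 1],}
#' mapping a cell's activity \eqn{x} to its instantaneous firing rate.
#' \code{x_rev} is the midpoint (activity at which the cell fires at half of
#' its maximum) and \code{x_sp} sets the gain: smaller values give a steeper,
#' more switch-like transfer.
#'
#' @param x_rev numeric scalar, sigmoid midpoint (activity units).
#' @param x_sp positive numeric scalar, slope scale (activity units).
#' @return An object of class \code{fi_params}.
#' @examples
#' f <- fi_params(0, 0.2)
#' fi_eval(f, 0)      # 0.5 at the midpoint
#' fi_eval(f, 10)     # saturates at 1
#' @export
fi_params <- function(x_rev, x_sp) {
  stopifnot(is.numeric(x_rev), length(x_rev) == 1L, is.finite(x_rev),
            is.numeric(x_sp), length(x_sp) == 1L, is.finite(x_sp))
  if (x_sp <= 0) stop("x_sp must be > 0")
  structure(list(x_rev = as.numeric(x_rev), x_sp = as.numeric(x_sp)),
            class = "fi_params")
}

#' Evaluate the F-I curve
#'
#' @param params an \code{\link{fi_params}} object, or an arbitrary function
#'   of one argument (a plug-in point used by tests for non-sigmoidal maps).
#' @param x numeric vector of activity values; must be finite.
#' @return \code{0.5 * (1 + tanh((x - x_rev)/x_sp))}, elementwise in
#'   \eqn{[0, 1]} and nondecreasing in \code{x}.
#' @export
fi_eval <- function(params, x) {
  if (!all(is.finite(x))) stop("fi_eval: 'x' must be finite")
  if (is.function(params)) return(params(x))
  stopifnot(inherits(params, "fi_params"))
  0.5 * (1 + tanh((x - params$x_rev) / params$x_sp))
}

# vectorized sigmoid over cells: x is order-by-ncell matrix (or vector),
# x_rev/x_sp recycled along columns
.fi_eval_cols <- function(x, x_rev, x_sp) {
  0.5 * (1 + tanh(sweep(sweep(x, 2, x_rev, "-"), 2, x_sp, "/")))
}
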