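#' Time-varying input signals
#'
#' Scalar drives applied to the background-input parameters of a network.
#' Three kinds are supported:
#' \describe{
#'   \item{constant}{\code{baseline} for all \eqn{t}.}
#'   \item{pulse}{a smooth double-sigmoid pulse
#'     \deqn{b + a\,[S((t - t_{on})/r) - S((t - t_{off})/r)]}
#'     with \eqn{S} the logistic function; \code{ramp} \eqn{r} sets the
#'     rise/fall timescale, so the pulse is differentiable (friendly to the
#'     adaptive ODE solver) yet arbitrarily fast.}
#'   \item{sinusoid}{\code{baseline + amplitude * sin(2*pi*freq*t + phase)}.}
#' }
#'
#' @param kind one of \code{"constant"}, \code{"pulse"}, \code{"sinusoid"}.
#' @param baseline numeric, value far from the pulse / sinusoid midline.
#' @param amplitude numeric, pulse height or sinusoid amplitude.
#' @param t_on,t_off pulse onset and offset times (\code{t_on < t_off}).
#' @param ramp positive pulse rise/fall timescale.
#' @param freq sinusoid frequency (cycles per time unit).
#' @param phase sinusoid phase (radians).
#' @return An object of class \code{rm_signal}, evaluable with
#'   \code{\link{signal_eval}}.
#' @examples
#' s <- input_signal("pulse", baseline = 0, amplitude = 1,
#'                   t_on = 2, t_off = 5, ramp = 0.1)
#' signal_eval(s, c(0, 3.5, 10))
#' @export
input_signal <- function(kind = c("constant", "pulse", "sinusoid"),
                         baseline = 0, amplitude = 1,
                         t_on = 2, t_off = 5, ramp = 0.1,
                         freq = 0.5, phase = 0) {
  kind <- match.arg(kind)
  params <- switch(kind,
    constant = list(baseline = baseline),
    pulse = {
      stopifnot(ramp > 0, t_on < t_off)
      list(baseline = baseline, amplitude = amplitude,
           t_on = t_on, t_off = t_off, ramp = ramp)
    },
    sinusoid = list(baseline = baseline, amplitude = amplitude,
                    freq = freq, phase = phase))
  stopifnot(all(vapply(params, function(p)
    is.numeric(p) && length(p) == 1L && is.finite(p), logical(1))))
  structure(list(kind = kind, params = params), class = "rm_signal")
}

#' Evaluate an input signal
#'
#' @param sig an \code{\link{input_signal}}.
#' @param t numeric vector of (finite) times.
#' @return numeric vector of the same length as \code{t}.
#' @export
signal_eval <- function(sig, t) {
  stopifnot(inherits(sig, "rm_signal"))
  if (!all(is.finite(t))) stop("signal_eval: 't' must be finite")
  p <- sig$params
  switch(sig$kind,
    constant = rep_len(p$baseline, length(t)),
    pulse = p$baseline + p$amplitude *
      (stats::plogis((t - p$t_on) / p$ramp) -
       stats::plogis((t - p$t_off) / p$ramp)),
    sinusoid = p$baseline + p$amplitude * sin(2 * pi * p$freq * t + p$phase))
}

#' Reference stimuli used in the package's experiments
#'
#' The bundled experiments drive every cell with a common background-mean
#' signal that is fast relative to the cells' time constants
#' (\eqn{\tau \approx 1}): a unit pulse from 0 up to 1 between \eqn{t = 2}
#' and \eqn{t = 5} with ramp 0.1, or a unit-amplitude sinusoid of period 2.
#' These defaults are fixed design choices of the package (see the methods
#' vignette), not tunables of the validation experiments.
#'
#' @return An \code{\link{input_signal}}.
#' @export
default_pulse <- function() {
  input_signal("pulse", baseline = 0, amplitude = 1,
               t_on = 2, t_off = 5, ramp = 0.1)
}

#' @rdname default_pulse
#' @param period sinusoid period (default 2, i.e. frequency 0.5); exposed so
#'   the adiabatic-limit experiments can slow the same stimulus down.
#' @export
default_sinusoid <- function(period = 2) {
  stopifnot(period > 0)
  input_signal("sinusoid", baseline = 0, amplitude = 1,
               freq = 1 / period, phase = 0)
}
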