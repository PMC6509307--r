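# Adaptive explicit Runge-Kutta integrator (Dormand-Prince 5(4)).
# Small, dependency-free replacement for a stiff-capable library solver:
# the closure system is smooth and non-stiff (weak coupling, tau ~ 1), so
# an embedded RK pair with standard PI-free step control suffices.

.dp_A <- rbind(
  c(0, 0, 0, 0, 0, 0),
  c(1/5, 0, 0, 0, 0, 0),
  c(3/40, 9/40, 0, 0, 0, 0),
  c(44/45, -56/15, 32/9, 0, 0, 0),
  c(19372/6561, -25360/2187, 64448/6561, -212/729, 0, 0),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656, 0))
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1)
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

# rhs(t, y) -> dy/dt; returns matrix length(times) x length(y0) of solutions
# at the requested times (times[1] is the initial time).
.ode_rk45 <- function(rhs, y0, times, rtol = 1e-8, atol = 1e-10,
                      max_steps = 1e6L) {
  stopifnot(length(times) >= 1L, all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, length(times), n)
  out[1L, ] <- y0
  if (length(times) == 1L) return(out)
  t <- times[1L]
  y <- y0
  f1 <- rhs(t, y)
  # initial step: conservative fraction of the first output interval
  h <- (times[2L] - times[1L]) / 100
  steps <- 0L
  next_i <- 2L
  while (next_i <= length(times)) {
    if (steps >= max_steps)
      stop("RK45: step limit exceeded at t = ", t)
    h <- min(h, times[length(times)] - t)
    hit <- t + h >= times[next_i] - 1e-14 * max(1, abs(times[next_i]))
    if (hit) h <- times[next_i] - t
    K <- matrix(0, 7L, n)
    K[1L, ] <- f1
    for (s in 2:6)
      K[s, ] <- rhs(t + .dp_c[s] * h,
                    y + h * as.numeric(.dp_A[s, 1:(s - 1)] %*%
                                         K[1:(s - 1), , drop = FALSE]))
    y5 <- y + h * as.numeric(.dp_b5 %*% K)
    K[7L, ] <- rhs(t + h, y5)
    # recompute y5 including K7 contribution (b5[7] = 0, so y5 unchanged)
    y4 <- y + h * as.numeric(.dp_b4 %*% K)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err))
      stop("RK45: non-finite state encountered at t = ", t,
           " (last valid time ", t, ")")
    if (err <= 1) {
      t <- t + h
      y <- y5
      f1 <- K[7L, ]                      # FSAL
      if (hit) { out[next_i, ] <- y; next_i <- next_i + 1L }
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    } else {
      h <- h * max(0.2, 0.9 * err^(-0.2))
      if (h < 1e-14 * max(1, abs(t)))
        stop("RK45: step-size underflow at t = ", t,
             " (last valid time ", t, ")")
    }
    steps <- steps + 1L
  }
  out
}
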