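# Adaptive explicit integrator (Cash-Karp RK45) with non-negativity
# clipping, plus a damped-Newton root polish used by the steady-state
# solver.  Written against the package's own RHS closures; no external
# solver dependency.

ck_a <- c(0, 1 / 5, 3 / 10, 3 / 5, 1, 7 / 8)
ck_b <- list(
  numeric(0),
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(3 / 10, -9 / 10, 6 / 5),
  c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
  c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
)
ck_c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
ck_c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296,
           277 / 14336, 1 / 4)

#' Integrate an ODE system with adaptive Runge-Kutta
#'
#' Cash-Karp embedded 4(5) pairs with PI-free step control, used for all
#' trajectory integration.  State is clipped at zero after every accepted
#' step: the saturating rate laws are undefined for negative
#' concentrations, so integrator under-shoot is guarded at the state
#' level.
#'
#' @param rhs Function `(t, y) -> dy` (named or unnamed numeric).
#' @param y0 Initial state (named numeric).
#' @param times Increasing vector of output times; `times[1]` is `t0`.
#' @param rtol,atol Relative / absolute local error tolerances.
#' @param max_steps Step budget before a numeric error is raised.
#' @return Matrix with a `time` column followed by one column per state.
#' @export
ode_integrate <- function(rhs, y0, times, rtol = 1e-8, atol = 1e-10,
                          max_steps = 2e5) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  y <- as.numeric(y0)
  nm <- names(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y) + 1,
                dimnames = list(NULL, c("time", nm)))
  out[1, ] <- c(times[1], y)
  t <- times[1]
  h <- (times[2] - times[1]) / 10
  steps <- 0
  k <- vector("list", 6)
  for (i in 2:length(times)) {
    t_end <- times[i]
    while (t < t_end) {
      h <- min(h, t_end - t)
      k[[1]] <- rhs(t, y)
      if (any(!is.finite(k[[1]]))) {
        bad <- nm[!is.finite(k[[1]])][1] %||% "?"
        stop("numeric error: non-finite derivative for species '", bad,
             "' at t=", signif(t, 6), call. = FALSE)
      }
      for (s in 2:6) {
        ys <- y
        bs <- ck_b[[s]]
        for (j in seq_along(bs)) ys <- ys + h * bs[j] * k[[j]]
        k[[s]] <- rhs(t + ck_a[s] * h, pmax(ys, 0))
      }
      y5 <- y
      y4 <- y
      for (s in 1:6) {
        y5 <- y5 + h * ck_c5[s] * k[[s]]
        y4 <- y4 + h * ck_c4[s] * k[[s]]
      }
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (!is.finite(err)) err <- 2
      if (err <= 1) {
        t <- t + h
        y <- pmax(y5, 0)
      }
      h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-16))^0.2))
      steps <- steps + 1
      if (steps > max_steps) {
        stop("numeric error: integrator exceeded ", max_steps,
             " steps (stiff or blowing up)", call. = FALSE)
      }
    }
    out[i, ] <- c(t, y)
  }
  out
}

# Finite-difference Jacobian of f at y restricted to indices `free`.
num_jacobian <- function(f, y, free, eps = 1e-7) {
  f0 <- f(y)[free]
  J <- matrix(0, length(free), length(free))
  for (j in seq_along(free)) {
    dy <- max(abs(y[free[j]]) * eps, eps)
    yp <- y
    yp[free[j]] <- yp[free[j]] + dy
    J[, j] <- (f(yp)[free] - f0) / dy
  }
  J
}

# Damped Newton iteration on the free (unclamped) coordinates of
# f(y) = 0. Steps are halved until the residual decreases; iterates are
# clipped at zero. Returns list(y, residual, converged).
newton_polish <- function(f, y, free, tol = 1e-6, max_iter = 50) {
  res <- function(y) max(abs(f(y)[free]))
  r0 <- res(y)
  for (it in seq_len(max_iter)) {
    if (r0 < tol * 1e-4) break
    J <- num_jacobian(f, y, free)
    step <- tryCatch(solve(J, -f(y)[free]), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:20) {
      y_try <- y
      y_try[free] <- pmax(y[free] + lambda * step, 0)
      r_try <- res(y_try)
      if (is.finite(r_try) && r_try < r0) {
        y <- y_try
        r0 <- r_try
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(y = y, residual = r0, converged = r0 < tol)
}
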