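# Generic stiff-ODE machinery: numeric Jacobian, an L-stable Rosenbrock
# integrator (ode23s coefficients: second order, embedded third-order error
# estimate) and a damped Newton root finder. Implemented here because the
# target system mixes capacitive charging (sub-millisecond) with
# concentration dynamics (minutes): ~7 orders of magnitude of stiffness.
#
# A useful structural fact exploited by the tests: linear invariants of the
# right-hand side (w . f(y) = 0 for all y, e.g. ion-mole conservation) are
# preserved exactly by every Rosenbrock stage, because w . J = 0 implies
# w . (I - h d J)^-1 = w.

.num_jacobian <- function(f, y, f0 = f(y)) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(abs(y[j]), 1e-3)
    yp <- y; yp[j] <- yp[j] + h
    J[, j] <- (f(yp) - f0) / h
  }
  J
}

# Integrate dy/dt = f(y) (autonomous) from t0 to t1, returning the solution
# sampled on seq(t0, t1, by = dt_out). Steps land exactly on output times.
.ros23 <- function(f, y0, t0, t1, dt_out, rtol = 1e-8, atol = 1e-9,
                   h0 = 1e-6, max_steps = 2e6) {
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  n <- length(y0)
  times <- seq(t0, t1, by = dt_out)
  if (times[length(times)] < t1) times <- c(times, t1)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0
  next_out <- 2L
  t <- t0; y <- y0; h <- min(h0, dt_out)
  steps <- 0L
  I <- diag(n)
  J <- NULL; steps_since_J <- 0L
  while (t < t1 - 1e-12) {
    if (steps >= max_steps) stop(sprintf(
      "integrator exceeded %d steps at t = %.6g s", max_steps, t), call. = FALSE)
    h <- min(h, times[next_out] - t)
    f0 <- f(y)
    # reuse the Jacobian across steps (refreshed periodically and on
    # rejection); the embedded error estimate guards the resulting accuracy
    if (is.null(J) || steps_since_J >= 20L) {
      J <- .num_jacobian(f, y, f0)
      steps_since_J <- 0L
    }
    rejected <- FALSE
    repeat {
      steps <- steps + 1L
      W <- I - (h * d) * J
      k1 <- solve(W, f0)
      res <- tryCatch({
        f1 <- f(y + 0.5 * h * k1)
        k2 <- solve(W, f1 - k1) + k1
        ynew <- y + h * k2
        f2 <- f(ynew)
        k3 <- solve(W, f2 - e32 * (k2 - f1) - 2 * (k1 - f0))
        err <- (h / 6) * (k1 - 2 * k2 + k3)
        sc <- atol + rtol * pmax(abs(y), abs(ynew))
        list(ynew = ynew, enorm = sqrt(mean((err / sc)^2)))
      }, error = function(e) NULL)   # state left the physical domain: retry smaller
      if (!is.null(res)) { ynew <- res$ynew; enorm <- res$enorm } else enorm <- Inf
      if (enorm <= 1) break
      if (!rejected && steps_since_J > 0L) {
        # refresh a stale Jacobian before blaming the step size
        J <- .num_jacobian(f, y, f0); steps_since_J <- 0L; rejected <- TRUE
        next
      }
      rejected <- TRUE
      h <- h * max(0.2, 0.9 * (if (is.finite(enorm)) enorm^(-1/3) else 0.2))
      if (h < 1e-14) stop(sprintf(
        "integrator step size underflow at t = %.6g s", t), call. = FALSE)
    }
    t <- t + h; y <- ynew
    steps_since_J <- steps_since_J + 1L
    while (next_out <= length(times) && t >= times[next_out] - 1e-9) {
      out[next_out, ] <- y
      next_out <- next_out + 1L
    }
    fac <- if (enorm > 0) min(5, max(0.2, 0.9 * enorm^(-1/3))) else 5
    h <- h * fac
  }
  if (next_out <= length(times)) out[next_out:length(times), ] <- rep(y, each = length(times) - next_out + 1)
  list(times = times, y = out, steps = steps, y_end = y)
}

# Newton for F(y) = 0 with a non-monotone line search: the full step is
# preferred (Newton transients may raise ||F|| for a few iterations before
# quadratic convergence sets in), damping is only used to stay inside the
# feasible domain. `guard` may reject a candidate state (e.g. non-positive
# concentrations) by returning FALSE.
.newton <- function(Ffun, y0, tol = 1e-10, max_iter = 60, guard = NULL) {
  y <- y0
  f <- Ffun(y)
  nf0 <- sqrt(sum(f^2))
  for (it in seq_len(max_iter)) {
    J <- .num_jacobian(Ffun, y, f)
    step <- tryCatch(qr.solve(J, -f), error = function(e)
      stop("singular Jacobian in Newton iteration; residual profile: ",
           paste(sprintf("%.3g", f), collapse = " "), call. = FALSE))
    lambda <- 1
    accepted <- FALSE
    while (lambda >= 1e-8) {
      cand <- y + lambda * step
      if (is.null(guard) || guard(cand)) {
        fc <- tryCatch(Ffun(cand), error = function(e) NULL)
        if (!is.null(fc) && all(is.finite(fc))) {
          y <- cand; f <- fc; accepted <- TRUE; break
        }
      }
      lambda <- lambda / 2
    }
    if (!accepted) stop(
      "Newton iteration stalled at the feasibility boundary; residual profile: ",
      paste(sprintf("%.3g", f), collapse = " "), call. = FALSE)
    if (max(abs(f) / (1 + abs(y))) < tol) {
      return(list(y = y, residual = f, iterations = it))
    }
    if (sqrt(sum(f^2)) > 1e10 * (nf0 + 1)) break
  }
  stop("Newton iteration did not converge; residual profile: ",
       paste(sprintf("%.3g", f), collapse = " "), call. = FALSE)
}
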