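#' Adaptive Rosenbrock 2(3) integration of an arbitrary R right-hand side
#'
#' Pure-R implementation of the same L-stable Rosenbrock scheme as the
#' compiled integrator, for use with arbitrary (e.g. dimensional) RHS
#' functions. Jacobian by forward differences. Used as the independent
#' integration route in the dimensional/dimensionless consistency checks.
#'
#' @param f Function `f(t, y)` returning the derivative vector.
#' @param y0 Initial state (numeric vector).
#' @param times Strictly increasing output times; integration spans the
#'   range.
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param hmax Maximum step size.
#' @param max_steps Hard cap on accepted+rejected steps.
#' @return Matrix with `length(times)` rows of states.
#' @export
ros23_r <- function(f, y0, times, rtol = 1e-8, atol = 1e-12, hmax = Inf,
                    max_steps = 2e6) {
  n <- length(y0)
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  t_end <- times[length(times)]
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0
  next_out <- 2L
  y <- as.numeric(y0)
  t <- times[1]
  f0 <- f(t, y)
  nsteps <- 0L

  num_jac <- function(y, f0) {
    J <- matrix(0, n, n)
    sq <- sqrt(.Machine$double.eps)
    for (j in seq_len(n)) {
      dj <- sq * max(abs(y[j]), 1e-6)
      yp <- y
      yp[j] <- y[j] + dj
      dj <- yp[j] - y[j]
      J[, j] <- (f(t, yp) - f0) / dj
    }
    J
  }

  h <- min((t_end - t) / 100, hmax)
  I_n <- diag(n)
  while (t < t_end) {
    nsteps <- nsteps + 1L
    if (nsteps > max_steps)
      stop("ros23_r: step limit exceeded at t = ", t, call. = FALSE)
    h <- min(h, t_end - t)
    J <- num_jac(y, f0)
    repeat {
      Wm <- I_n - h * d * J
      k1 <- solve(Wm, f0)
      f1 <- f(t + 0.5 * h, y + 0.5 * h * k1)
      k2 <- solve(Wm, f1 - k1) + k1
      ynew <- y + h * k2
      f2 <- f(t + h, ynew)
      k3 <- solve(Wm, f2 - e32 * (k2 - f1) - 2 * (k1 - f0))
      err <- (h / 6) * (k1 - 2 * k2 + k3)
      sc <- atol + rtol * pmax(abs(y), abs(ynew))
      enorm <- max(abs(err) / sc)
      if (enorm <= 1 || h <= abs(t) * 4e-15) break
      h <- h * max(0.2, 0.9 * enorm^(-1 / 3))
      nsteps <- nsteps + 1L
      if (nsteps > max_steps)
        stop("ros23_r: step limit exceeded at t = ", t, call. = FALSE)
    }
    tnew <- t + h
    while (next_out <= length(times) && times[next_out] <= tnew * (1 + 4e-16)) {
      s <- (min(times[next_out], tnew) - t) / h
      yi <- (2 * s^3 - 3 * s^2 + 1) * y + (s^3 - 2 * s^2 + s) * h * f0 +
        (-2 * s^3 + 3 * s^2) * ynew + (s^3 - s^2) * h * f2
      out[next_out, ] <- pmax(yi, 0)
      next_out <- next_out + 1L
    }
    y <- pmax(ynew, 0)
    t <- tnew
    f0 <- f2
    h <- min(h * min(5, max(0.2, 0.9 * max(enorm, 1e-10)^(-1 / 3))), hmax)
  }
  if (next_out <= length(times)) out[length(times), ] <- y
  out
}

# thin wrapper over the compiled integrator returning named output
ros23_dimless <- function(y0, times, q, sources = NULL, rtol = 1e-8,
                          atol = 1e-12, hmax = Inf, neg_tol = 1e-9) {
  s <- as_sources(sources)
  res <- .hl_ros23_cpp(as.numeric(y0), as.numeric(times), as.numeric(q),
                       as.numeric(s), rtol, atol, hmax, neg_tol)
  colnames(res$y) <- hl_state_names()
  names(res$final_state) <- hl_state_names()
  res
}
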