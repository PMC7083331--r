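# Independent oracles used across the suite. These never call the
# package's analytic solvers: the master equation is integrated directly
# (deSolve) or solved by eigendecomposition of the generator.

# generator matrix (acting on a column probability vector) from a
# transition system built by the package: A[to, from] += rate
generator_from_system <- function(sys) {
  n <- sys$n_states
  from <- max.col(sys$sources, ties.method = "first")
  to <- max.col(sys$targets, ties.method = "first")
  A <- matrix(0, n, n)
  for (i in seq_along(sys$rates)) {
    A[to[i], from[i]] <- A[to[i], from[i]] + sys$rates[i]
    A[from[i], from[i]] <- A[from[i], from[i]] - sys$rates[i]
  }
  A
}

# integrate dp/dt = A p from p(0) = e1 at the given times (deSolve)
ode_occupancy_oracle <- function(A, times) {
  p0 <- c(1, rep(0, nrow(A) - 1L))
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y = p0, times = tt,
                      func = function(t, y, parms) list(A %*% y),
                      rtol = 1e-10, atol = 1e-12)
  out <- sol[match(times, tt), -1L, drop = FALSE]
  unname(as.matrix(out))
}

# eigendecomposition matrix exponential (small dense generators)
eigen_occupancy_oracle <- function(A, times) {
  ee <- eigen(A)
  Vinv <- solve(ee$vectors)
  p0 <- c(1, rep(0, nrow(A) - 1L))
  t(sapply(times, function(t)
    Re(ee$vectors %*% (exp(ee$values * t) * (Vinv %*% p0)))))
}

# simultaneous multinomial bound: TRUE if every |emp - p| is within the
# Bonferroni-corrected normal bound at family level alpha
within_multinomial_bounds <- function(emp, p, n, alpha = 0.01) {
  z <- qnorm(1 - alpha / (2 * length(p)))
  all(abs(emp - p) <= z * sqrt(pmax(p * (1 - p), 1e-12) / n) + 1 / n)
}

# trapezoid integral on a grid (independent of the package's Simpson rule)
trapz <- function(x, y) sum((y[-1L] + y[-length(y)]) / 2 * diff(x))
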