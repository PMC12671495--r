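# Independent oracles used across test files.

# Brute-force integration of the closure kinetics dC/dt = k (1-C)/(1 - p C)
# with a generic stiff ODE solver; independent of the package's implicit
# bisection path.
ode_closure_oracle <- function(t_grid, k_ph, J) {
  p <- J / (1 + J)
  rhs <- function(t, state, parms) {
    C <- min(max(state[1L], 0), 1 - 1e-14)
    list(k_ph * (1 - C) / (1 - p * C))
  }
  sol <- deSolve::lsoda(c(C = 0), times = t_grid, func = rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  pmin(pmax(sol[, "C"], 0), 1)
}

# Numeric root-finder oracle for the time at which V crosses a level, using
# the ODE oracle plus interpolation (never the package's closed form).
ode_t_at_V <- function(level, k_ph, J, t_max = 10) {
  t <- seq(0, t_max, length.out = 4001)
  C <- ode_closure_oracle(t, k_ph, J)
  p <- J / (1 + J)
  V <- (1 - p) * C / (1 - p * C)
  stats::approx(V, t, xout = level, ties = "ordered")$y
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

with_seed_for_tests <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
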