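# Shared oracle helpers: random stable affine systems and a Runge-Kutta
# reference solver (deSolve), independent of the package's matrix-
# exponential path.

random_stable_system <- function(masked = TRUE) {
  A <- matrix(rnorm(25, 0, 0.3), 5, 5)
  diag(A) <- -abs(rnorm(5, 0.5, 0.2))   # diagonally dominant-ish: stable
  if (masked) A[1:2, 3:5] <- 0
  b <- rnorm(5, 0, 0.2)
  if (masked) {
    vp <- velocity_params(A, v0 = b)
    assemble_system(vp, covariate_vector(0, 0))
  } else {
    structure(list(A = A, b = b), class = "affine_system")
  }
}

rk_trajectory <- function(x0, sys, times) {
  f <- function(t, y, parms) list(drop(sys$A %*% y) + sys$b)
  t0 <- sort(unique(c(0, times)))
  out <- deSolve::ode(y = x0, times = t0, func = f, parms = NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-10)
  unname(out[match(times, t0), -1, drop = FALSE])
}

tiny_cohort <- function(...) make_fixture("tiny", ...)
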