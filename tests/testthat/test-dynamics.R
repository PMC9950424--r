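test_that("assemble_system combines covariate effects elementwise", {
  vp0 <- velocity_params(matrix(0, 5, 5))
  y0 <- covariate_vector(0, 0)
  sys <- assemble_system(vp0, y0)
  expect_equal(unname(sys$A), matrix(0, 5, 5))
  expect_equal(unname(sys$b), rep(0, 5))

  set.seed(42)
  for (rep in 1:5) {
    mk <- function() {
      M <- matrix(rnorm(25), 5, 5)
      M[1:2, 3:5] <- 0
      M
    }
    V <- mk(); Wa <- mk(); Wp <- mk()
    v0 <- rnorm(5)
    vp <- velocity_params(V, Wa, Wp, v0)
    age <- rnorm(1)
    apoe <- sample(0:1, 1)
    sys <- assemble_system(vp, covariate_vector(age, apoe))
    # independent loop-based summation oracle
    expected <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5)
      expected[i, j] <- V[i, j] + age * Wa[i, j] + apoe * Wp[i, j]
    expect_equal(unname(sys$A), expected, tolerance = 1e-12)
    expect_equal(unname(sys$b), v0)
    expect_true(all(sys$A[1:2, 3:5] == 0))
  }
})

test_that("velocity matrices reject violations of the CSF x cognition zero block", {
  V <- matrix(1, 5, 5)
  expect_error(velocity_params(V), "zero")
  mask <- velocity_sparsity_mask()
  expect_true(all(mask[1:2, 3:5]))
  expect_equal(sum(mask), 6L)
})

test_that("velocity_at equals a row-by-row dot-product oracle", {
  set.seed(7)
  sys <- random_stable_system(masked = FALSE)
  x <- rnorm(5)
  naive <- vapply(1:5, function(i) sum(sys$A[i, ] * x) + sys$b[i], 0)
  expect_equal(unname(velocity_at(x, sys)), naive, tolerance = 1e-14)
  expect_equal(unname(velocity_at(rep(0, 5), sys)), unname(sys$b))
  null_sys <- structure(list(A = matrix(0, 5, 5), b = rep(0, 5)),
                        class = "affine_system")
  expect_equal(unname(velocity_at(rnorm(5), null_sys)), rep(0, 5))
})

test_that("solve_trajectory handles degenerate systems in closed form", {
  x0 <- c(1, -2, 0.5, 3, -1)
  null_sys <- structure(list(A = matrix(0, 5, 5), b = rep(0, 5)),
                        class = "affine_system")
  traj <- solve_trajectory(x0, null_sys, c(-3, 0, 1, 10))
  for (i in 1:4) expect_equal(unname(traj[i, ]), x0, tolerance = 1e-12)

  drift <- structure(list(A = matrix(0, 5, 5), b = 1:5 / 10),
                     class = "affine_system")
  traj <- solve_trajectory(x0, drift, c(0, 2, -4))
  expect_equal(unname(traj[2, ]), x0 + 2 * (1:5 / 10), tolerance = 1e-10)
  expect_equal(unname(traj[3, ]), x0 - 4 * (1:5 / 10), tolerance = 1e-10)
})

test_that("scalar affine subsystem matches its closed form", {
  # dx/dt = -x/2 + 1, x(0) = 0  =>  x(t) = 2(1 - exp(-t/2))
  sys <- structure(list(A = matrix(-0.5, 1, 1), b = 1),
                   class = "affine_system")
  ts <- c(0.5, 1, 2, 5, 10)
  traj <- solve_trajectory(0, sys, ts)
  expect_equal(traj[, 1], 2 * (1 - exp(-ts / 2)), tolerance = 1e-10)
  expect_equal(traj[ts == 2, 1], 2 * (1 - exp(-1)), tolerance = 1e-10)
})

test_that("matrix-exponential trajectories match the Runge-Kutta oracle", {
  set.seed(1)
  ts <- seq(0.5, 20, by = 0.5)
  for (rep in 1:20) {
    sys <- random_stable_system()
    x0 <- rnorm(5)
    expect_lt(max(abs(solve_trajectory(x0, sys, ts) -
                        rk_trajectory(x0, sys, ts))), 1e-6)
  }
})

test_that("trajectories obey the semigroup and time-reversal properties", {
  set.seed(2)
  for (rep in 1:10) {
    sys <- random_stable_system()
    x0 <- rnorm(5)
    t1 <- runif(1, 0.5, 5)
    dt <- runif(1, 0.5, 5)
    x_t1 <- solve_trajectory(x0, sys, t1)[1, ]
    via <- solve_trajectory(x_t1, sys, dt)[1, ]
    direct <- solve_trajectory(x0, sys, t1 + dt)[1, ]
    expect_equal(via, direct, tolerance = 1e-9)
    back <- solve_trajectory(x_t1, sys, -t1)[1, ]
    expect_equal(unname(back), x0, tolerance = 1e-8)
  }
})

test_that("augmented exponential agrees with an explicit expm cross-check", {
  set.seed(3)
  sys <- random_stable_system()
  x0 <- rnorm(5)
  t <- 3.7
  M <- rbind(cbind(sys$A, sys$b), 0) * t
  E <- as.matrix(Matrix::expm(M))
  expect_equal(solve_trajectory(x0, sys, t)[1, ],
               drop(E[1:5, 1:5] %*% x0 + E[1:5, 6]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("CSF components are unaffected by cognitive initial values", {
  set.seed(4)
  for (rep in 1:10) {
    sys <- random_stable_system()          # masked block
    x0 <- rnorm(5)
    x0_pert <- x0 + c(0, 0, rnorm(3))
    ts <- seq(-5, 15, by = 1)
    t1 <- solve_trajectory(x0, sys, ts)[, 1:2]
    t2 <- solve_trajectory(x0_pert, sys, ts)[, 1:2]
    expect_lt(max(abs(t1 - t2)), 1e-10)
  }
})

test_that("solver reports the offending time on overflow", {
  sys <- structure(list(A = diag(5) * 50, b = rep(0, 5)),
                   class = "affine_system")
  expect_error(solve_trajectory(rep(1, 5), sys, c(1, 500)), "500")
})
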