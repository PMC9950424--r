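# Canonical state ordering used everywhere in the package:
# [tau, abeta, lang, mem, praxis].  The CSF block is components 1-2, the
# cognitive block components 3-5.

#' Channel names of the dynamical state vector
#'
#' The five dynamical variables, in their canonical order: CSF total tau,
#' CSF amyloid-beta 1-42, and the language, memory and praxis cognitive
#' traits.
#'
#' @return Character vector of length 5.
#' @export
adpm_channels <- function() c("tau", "abeta", "lang", "mem", "praxis")

.n_state <- 5L
.csf_idx <- 1:2
.cog_idx <- 3:5

#' Forced-zero pattern of the velocity matrices
#'
#' Biomarker velocities are assumed unaffected by cognitive status: the
#' rows of the CSF block (tau, abeta) receive no input from the cognitive
#' columns (lang, mem, praxis).  `TRUE` entries mark the forced zeros.
#'
#' @return A 5x5 logical matrix.
#' @export
velocity_sparsity_mask <- function() {
  m <- matrix(FALSE, .n_state, .n_state,
              dimnames = list(adpm_channels(), adpm_channels()))
  m[.csf_idx, .cog_idx] <- TRUE
  m
}

.check_mask <- function(M, name) {
  mask <- velocity_sparsity_mask()
  if (any(abs(M[mask]) > 0))
    stop(sprintf("'%s' must be zero on the CSF x cognition block", name),
         call. = FALSE)
}

.as_state_matrix <- function(M, name) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(.n_state, .n_state)))
    stop(sprintf("'%s' must be a 5x5 matrix", name), call. = FALSE)
  if (!all(is.finite(M)))
    stop(sprintf("'%s' has non-finite entries", name), call. = FALSE)
  dimnames(M) <- list(adpm_channels(), adpm_channels())
  M
}

#' Velocity-field parameters
#'
#' Bundles the population velocity matrix `V`, the covariate-effect matrices
#' `W_age` and `W_apoe`, and the constant drift `v0` of the affine velocity
#' field v(x, y) = (V + age_std W_age + apoe4 W_apoe) x + v0.  All matrices
#' must respect the forced-zero CSF x cognition block
#' (see [velocity_sparsity_mask()]).
#'
#' @param V,W_age,W_apoe 5x5 numeric matrices (units: 1/year on the
#'   standardized latent scale).
#' @param v0 Numeric drift vector of length 5 (latent units/year).
#' @return An object of class `velocity_params`.
#' @export
velocity_params <- function(V, W_age = matrix(0, 5, 5),
                            W_apoe = matrix(0, 5, 5), v0 = numeric(5)) {
  V <- .as_state_matrix(V, "V")
  W_age <- .as_state_matrix(W_age, "W_age")
  W_apoe <- .as_state_matrix(W_apoe, "W_apoe")
  v0 <- as.numeric(v0)
  if (length(v0) != .n_state || !all(is.finite(v0)))
    stop("'v0' must be a finite vector of length 5", call. = FALSE)
  .check_mask(V, "V")
  .check_mask(W_age, "W_age")
  .check_mask(W_apoe, "W_apoe")
  structure(list(V = V, W_age = W_age, W_apoe = W_apoe,
                 v0 = setNames(v0, adpm_channels()),
                 sparsity_mask = velocity_sparsity_mask()),
            class = "velocity_params")
}

#' Covariate vector of one subject
#'
#' @param age_std Baseline age, standardized (see [adpm_config()] for the
#'   centering constants); frozen along the trajectory.
#' @param apoe4 APOE epsilon-4 carrier status, 0 or 1.
#' @return An object of class `covariate_vector`.
#' @export
covariate_vector <- function(age_std, apoe4) {
  if (!is.finite(age_std)) stop("'age_std' must be finite", call. = FALSE)
  if (!apoe4 %in% c(0, 1)) stop("'apoe4' must be 0 or 1", call. = FALSE)
  structure(list(age_std = as.numeric(age_std), apoe4 = as.integer(apoe4)),
            class = "covariate_vector")
}

#' Assemble the subject-specific affine system
#'
#' Collapses the velocity-field parameters and one subject's covariates into
#' the affine system dx/dt = A x + b with
#' A = V + age_std W_age + apoe4 W_apoe and b = v0.
#'
#' @param params A [velocity_params()] object.
#' @param y A [covariate_vector()].
#' @return An object of class `affine_system` with elements `A` and `b`.
#' @export
assemble_system <- function(params, y) {
  stopifnot(inherits(params, "velocity_params"),
            inherits(y, "covariate_vector"))
  A <- params$V + y$age_std * params$W_age + y$apoe4 * params$W_apoe
  structure(list(A = A, b = params$v0), class = "affine_system")
}

#' Evaluate the velocity field at a state
#'
#' @param x Numeric state vector (length 5 for the disease model; any length
#'   matching the system is accepted).
#' @param sys An `affine_system` (see [assemble_system()]).
#' @return The velocity A x + b.
#' @export
velocity_at <- function(x, sys) {
  stopifnot(inherits(sys, "affine_system"))
  x <- as.numeric(x)
  if (length(x) != nrow(sys$A))
    stop("state length does not match the system dimension", call. = FALSE)
  if (!all(is.finite(x))) stop("state has non-finite entries", call. = FALSE)
  drop(sys$A %*% x) + sys$b
}

#' Exact trajectory of the affine linear ODE
#'
#' Solves dx/dt = A x + b with x(0) = x0 at the requested times through the
#' augmented matrix exponential expm(\[\[A, b\], \[0, 0\]\] t), which needs
#' no inversion of A and therefore handles singular systems.  Negative times
#' propagate backwards.
#'
#' @param x0 Initial state.
#' @param sys An `affine_system`.
#' @param times Numeric vector of times in years (t = 0 at the subject's
#'   first observation); may be negative.
#' @return A `length(times)` x d matrix of states, one row per time.
#' @export
solve_trajectory <- function(x0, sys, times) {
  stopifnot(inherits(sys, "affine_system"))
  x0 <- as.numeric(x0)
  times <- as.numeric(times)
  if (length(x0) != nrow(sys$A))
    stop("initial state length does not match the system", call. = FALSE)
  if (!all(is.finite(times))) stop("'times' must be finite", call. = FALSE)
  out <- cpp_solve_trajectory(sys$A, sys$b, x0, times)
  bad <- !apply(is.finite(out), 1, all)
  if (any(bad))
    stop(sprintf("trajectory overflow at t = %g (unstable system?)",
                 times[which(bad)[1]]), call. = FALSE)
  colnames(out) <- names(x0) %||% colnames(sys$A)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
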