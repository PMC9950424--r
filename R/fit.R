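# Hierarchical Bayesian inference: the adpm() fitting function and methods.

# ---- flat data container handed to the C++ likelihood/sampler -------------
.adpm_pack_data <- function(cohort, config) {
  sub <- cohort$subjects
  obs <- cohort$observations
  dg <- cohort$diagnoses
  nsub <- nrow(sub)
  sid <- as.character(sub$subject_id)
  links <- config$links

  ob_sub <- ob_tidx <- ob_chan <- ob_cens <- integer(0)
  ob_val <- ob_se <- numeric(0)
  dg_sub <- dg_tidx <- dg_lab <- integer(0)
  ut <- numeric(0)
  ut_start <- ob_start <- dg_start <- integer(nsub + 1)
  lab_code <- c(CN = 0L, MCI = 1L, AD = 2L)

  for (s in seq_len(nsub)) {
    o <- obs[obs$subject_id == sid[s], , drop = FALSE]
    d <- dg[dg$subject_id == sid[s], , drop = FALSE]
    u <- sort(unique(c(o$time_years, d$time_years)))
    ut <- c(ut, u)
    ut_start[s + 1] <- length(ut)
    ob_sub <- c(ob_sub, rep(s - 1L, nrow(o)))
    ob_tidx <- c(ob_tidx, match(o$time_years, u) - 1L)
    ob_chan <- c(ob_chan, match(o$channel, adpm_channels()) - 1L)
    ob_cens <- c(ob_cens, as.integer(o$censored))
    ob_val <- c(ob_val, o$value)
    ob_se <- c(ob_se, if (is.null(o$se)) rep(0, nrow(o)) else o$se)
    ob_start[s + 1] <- length(ob_val)
    dg_sub <- c(dg_sub, rep(s - 1L, nrow(d)))
    dg_tidx <- c(dg_tidx, match(d$time_years, u) - 1L)
    dg_lab <- c(dg_lab, lab_code[as.character(d$label)])
    dg_start[s + 1] <- length(dg_lab)
  }
  get <- function(f) vapply(links, function(l) l[[f]], 0)[adpm_channels()]
  list(nsub = nsub,
       age = .std_age(sub$age, config), apoe = as.numeric(sub$apoe4),
       ut = ut, ut_start = as.integer(ut_start),
       ob_sub = ob_sub, ob_tidx = ob_tidx, ob_chan = ob_chan,
       ob_cens = ob_cens, ob_start = as.integer(ob_start), ob_val = ob_val,
       ob_se = ob_se, dg_sub = dg_sub, dg_tidx = dg_tidx, dg_lab = as.integer(dg_lab),
       dg_start = as.integer(dg_start),
       link_lower = get("lower"), link_upper = get("upper"),
       link_slope = get("slope"), link_mid = get("midpoint"),
       cens_upper = unname(.censor_limits(config)),
       w = config$likelihood_weight)
}

# rough velocity start values: ridge regression of inverse-link finite
# differences on midpoint states, using visits where all channels were
# observed (possible on synchronized schedules; returns NULL otherwise)
.velocity_ridge_init <- function(cohort, config, lambda = 1) {
  obs <- cohort$observations[cohort$observations$censored == 0, ,
                             drop = FALSE]
  ch <- adpm_channels()
  rows_x <- list()
  rows_dz <- list()
  covs <- list()
  for (s in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[s]
    o <- obs[obs$subject_id == sid, , drop = FALSE]
    times <- sort(unique(o$time_years))
    full <- times[vapply(times, function(tt)
      all(ch %in% o$channel[o$time_years == tt]), TRUE)]
    if (length(full) < 2) next
    z <- t(vapply(full, function(tt) {
      vapply(ch, function(k)
        inv_sigmoid_link(o$value[o$time_years == tt & o$channel == k][1],
                         config$links[[k]]), 0)
    }, numeric(5)))
    for (i in seq_len(length(full) - 1)) {
      dt <- full[i + 1] - full[i]
      if (dt <= 0) next
      rows_dz[[length(rows_dz) + 1]] <- (z[i + 1, ] - z[i, ]) / dt
      rows_x[[length(rows_x) + 1]] <- (z[i + 1, ] + z[i, ]) / 2
      covs[[length(covs) + 1]] <- c(.std_age(cohort$subjects$age[s], config),
                                    cohort$subjects$apoe4[s])
    }
  }
  if (length(rows_x) < 30) return(NULL)
  X0 <- do.call(rbind, rows_x)
  DZ <- do.call(rbind, rows_dz)
  CV <- do.call(rbind, covs)
  V <- W1 <- W2 <- matrix(0, 5, 5)
  v0 <- numeric(5)
  mask <- !velocity_sparsity_mask()
  for (k in seq_len(5)) {
    use <- which(mask[k, ])
    X <- cbind(X0[, use, drop = FALSE],
               CV[, 1] * X0[, use, drop = FALSE],
               CV[, 2] * X0[, use, drop = FALSE], 1)
    beta <- solve(crossprod(X) + lambda * diag(ncol(X)),
                  crossprod(X, DZ[, k]))
    m <- length(use)
    V[k, use] <- beta[seq_len(m)]
    W1[k, use] <- beta[m + seq_len(m)]
    W2[k, use] <- beta[2 * m + seq_len(m)]
    v0[k] <- beta[3 * m + 1]
  }
  list(V = V, W_age = W1, W_apoe = W2, v0 = v0)
}

# initial values: back-transform each subject's earliest observation per
# channel through the link; empty channels fall back to the column mean
.adpm_init <- function(dat, config, cohort) {
  nsub <- dat$nsub
  x0 <- matrix(NA_real_, nsub, 5)
  obs <- cohort$observations
  sid <- as.character(cohort$subjects$subject_id)
  for (s in seq_len(nsub)) {
    o <- obs[obs$subject_id == sid[s] & obs$censored == 0, , drop = FALSE]
    for (k in seq_len(5)) {
      ok <- o[o$channel == adpm_channels()[k], , drop = FALSE]
      if (nrow(ok)) {
        first <- ok[which.min(ok$time_years), ]
        x0[s, k] <- inv_sigmoid_link(first$value,
                                     config$links[[adpm_channels()[k]]])
      }
    }
  }
  mu_fallback <- colMeans(x0, na.rm = TRUE)
  mu_fallback[!is.finite(mu_fallback)] <- 0
  for (k in seq_len(5)) x0[is.na(x0[, k]), k] <- mu_fallback[k]

  lab <- dat$dg_lab
  p_cn <- max(mean(lab == 0), 0.02)
  p_ad <- max(mean(lab == 2), 0.02)
  vel <- .velocity_ridge_init(cohort, config) %||%
    list(V = matrix(0, 5, 5), W_age = matrix(0, 5, 5),
         W_apoe = matrix(0, 5, 5), v0 = numeric(5))
  list(V = vel$V, W_age = vel$W_age,
       W_apoe = vel$W_apoe, v0 = vel$v0,
       sigma = unname(config$sigma_init[adpm_channels()]),
       mu0 = unname(mu_fallback),
       tau0 = pmax(apply(x0, 2, sd), 0.3),
       beta_x = numeric(5), beta_y = numeric(2),
       link_slope = unname(vapply(config$links, `[[`, 0, "slope")),
       link_mid = unname(vapply(config$links, `[[`, 0, "midpoint")),
       c1 = qlogis(p_cn), c2 = qlogis(min(1 - p_ad, 0.98)), x0 = x0)
}

.free_idx <- function() which(!velocity_sparsity_mask())

.pop_names <- function() {
  ch <- adpm_channels()
  free <- .free_idx()
  nm_mat <- function(tag) {
    full <- outer(ch, ch, function(i, j) sprintf("%s[%s,%s]", tag, i, j))
    full[free]
  }
  c(nm_mat("V"), nm_mat("W_age"), nm_mat("W_apoe"),
    paste0("v0[", ch, "]"), paste0("sigma[", ch, "]"),
    paste0("mu0[", ch, "]"), paste0("tau0[", ch, "]"),
    "c1", "c2", paste0("beta_x[", ch, "]"),
    c("beta_y[age]", "beta_y[apoe4]"),
    paste0("slope[", ch, "]"), paste0("mid[", ch, "]"))
}

# split-half Rhat (rank-free classic formula on split chains)
.split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (m in draws_by_chain) {
    n <- floor(length(m) / 2)
    if (n < 2) return(NA_real_)
    halves <- c(halves, list(m[1:n]), list(m[(n + 1):(2 * n)]))
  }
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the disease-progression model
#'
#' Samples the joint posterior of the velocity-field parameters, observation
#' noise, ordered-logit diagnosis layer, hierarchical initial-state
#' population parameters, and per-subject initial states, given a cohort of
#' irregular longitudinal observations.  The velocity-field group and all
#' subject initial states move jointly by Hamiltonian Monte Carlo with exact
#' adjoint gradients through the matrix exponential; noise sds, link shapes
#' and the ordered-logit block use covariance-adapted Metropolis proposals;
#' the initial-state population mean is a conjugate Gibbs draw.  Step sizes
#' and the diagonal mass matrix adapt during warmup only.  An additional
#' cheap per-subject Metropolis refresh of the initial states uses the
#' cached trajectory operators (no matrix exponentials).
#'
#' @param cohort An `adpm_cohort`.
#' @param config An [adpm_config()]; `config$mcmc` controls chains, warmup,
#'   retained iterations and the seed.
#' @param ... Convenience overrides of `config$mcmc` entries
#'   (e.g. `iter = 500`).
#' @return An object of class `adpm` with posterior draws, convergence
#'   diagnostics (split-Rhat, effective sample size), acceptance rates, and
#'   the data/config used.
#' @export
adpm <- function(cohort, config = adpm_config(), ...) {
  stopifnot(inherits(cohort, "adpm_cohort"))
  if (nrow(cohort$subjects) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (nrow(cohort$observations) == 0)
    stop("cohort has no observations", call. = FALSE)
  mc <- .merge_config(config$mcmc, list(...))

  dat <- .adpm_pack_data(cohort, config)
  init <- .adpm_init(dat, config, cohort)
  rng <- (config$links[[1]]$upper - config$links[[1]]$lower)
  priors <- c(config$priors[c("velocity_sd", "mu0_sd", "tau0_scale",
                              "clinical_sd", "log_gap_sd", "log_slope_sd",
                              "midpoint_sd")],
              list(sigma_scale = config$priors$sigma_scale_rel *
                     vapply(config$links, function(l)
                       (l$upper - l$lower) / 4, 0)[adpm_channels()],
                   midpoint_anchor = init$link_mid))
  control <- list(warmup = as.integer(mc$warmup), iter = as.integer(mc$iter),
                  estimate_covariate_effects =
                    isTRUE(config$estimate_covariate_effects),
                  estimate_links = isTRUE(config$estimate_links),
                  vel_updates = as.integer(mc$vel_updates %||% 1),
                  hmc_steps = as.integer(mc$hmc_steps %||% 8),
                  x0_refresh = !isFALSE(mc$x0_refresh),
                  refresh = as.integer(mc$refresh %||% 0))

  chains <- as.integer(mc$chains)
  pop_list <- vector("list", chains)
  x0_list <- vector("list", chains)
  accept <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(mc$seed) + 1000L * (ch - 1L))
    res <- cpp_adpm_mcmc(dat, init, priors, control)
    colnames(res$pop) <- .pop_names()
    pop_list[[ch]] <- res$pop
    x0_list[[ch]] <- res$x0
    accept[[ch]] <- res$accept
  }
  pop <- do.call(rbind, pop_list)
  chain_id <- rep(seq_len(chains), each = as.integer(mc$iter))

  # convergence diagnostics on the sampled population parameters
  varying <- apply(pop, 2, function(v) sd(v) > 1e-12)
  rhat <- vapply(colnames(pop)[varying], function(nm) {
    .split_rhat(lapply(pop_list, function(m) m[, nm]))
  }, 0)
  ess <- tryCatch(
    as.numeric(coda::effectiveSize(coda::as.mcmc(pop[, varying,
                                                     drop = FALSE]))),
    error = function(e) rep(NA_real_, sum(varying)))
  diagnostics <- data.frame(parameter = colnames(pop)[varying],
                            rhat = unname(rhat), ess = ess,
                            row.names = NULL)
  if (any(is.finite(diagnostics$rhat) & diagnostics$rhat > 1.05))
    warning("split-Rhat > 1.05 on: ",
            paste(diagnostics$parameter[
              is.finite(diagnostics$rhat) & diagnostics$rhat > 1.05],
              collapse = ", "),
            "; consider longer chains", call. = FALSE)

  free <- .free_idx()
  nfree <- length(free)
  expand <- function(cols) {
    out <- matrix(0, nrow(pop), 25)
    out[, free] <- pop[, cols, drop = FALSE]
    out
  }
  ndraw <- nrow(pop)
  x0_arr <- array(NA_real_, c(ndraw, dat$nsub, 5))
  off <- 0
  for (ch in seq_len(chains)) {
    ni <- dim(x0_list[[ch]])[1]
    x0_arr[off + seq_len(ni), , ] <- x0_list[[ch]]
    off <- off + ni
  }
  i0 <- 3 * nfree
  draws <- list(
    V = expand(seq_len(nfree)),
    W_age = expand(nfree + seq_len(nfree)),
    W_apoe = expand(2 * nfree + seq_len(nfree)),
    v0 = pop[, i0 + 1:5, drop = FALSE],
    sigma = pop[, i0 + 6:10, drop = FALSE],
    mu0 = pop[, i0 + 11:15, drop = FALSE],
    tau0 = pop[, i0 + 16:20, drop = FALSE],
    c1 = pop[, i0 + 21], c2 = pop[, i0 + 22],
    beta_x = pop[, i0 + 23:27, drop = FALSE],
    beta_y = pop[, i0 + 28:29, drop = FALSE],
    link_slope = pop[, i0 + 30:34, drop = FALSE],
    link_mid = pop[, i0 + 35:39, drop = FALSE],
    x0 = x0_arr)

  structure(list(draws = draws, pop = pop, chain = chain_id,
                 diagnostics = diagnostics, accept = accept,
                 config = config, cohort = cohort, data = dat,
                 subject_ids = as.character(cohort$subjects$subject_id)),
            class = "adpm")
}

#' @export
print.adpm <- function(x, ...) {
  cat(sprintf(
    "adpm fit: %d subjects, %d draws (%d chain%s), max split-Rhat %.3f\n",
    x$data$nsub, nrow(x$pop), max(x$chain),
    if (max(x$chain) > 1) "s" else "",
    suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))))
  cat("velocity matrix V (posterior mean, 1/year):\n")
  print(round(coef(x)$V, 3))
  invisible(x)
}

#' Posterior means of the population parameters
#'
#' @param object An `adpm` fit.
#' @param ... Unused.
#' @return List with matrices `V`, `W_age`, `W_apoe` and vectors `v0`,
#'   `sigma`, `mu0`, `tau0`, plus the ordered-logit parameters.
#' @export
coef.adpm <- function(object, ...) {
  ch <- adpm_channels()
  msh <- function(m) matrix(colMeans(m), 5, 5, dimnames = list(ch, ch))
  vsh <- function(v) setNames(colMeans(v), ch)
  list(V = msh(object$draws$V), W_age = msh(object$draws$W_age),
       W_apoe = msh(object$draws$W_apoe), v0 = vsh(object$draws$v0),
       sigma = vsh(object$draws$sigma), mu0 = vsh(object$draws$mu0),
       tau0 = vsh(object$draws$tau0),
       clinical = ordered_logit_params(
         mean(object$draws$c1), mean(object$draws$c2),
         colMeans(object$draws$beta_x), colMeans(object$draws$beta_y)),
       x0 = apply(object$draws$x0, c(2, 3), mean))
}

#' @export
summary.adpm <- function(object, ...) {
  pop <- object$pop
  keep <- apply(pop, 2, function(v) sd(v) > 1e-12)
  tab <- data.frame(
    mean = colMeans(pop[, keep, drop = FALSE]),
    sd = apply(pop[, keep, drop = FALSE], 2, sd),
    q5 = apply(pop[, keep, drop = FALSE], 2, quantile, 0.05),
    q95 = apply(pop[, keep, drop = FALSE], 2, quantile, 0.95))
  tab$rhat <- object$diagnostics$rhat[match(rownames(tab),
                                            object$diagnostics$parameter)]
  tab$ess <- object$diagnostics$ess[match(rownames(tab),
                                          object$diagnostics$parameter)]
  class(tab) <- c("summary.adpm", class(tab))
  tab
}

#' @export
print.summary.adpm <- function(x, ...) {
  print.data.frame(round(as.data.frame(x), 3))
  invisible(x)
}

# velocity parameters of one posterior draw
.draw_velocity <- function(fit, d) {
  velocity_params(matrix(fit$draws$V[d, ], 5, 5),
                  matrix(fit$draws$W_age[d, ], 5, 5),
                  matrix(fit$draws$W_apoe[d, ], 5, 5),
                  fit$draws$v0[d, ])
}

.draw_clinical <- function(fit, d) {
  ordered_logit_params(fit$draws$c1[d], fit$draws$c2[d],
                       fit$draws$beta_x[d, ], fit$draws$beta_y[d, ])
}

#' Joint log-density of a cohort at a parameter point
#'
#' Reference (pure-R) evaluation of the model's joint log-likelihood plus
#' the hierarchical prior of the subject initial states: the sum over
#' subjects of the biomarker/trait likelihood terms at each observation
#' time (Gaussian through the sigmoid link; tail mass for right-censored
#' rows), the ordered-logit terms at each diagnosis time, and the
#' Gaussian x0 prior.  Population-parameter priors are not included.
#'
#' @param cohort An `adpm_cohort`.
#' @param params List with `velocity` ([velocity_params()]), `sigma`,
#'   `mu0`, `tau0`, `clinical` ([ordered_logit_params()]) and `x0` (matrix,
#'   subjects x 5, rows ordered as `cohort$subjects`).
#' @param config An [adpm_config()].
#' @return Scalar log-density.
#' @export
build_joint_loglik <- function(cohort, params, config = cohort$config) {
  stopifnot(inherits(cohort, "adpm_cohort"))
  sub <- cohort$subjects
  w <- config$likelihood_weight
  limits <- .censor_limits(config)
  ll <- 0
  for (s in seq_len(nrow(sub))) {
    sid <- sub$subject_id[s]
    y <- covariate_vector(.std_age(sub$age[s], config), sub$apoe4[s])
    sys <- assemble_system(params$velocity, y)
    o <- cohort$observations[cohort$observations$subject_id == sid, ,
                             drop = FALSE]
    d <- cohort$diagnoses[cohort$diagnoses$subject_id == sid, ,
                          drop = FALSE]
    x0s <- params$x0[s, ]
    for (i in seq_len(nrow(o))) {
      k <- o$channel[i]
      xt <- solve_trajectory(x0s, sys, o$time_years[i])[1, ]
      mean_i <- sigmoid_link(xt[[k]], config$links[[k]])
      se_i <- if (is.null(o$se)) 0 else o$se[i]
      sd_i <- sqrt(params$sigma[[k]]^2 + se_i^2)
      ll <- ll + w * if (o$censored[i] == 1) {
        censored_gaussian_loglik(mean_i, sd_i, limits[[k]])
      } else {
        gaussian_loglik(o$value[i], mean_i, sd_i)
      }
    }
    for (i in seq_len(nrow(d))) {
      xt <- solve_trajectory(x0s, sys, d$time_years[i])[1, ]
      p <- label_probs(xt, y, params$clinical)
      ll <- ll + w * log(p[[as.character(d$label[i])]])
    }
    ll <- ll + sum(dnorm(x0s, params$mu0, params$tau0, log = TRUE))
  }
  unname(ll)
}

#' Build a degenerate fit from fixed parameter values
#'
#' Wraps known parameter values — e.g. a generator's ground truth, or
#' estimates imported from elsewhere — as an `adpm` object whose draws all
#' equal those values, so the forecasting, conversion-time and
#' velocity-summary machinery can run without MCMC.  Subject initial states
#' are still estimated from data by [estimate_initial_state()]; only the
#' population parameters are fixed.
#'
#' @param cohort An `adpm_cohort`.
#' @param params List with `velocity` ([velocity_params()]), `sigma`,
#'   `mu0`, `tau0` and `clinical` ([ordered_logit_params()]); defaults to
#'   the cohort's attached ground truth if present.
#' @param ndraws Number of (identical) draws to expose.
#' @return An object of class `adpm` without `x0` draws or diagnostics.
#' @export
adpm_fixed_fit <- function(cohort,
                           params = attr(cohort, "ground_truth")$params,
                           ndraws = 100) {
  stopifnot(inherits(cohort, "adpm_cohort"))
  if (is.null(params))
    stop("no parameters supplied and no ground truth attached",
         call. = FALSE)
  dat <- .adpm_pack_data(cohort, cohort$config)
  repv <- function(v) matrix(rep(as.numeric(v), each = ndraws), ndraws)
  draws <- list(
    V = repv(params$velocity$V), W_age = repv(params$velocity$W_age),
    W_apoe = repv(params$velocity$W_apoe), v0 = repv(params$velocity$v0),
    sigma = repv(params$sigma[adpm_channels()]),
    mu0 = repv(params$mu0), tau0 = repv(params$tau0),
    c1 = rep(params$clinical$c1, ndraws),
    c2 = rep(params$clinical$c2, ndraws),
    beta_x = repv(params$clinical$beta_x),
    beta_y = repv(params$clinical$beta_y),
    link_slope = repv(dat$link_slope), link_mid = repv(dat$link_mid))
  structure(list(draws = draws, pop = matrix(0, ndraws, 1),
                 chain = rep(1L, ndraws), config = cohort$config,
                 cohort = cohort, data = dat,
                 subject_ids = as.character(cohort$subjects$subject_id)),
            class = "adpm")
}

#' Posterior-predictive replication of a cohort's observations
#'
#' For each retained draw, simulates replicate observations at the cohort's
#' own observation times from the fitted model (link-transformed trajectory
#' plus Gaussian noise, with the censoring rule applied).
#'
#' @param fit An `adpm` fit.
#' @param ndraws Number of posterior draws to use (thinned evenly).
#' @param seed Optional RNG seed.
#' @return Data frame: `draw`, `subject_id`, `time_years`, `channel`,
#'   `value`, `censored`.
#' @export
posterior_predictive <- function(fit, ndraws = 100, seed = NULL) {
  stopifnot(inherits(fit, "adpm"))
  if (!is.null(seed)) set.seed(seed)
  cohort <- fit$cohort
  config <- fit$config
  limits <- .censor_limits(config)
  idx <- unique(round(seq(1, nrow(fit$pop), length.out = ndraws)))
  out <- vector("list", length(idx))
  sub <- cohort$subjects
  for (j in seq_along(idx)) {
    d <- idx[j]
    vel <- .draw_velocity(fit, d)
    rows <- vector("list", nrow(sub))
    for (s in seq_len(nrow(sub))) {
      sid <- sub$subject_id[s]
      o <- cohort$observations[cohort$observations$subject_id == sid, ,
                               drop = FALSE]
      if (!nrow(o)) next
      y <- covariate_vector(.std_age(sub$age[s], config), sub$apoe4[s])
      sys <- assemble_system(vel, y)
      times <- sort(unique(o$time_years))
      traj <- solve_trajectory(fit$draws$x0[d, s, ], sys, times)
      k <- match(o$channel, adpm_channels())
      mu <- vapply(seq_len(nrow(o)), function(i)
        sigmoid_link(traj[match(o$time_years[i], times), k[i]],
                     config$links[[o$channel[i]]]), 0)
      se_o <- if (is.null(o$se)) 0 else o$se
      val <- rnorm(nrow(o), mu, sqrt(fit$draws$sigma[d, k]^2 + se_o^2))
      cens <- rep(0L, nrow(o))
      over <- !is.na(limits[o$channel]) & val > limits[o$channel]
      cens[over] <- 1L
      val[over] <- limits[o$channel][over]
      rows[[s]] <- data.frame(draw = d, subject_id = sid,
                              time_years = o$time_years,
                              channel = o$channel, value = val,
                              censored = cens)
    }
    out[[j]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' @export
simulate.adpm <- function(object, nsim = 1, seed = NULL, ...) {
  posterior_predictive(object, ndraws = nsim, seed = seed)
}

#' @export
residuals.adpm <- function(object, ...) {
  cohort <- object$cohort
  config <- object$config
  est <- coef(object)
  sub <- cohort$subjects
  res <- rep(NA_real_, nrow(cohort$observations))
  for (s in seq_len(nrow(sub))) {
    sid <- sub$subject_id[s]
    sel <- which(cohort$observations$subject_id == sid &
                   cohort$observations$censored == 0)
    if (!length(sel)) next
    o <- cohort$observations[sel, , drop = FALSE]
    y <- covariate_vector(.std_age(sub$age[s], config), sub$apoe4[s])
    sys <- assemble_system(velocity_params(est$V, est$W_age, est$W_apoe,
                                           est$v0), y)
    times <- sort(unique(o$time_years))
    traj <- solve_trajectory(est$x0[s, ], sys, times)
    for (i in seq_along(sel)) {
      k <- o$channel[i]
      mu <- sigmoid_link(traj[match(o$time_years[i], times),
                              match(k, adpm_channels())],
                         config$links[[k]])
      res[sel[i]] <- o$value[i] - mu
    }
  }
  res
}
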