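# Subject forecasting: conditional initial-state estimation from an early
# observation window, trajectory/label-probability forecasts, time to
# conversion, and velocity-field posterior summaries.

.thin_idx <- function(fit, ndraws) {
  unique(round(seq(1, nrow(fit$pop), length.out = min(ndraws,
                                                      nrow(fit$pop)))))
}

.draws_for_cpp <- function(fit, idx) {
  d <- fit$draws
  list(V = d$V[idx, , drop = FALSE], W_age = d$W_age[idx, , drop = FALSE],
       W_apoe = d$W_apoe[idx, , drop = FALSE],
       v0 = d$v0[idx, , drop = FALSE], sigma = d$sigma[idx, , drop = FALSE],
       mu0 = d$mu0[idx, , drop = FALSE], tau0 = d$tau0[idx, , drop = FALSE],
       link_slope = d$link_slope[idx, , drop = FALSE],
       link_mid = d$link_mid[idx, , drop = FALSE],
       c1 = d$c1[idx], c2 = d$c2[idx],
       beta_x = d$beta_x[idx, , drop = FALSE],
       beta_y = d$beta_y[idx, , drop = FALSE])
}

.subject_window <- function(cohort, subject_id, window, config) {
  sub <- cohort$subjects[cohort$subjects$subject_id == subject_id, ,
                         drop = FALSE]
  if (!nrow(sub)) stop("unknown subject: ", subject_id, call. = FALSE)
  o <- cohort$observations
  o <- o[o$subject_id == subject_id & o$time_years >= window[1] &
           o$time_years <= window[2], , drop = FALSE]
  d <- cohort$diagnoses
  d <- d[d$subject_id == subject_id & d$time_years >= window[1] &
           d$time_years <= window[2], , drop = FALSE]
  if (!nrow(o))
    stop(sprintf("subject %s has no observations in [%g, %g] years",
                 subject_id, window[1], window[2]), call. = FALSE)
  lab_code <- c(CN = 0L, MCI = 1L, AD = 2L)
  list(ob_time = o$time_years,
       ob_chan = match(o$channel, adpm_channels()) - 1L,
       ob_cens = as.integer(o$censored), ob_val = o$value,
       ob_se = if (is.null(o$se)) rep(0, nrow(o)) else o$se,
       dg_time = d$time_years,
       dg_lab = unname(lab_code[as.character(d$label)]),
       age = .std_age(sub$age, config), apoe = as.numeric(sub$apoe4))
}

#' Conditional initial-state samples for a new subject
#'
#' For each (thinned) posterior draw of the population parameters, draws the
#' subject's initial state conditioned on the observations and diagnoses in
#' an early follow-up window (default the first two years), holding the
#' population parameters fixed per draw.  Sampling is a short warm-started
#' Metropolis chain per draw on the 5-dimensional initial state.
#'
#' @param fit An `adpm` fit.
#' @param cohort Cohort containing the new subject (its covariates,
#'   observations, diagnoses).
#' @param subject_id Subject to condition on.
#' @param window Time window in years, default `c(0, 2)`.
#' @param ndraws Number of population-parameter draws used.
#' @param n_steps Metropolis steps per draw.
#' @return Matrix `ndraws` x 5 of initial-state samples.
#' @export
estimate_initial_state <- function(fit, cohort, subject_id,
                                   window = c(0, 2), ndraws = 200,
                                   n_steps = 40) {
  stopifnot(inherits(fit, "adpm"))
  subj <- .subject_window(cohort, subject_id, window, fit$config)
  idx <- .thin_idx(fit, ndraws)
  fixed <- list(link_lower = fit$data$link_lower,
                link_upper = fit$data$link_upper,
                cens_upper = fit$data$cens_upper)
  out <- cpp_sample_x0(subj, .draws_for_cpp(fit, idx), fixed,
                       as.integer(n_steps), fit$config$likelihood_weight)
  colnames(out) <- adpm_channels()
  out
}

#' Forecast a subject's trajectory and label probabilities
#'
#' Per posterior draw: initial state from [estimate_initial_state()], exact
#' trajectory over the grid under the draw's velocity field, ordered-logit
#' label probabilities along it; the reported curves are draw-averages.
#' The grid may extend backwards (negative years) and beyond the follow-up.
#'
#' @param fit An `adpm` fit.
#' @param cohort Cohort holding the subject.
#' @param subject_id Subject to forecast.
#' @param grid Time grid in years (default monthly from 0 to 10).
#' @param window Conditioning window passed to [estimate_initial_state()].
#' @param ndraws Posterior draws used.
#' @param n_steps Metropolis steps per draw for the initial state.
#' @return Object of class `adpm_forecast`: `grid`, `mean_prob` (grid x 3),
#'   `mean_latent` (grid x 5), per-draw arrays `prob` and `latent`, and
#'   `x0_draws`.
#' @export
forecast <- function(fit, cohort, subject_id,
                     grid = seq(0, 10, by = 1 / 12), window = c(0, 2),
                     ndraws = 200, n_steps = 40) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing", call. = FALSE)
  x0d <- estimate_initial_state(fit, cohort, subject_id, window, ndraws,
                                n_steps)
  idx <- .thin_idx(fit, ndraws)
  sub <- cohort$subjects[cohort$subjects$subject_id == subject_id, ]
  fc <- cpp_forecast(x0d, .draws_for_cpp(fit, idx),
                     .std_age(sub$age, fit$config), as.numeric(sub$apoe4),
                     grid)
  mean_prob <- apply(fc$prob, c(2, 3), mean)
  colnames(mean_prob) <- .labels
  mean_latent <- apply(fc$latent, c(2, 3), mean)
  colnames(mean_latent) <- adpm_channels()
  structure(list(subject_id = subject_id, grid = grid,
                 mean_prob = mean_prob, mean_latent = mean_latent,
                 prob = fc$prob, latent = fc$latent, x0_draws = x0d),
            class = "adpm_forecast")
}

#' @export
print.adpm_forecast <- function(x, ...) {
  cat(sprintf("forecast for %s over [%g, %g] years (%d draws)\n",
              x$subject_id, min(x$grid), max(x$grid), dim(x$prob)[1]))
  invisible(x)
}

#' @export
as.data.frame.adpm_forecast <- function(x, ...) {
  data.frame(subject_id = x$subject_id, time_years = x$grid,
             p_cn = x$mean_prob[, "CN"], p_mci = x$mean_prob[, "MCI"],
             p_ad = x$mean_prob[, "AD"])
}

#' @export
plot.adpm_forecast <- function(x, ...) {
  graphics::matplot(x$grid, x$mean_prob, type = "l", lty = 1, lwd = 2,
                    col = c("forestgreen", "orange", "firebrick"),
                    xlab = "years from first observation",
                    ylab = "label probability", ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = .labels, lwd = 2, bty = "n",
                   col = c("forestgreen", "orange", "firebrick"))
  invisible(x)
}

#' Forecasts for every subject of a cohort
#'
#' @param object An `adpm` fit.
#' @param newdata Cohort of subjects to forecast (default: training cohort).
#' @param subjects Subject ids (default: all with observations in the
#'   window).
#' @param ... Passed to [forecast()].
#' @return Named list of `adpm_forecast` objects.
#' @export
predict.adpm <- function(object, newdata = object$cohort, subjects = NULL,
                         ...) {
  if (is.null(subjects))
    subjects <- as.character(newdata$subjects$subject_id)
  out <- lapply(subjects, function(sid)
    tryCatch(forecast(object, newdata, sid, ...),
             error = function(e) e))
  names(out) <- subjects
  out
}

#' Threshold-crossing times of the forecast dementia probability
#'
#' First crossing (linear interpolation between grid points) of the
#' draw-averaged P(AD) curve for each threshold; crossings beyond the
#' horizon are flagged.  The per-draw distribution of the 50% crossing is
#' also reported.
#'
#' @param fc An `adpm_forecast`.
#' @param thresholds Probability thresholds, default 30/50/70%.
#' @param horizon Prediction horizon in years (default 10).
#' @return Object of class `conversion_prediction`: named crossing times
#'   (`NA` + `beyond` flag when never crossed), the horizon, and per-draw
#'   `t50_draws`.
#' @export
time_to_conversion <- function(fc, thresholds = c(0.3, 0.5, 0.7),
                               horizon = 10) {
  stopifnot(inherits(fc, "adpm_forecast"))
  keep <- fc$grid >= 0 & fc$grid <= horizon
  if (!any(keep))
    stop("forecast grid does not cover [0, horizon]", call. = FALSE)
  t <- fc$grid[keep]
  p <- fc$mean_prob[keep, "AD"]
  times <- vapply(thresholds, function(th) .first_crossing(t, p, th), 0)
  names(times) <- paste0("t", round(100 * thresholds))
  t50d <- apply(fc$prob[, keep, 3, drop = FALSE], 1, function(pd)
    .first_crossing(t, as.numeric(pd), 0.5))
  structure(list(times = times, beyond = is.na(times), horizon = horizon,
                 thresholds = thresholds, t50_draws = t50d,
                 subject_id = fc$subject_id),
            class = "conversion_prediction")
}

#' @export
print.conversion_prediction <- function(x, ...) {
  shown <- ifelse(is.na(x$times), sprintf("> %g", x$horizon),
                  sprintf("%.2f", x$times))
  cat(sprintf("time to conversion for %s (years): %s\n", x$subject_id,
              paste(names(x$times), shown, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Velocity-field map of a fitted model
#'
#' Plots each subject's posterior-mean initial state in a two-channel plane
#' with an arrow showing the expected displacement over `years` years of
#' evolution under the posterior-mean velocity field (APOE4 carriers in
#' red).
#'
#' @param x An `adpm` fit.
#' @param channels Two channel names spanning the plane (default
#'   amyloid-beta vs tau).
#' @param years Arrow length in years of evolution.
#' @param ... Passed to `plot()`.
#' @export
plot.adpm <- function(x, channels = c("abeta", "tau"), years = 2, ...) {
  stopifnot(length(channels) == 2, all(channels %in% adpm_channels()))
  est <- coef(x)
  i <- match(channels[1], adpm_channels())
  j <- match(channels[2], adpm_channels())
  x0 <- est$x0
  vel <- t(vapply(seq_len(nrow(x0)), function(s) {
    A <- est$V + x$data$age[s] * est$W_age + x$data$apoe[s] * est$W_apoe
    drop(A %*% x0[s, ]) + est$v0
  }, numeric(5)))
  cols <- ifelse(x$data$apoe == 1, "firebrick", "grey30")
  graphics::plot(x0[, i], x0[, j], pch = 16, cex = 0.6, col = cols,
                 xlab = paste(channels[1], "(latent)"),
                 ylab = paste(channels[2], "(latent)"), ...)
  graphics::arrows(x0[, i], x0[, j], x0[, i] + years * vel[, i],
                   x0[, j] + years * vel[, j], length = 0.05, col = cols)
  invisible(x)
}

#' Posterior velocity distribution in a region of biomarker space
#'
#' Pools the velocity field evaluated at the posterior initial-state draws
#' of the fitted subjects whose states fall inside a region, optionally
#' within covariate strata, and summarises each velocity component by its
#' posterior mean and 90% highest-density interval.
#'
#' @param fit An `adpm` fit.
#' @param region Named list of `c(min, max)` latent ranges per channel
#'   (unspecified channels are unrestricted).
#' @param apoe4 Optional 0/1 to restrict the stratum.
#' @param ndraws Posterior draws used.
#' @param prob HDI mass (default 0.9).
#' @return Data frame: `component`, `mean`, `hdi_lower`, `hdi_upper`, `n`
#'   (pooled subject-draw pairs); zero rows if the region is empty.
#' @export
velocity_summary <- function(fit, region = list(), apoe4 = NULL,
                             ndraws = 200, prob = 0.9) {
  stopifnot(inherits(fit, "adpm"))
  idx <- .thin_idx(fit, ndraws)
  subs <- seq_len(fit$data$nsub)
  if (!is.null(apoe4)) subs <- subs[fit$data$apoe == apoe4]
  vels <- vector("list", length(idx))
  n_pool <- 0
  for (j in seq_along(idx)) {
    d <- idx[j]
    A_base <- matrix(fit$draws$V[d, ], 5, 5)
    Wa <- matrix(fit$draws$W_age[d, ], 5, 5)
    Wp <- matrix(fit$draws$W_apoe[d, ], 5, 5)
    v0 <- fit$draws$v0[d, ]
    rows <- list()
    for (s in subs) {
      x <- fit$draws$x0[d, s, ]
      inside <- TRUE
      for (ch in names(region)) {
        k <- match(ch, adpm_channels())
        if (x[k] < region[[ch]][1] || x[k] > region[[ch]][2]) {
          inside <- FALSE
          break
        }
      }
      if (!inside) next
      A <- A_base + fit$data$age[s] * Wa + fit$data$apoe[s] * Wp
      rows[[length(rows) + 1]] <- drop(A %*% x) + v0
    }
    if (length(rows)) {
      vels[[j]] <- do.call(rbind, rows)
      n_pool <- n_pool + length(rows)
    }
  }
  vels <- do.call(rbind, vels)
  if (is.null(vels) || nrow(vels) == 0) {
    message("velocity_summary: empty region")
    return(data.frame(component = character(), mean = numeric(),
                      hdi_lower = numeric(), hdi_upper = numeric(),
                      n = integer()))
  }
  hdi <- apply(vels, 2, function(v)
    coda::HPDinterval(coda::as.mcmc(v), prob = prob))
  data.frame(component = adpm_channels(), mean = colMeans(vels),
             hdi_lower = hdi[1, ], hdi_upper = hdi[2, ], n = nrow(vels),
             row.names = NULL)
}
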