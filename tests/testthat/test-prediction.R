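# Forecasting, time-to-conversion and velocity summaries.  A shared small
# fit on a well-specified synthetic cohort backs the integration checks.

fit_pred <- local({
  co <- simulate_cohort(generator_config(n_subjects = 40, n_sites = 3,
                                         seed = 31))
  suppressWarnings(adpm(co, adpm_config(), chains = 1, warmup = 180,
                        iter = 180, seed = 5))
})

fake_forecast <- function(grid, p_ad) {
  pr <- cbind(1 - p_ad, 0, p_ad)
  cube <- array(NA_real_, c(1, length(grid), 3))
  cube[1, , ] <- pr
  structure(list(subject_id = "fake", grid = grid,
                 mean_prob = `colnames<-`(pr, c("CN", "MCI", "AD")),
                 mean_latent = matrix(0, length(grid), 5),
                 prob = cube, latent = array(0, c(1, length(grid), 5)),
                 x0_draws = matrix(0, 1, 5)),
            class = "adpm_forecast")
}

test_that("threshold crossings interpolate linearly and flag the horizon", {
  grid <- seq(0, 10, by = 0.5)
  fc <- fake_forecast(grid, 0.05 * grid)
  ttc <- time_to_conversion(fc)
  expect_equal(unname(ttc$times["t30"]), 6, tolerance = 1e-9)
  expect_equal(unname(ttc$times["t50"]), 10, tolerance = 1e-9)
  expect_true(is.na(ttc$times["t70"]))
  expect_true(ttc$beyond["t70"])

  # immediate crossing
  fc2 <- fake_forecast(grid, rep(0.9, length(grid)))
  expect_equal(unname(time_to_conversion(fc2)$times), rep(0, 3))

  # flat low curve: everything beyond horizon
  fc3 <- fake_forecast(grid, rep(0.1, length(grid)))
  expect_true(all(time_to_conversion(fc3)$beyond))

  # monotone curve => ordered thresholds
  fc4 <- fake_forecast(grid, plogis((grid - 4)))
  t4 <- time_to_conversion(fc4)$times
  expect_true(t4["t30"] <= t4["t50"] && t4["t50"] <= t4["t70"])
})

test_that("a missing conditioning window raises an error naming the subject", {
  co <- fit_pred$cohort
  late <- co
  sid <- as.character(co$subjects$subject_id[1])
  keep <- !(late$observations$subject_id == sid &
              late$observations$time_years <= 2)
  late$observations <- late$observations[keep, ]
  late$observations$time_years[late$observations$subject_id == sid] <-
    late$observations$time_years[late$observations$subject_id == sid] + 3
  expect_error(estimate_initial_state(fit_pred, late, sid), sid)
})

test_that("forecasts cover backward and forward grids and normalise", {
  sid <- as.character(fit_pred$cohort$subjects$subject_id[1])
  fc <- forecast(fit_pred, fit_pred$cohort, sid,
                 grid = seq(-10, 20, by = 0.5), ndraws = 50)
  expect_equal(range(fc$grid), c(-10, 20))
  expect_equal(rowSums(fc$mean_prob), rep(1, length(fc$grid)),
               tolerance = 1e-9)
  expect_true(all(is.finite(fc$mean_latent)))
  df <- as.data.frame(fc)
  expect_equal(names(df), c("subject_id", "time_years", "p_cn", "p_mci",
                            "p_ad"))
})

test_that("halving the grid step moves t50 by less than the step", {
  sid <- as.character(fit_pred$cohort$subjects$subject_id[2])
  set.seed(42)
  fc1 <- forecast(fit_pred, fit_pred$cohort, sid,
                  grid = seq(0, 10, by = 1 / 6), ndraws = 80)
  set.seed(42)
  fc2 <- forecast(fit_pred, fit_pred$cohort, sid,
                  grid = seq(0, 10, by = 1 / 12), ndraws = 80)
  t1 <- time_to_conversion(fc1)$times["t50"]
  t2 <- time_to_conversion(fc2)$times["t50"]
  if (!is.na(t1) && !is.na(t2)) expect_lt(abs(t1 - t2), 1 / 6)
  # probability curves agree up to Monte-Carlo and interpolation error
  common <- intersect(round(fc1$grid, 6), round(fc2$grid, 6))
  i1 <- match(common, round(fc1$grid, 6))
  i2 <- match(common, round(fc2$grid, 6))
  expect_lt(max(abs(fc1$mean_prob[i1, "AD"] - fc2$mean_prob[i2, "AD"])),
            0.05)
})

test_that("more windowed observations do not inflate initial-state spread", {
  # same subject scored with 1 visit vs full 2-year window
  co <- fit_pred$cohort
  counts <- table(co$observations$subject_id[co$observations$time_years <= 2])
  sid <- names(which.max(counts))
  x_full <- estimate_initial_state(fit_pred, co, sid, ndraws = 120)
  co1 <- co
  first_t <- min(co$observations$time_years[co$observations$subject_id == sid])
  co1$observations <- co1$observations[
    co1$observations$subject_id != sid |
      co1$observations$time_years == first_t, ]
  x_one <- estimate_initial_state(fit_pred, co1, sid, ndraws = 120)
  # average posterior sd across components should not grow with more data
  expect_lte(mean(apply(x_full, 2, sd)), mean(apply(x_one, 2, sd)) * 1.25)
})

test_that("initial-state estimation recovers simulated subjects", {
  gt <- attr(fit_pred$cohort, "ground_truth")
  hits <- 0; tries <- 0
  for (sid in as.character(fit_pred$cohort$subjects$subject_id[1:8])) {
    x <- estimate_initial_state(fit_pred, fit_pred$cohort, sid,
                                ndraws = 100)
    mu <- colMeans(x); sdv <- apply(x, 2, sd)
    truth <- gt$x0[sid, ]
    hits <- hits + sum(abs(mu - truth) <= 2.5 * sdv)
    tries <- tries + 5
  }
  expect_gt(hits / tries, 0.75)
})

test_that("velocity summaries match brute-force enumeration", {
  region <- list(tau = c(-0.5, 1.5))
  vs <- velocity_summary(fit_pred, region, ndraws = 40)
  expect_equal(vs$component, adpm_channels())
  expect_true(all(vs$hdi_lower <= vs$mean & vs$mean <= vs$hdi_upper))

  # enumeration oracle over the same thinned draws
  idx <- adpm:::.thin_idx(fit_pred, 40)
  vals <- NULL
  for (d in idx) {
    for (s in seq_len(fit_pred$data$nsub)) {
      x <- fit_pred$draws$x0[d, s, ]
      if (x[1] < region$tau[1] || x[1] > region$tau[2]) next
      A <- matrix(fit_pred$draws$V[d, ], 5, 5) +
        fit_pred$data$age[s] * matrix(fit_pred$draws$W_age[d, ], 5, 5) +
        fit_pred$data$apoe[s] * matrix(fit_pred$draws$W_apoe[d, ], 5, 5)
      vals <- rbind(vals, drop(A %*% x) + fit_pred$draws$v0[d, ])
    }
  }
  expect_equal(vs$mean, unname(colMeans(vals)), tolerance = 1e-10)
  expect_equal(vs$n[1], nrow(vals))

  # empty region reports itself explicitly
  expect_message(
    out <- velocity_summary(fit_pred, list(tau = c(50, 60)), ndraws = 10),
    "empty")
  expect_equal(nrow(out), 0)
})

test_that("plot methods draw without error", {
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit_pred))
  sid <- as.character(fit_pred$cohort$subjects$subject_id[1])
  fc <- forecast(fit_pred, fit_pred$cohort, sid, grid = seq(0, 5, 0.25),
                 ndraws = 20)
  expect_invisible(plot(fc))
})

test_that("apoe stratification restricts the pooled subjects", {
  vs1 <- velocity_summary(fit_pred, apoe4 = 1, ndraws = 20)
  vs0 <- velocity_summary(fit_pred, apoe4 = 0, ndraws = 20)
  n_apoe <- sum(fit_pred$data$apoe == 1)
  idx <- adpm:::.thin_idx(fit_pred, 20)
  expect_equal(vs1$n[1], length(idx) * n_apoe)
  expect_equal(vs0$n[1], length(idx) * (fit_pred$data$nsub - n_apoe))
})
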