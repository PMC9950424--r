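# Joint likelihood and the fitting machinery.  One small shared fit keeps
# the file fast; substantive recovery checks live in test-acceptance.R.

make_params <- function(seed = 1) {
  set.seed(seed)
  mk <- function() {
    M <- matrix(rnorm(25, 0, 0.2), 5, 5)
    M[1:2, 3:5] <- 0
    M
  }
  list(velocity = velocity_params(mk(), mk(), mk(), rnorm(5, 0, 0.1)),
       sigma = c(tau = 20, abeta = 80, lang = 0.3, mem = 0.3, praxis = 0.3),
       mu0 = rnorm(5, 0, 0.3), tau0 = runif(5, 0.5, 1),
       clinical = ordered_logit_params(-0.5, 1.5, rnorm(5, 0, 0.5),
                                       rnorm(2, 0, 0.3)))
}

test_that("R and C++ joint log-likelihoods agree on a synthetic cohort", {
  co <- tiny_cohort()
  pars <- make_params()
  pars$x0 <- matrix(rnorm(nrow(co$subjects) * 5, 0, 0.5),
                    nrow(co$subjects), 5)
  cfg <- co$config
  ll_r <- build_joint_loglik(co, pars, cfg)
  dat <- adpm:::.adpm_pack_data(co, cfg)
  cpp_pars <- list(V = pars$velocity$V, W_age = pars$velocity$W_age,
                   W_apoe = pars$velocity$W_apoe, v0 = pars$velocity$v0,
                   sigma = unname(pars$sigma), mu0 = pars$mu0,
                   tau0 = pars$tau0, beta_x = unname(pars$clinical$beta_x),
                   beta_y = unname(pars$clinical$beta_y),
                   link_slope = dat$link_slope, link_mid = dat$link_mid,
                   c1 = pars$clinical$c1, c2 = pars$clinical$c2,
                   x0 = pars$x0)
  ll_cpp <- adpm:::cpp_cohort_loglik(dat, cpp_pars)
  expect_equal(ll_r, ll_cpp, tolerance = 1e-8)
})

test_that("joint log-density matches a hand-computed two-term sum", {
  cfg <- adpm_config()
  sub <- data.frame(subject_id = "s1", site_id = "a", age = 75, apoe4 = 0)
  obs <- data.frame(subject_id = "s1", time_years = 0, channel = "mem",
                    value = 0.4, censored = 0L)
  dg <- obs[0, c("subject_id", "time_years")]
  dg$label <- character(0)
  co <- adpm_cohort(sub, obs, dg, cfg)
  # second subject so the cohort is non-degenerate for other helpers
  pars <- make_params(2)
  pars$x0 <- matrix(c(0.1, -0.2, 0.3, 0.5, -0.1), 1)
  # with A = 0, b = 0 the state never moves: prior + one Gaussian term
  pars$velocity <- velocity_params(matrix(0, 5, 5))
  mean_mem <- sigmoid_link(0.5, cfg$links$mem)
  expected <- sum(dnorm(pars$x0, pars$mu0, pars$tau0, log = TRUE)) +
    dnorm(0.4, mean_mem, pars$sigma[["mem"]], log = TRUE)
  expect_equal(build_joint_loglik(co, pars, cfg), expected,
               tolerance = 1e-10)
})

test_that("duplicated observation rows double their likelihood share", {
  cfg <- adpm_config()
  sub <- data.frame(subject_id = "s1", site_id = "a", age = 70, apoe4 = 1)
  obs1 <- data.frame(subject_id = "s1", time_years = 1.5, channel = "tau",
                     value = 300, censored = 0L)
  dg0 <- data.frame(subject_id = character(), time_years = numeric(),
                    label = character())
  pars <- make_params(3)
  pars$x0 <- matrix(rnorm(5, 0, 0.3), 1)
  co1 <- adpm_cohort(sub, obs1, dg0, cfg)
  co2 <- adpm_cohort(sub, rbind(obs1, obs1), dg0, cfg)
  prior <- sum(dnorm(pars$x0, pars$mu0, pars$tau0, log = TRUE))
  l1 <- build_joint_loglik(co1, pars, cfg) - prior
  l2 <- build_joint_loglik(co2, pars, cfg) - prior
  expect_equal(l2, 2 * l1, tolerance = 1e-10)
})

test_that("log-density is invariant to subject and row ordering", {
  co <- tiny_cohort()
  pars <- make_params(4)
  n <- nrow(co$subjects)
  pars$x0 <- matrix(rnorm(n * 5, 0, 0.4), n)
  rownames(pars$x0) <- co$subjects$subject_id
  ll <- build_joint_loglik(co, pars, co$config)

  perm <- sample(n)
  co2 <- co
  co2$subjects <- co$subjects[perm, ]
  co2$observations <- co$observations[sample(nrow(co$observations)), ]
  co2$diagnoses <- co$diagnoses[sample(nrow(co$diagnoses)), ]
  pars2 <- pars
  pars2$x0 <- pars$x0[as.character(co2$subjects$subject_id), , drop = FALSE]
  expect_equal(build_joint_loglik(co2, pars2, co$config), ll,
               tolerance = 1e-9)
})

# one shared small fit reused by the structural checks below
fit_tiny <- local({
  co <- tiny_cohort()
  suppressWarnings(adpm(co, adpm_config(), chains = 2, warmup = 150,
                        iter = 150, seed = 7))
})

test_that("every posterior draw respects the sparsity mask and c1 < c2", {
  masked_cols <- which(velocity_sparsity_mask())
  expect_true(all(fit_tiny$draws$V[, masked_cols] == 0))
  expect_true(all(fit_tiny$draws$W_age[, masked_cols] == 0))
  expect_true(all(fit_tiny$draws$W_apoe[, masked_cols] == 0))
  expect_true(all(fit_tiny$draws$c1 < fit_tiny$draws$c2))
  expect_true(all(fit_tiny$draws$sigma > 0))
  expect_true(all(fit_tiny$draws$tau0 > 0))
})

test_that("fit object methods work and diagnostics are attached", {
  expect_s3_class(fit_tiny, "adpm")
  est <- coef(fit_tiny)
  expect_equal(dim(est$V), c(5, 5))
  expect_true(all(est$sigma > 0))
  expect_true(all(c("rhat", "ess") %in% names(fit_tiny$diagnostics)))
  s <- summary(fit_tiny)
  expect_true(all(c("mean", "sd", "q5", "q95") %in% colnames(s)))
  expect_output(print(fit_tiny), "adpm fit")
  r <- residuals(fit_tiny)
  expect_length(r, nrow(fit_tiny$cohort$observations))
})

test_that("subject initial states track the inverse-link of baseline data", {
  co <- fit_tiny$cohort
  est <- coef(fit_tiny)
  diffs <- c()
  for (s in seq_len(nrow(co$subjects))) {
    sid <- co$subjects$subject_id[s]
    o <- co$observations
    o <- o[o$subject_id == sid & o$time_years == 0 & o$censored == 0, ]
    for (i in seq_len(nrow(o))) {
      k <- match(o$channel[i], adpm_channels())
      z <- inv_sigmoid_link(o$value[i], co$config$links[[o$channel[i]]])
      diffs <- c(diffs, est$x0[s, k] - z)
    }
  }
  # anchored within a noise sd or so on the latent scale
  expect_lt(median(abs(diffs)), 0.5)
})

test_that("prior-predictive mode returns the prior marginals", {
  co <- tiny_cohort()
  fit0 <- suppressWarnings(adpm(co, adpm_config(likelihood_weight = 0),
                                chains = 1, warmup = 200, iter = 300,
                                seed = 9))
  vfree <- fit0$draws$V[, adpm:::.free_idx()]
  # free velocity entries ~ Normal(0, 0.5)
  expect_lt(abs(mean(vfree)), 0.1)
  expect_lt(abs(sd(vfree) - 0.5), 0.12)
})

test_that("posterior predictive replicates resemble the observations", {
  rep_obs <- posterior_predictive(fit_tiny, ndraws = 60, seed = 1)
  co <- fit_tiny$cohort
  expect_setequal(unique(rep_obs$channel), unique(co$observations$channel))
  # central 95% replicate interval should cover most observed values
  key <- paste(co$observations$subject_id, co$observations$time_years,
               co$observations$channel)
  rep_key <- paste(rep_obs$subject_id, rep_obs$time_years, rep_obs$channel)
  cover <- vapply(seq_len(nrow(co$observations)), function(i) {
    v <- rep_obs$value[rep_key == key[i]]
    q <- quantile(v, c(0.025, 0.975))
    co$observations$value[i] >= q[1] && co$observations$value[i] <= q[2]
  }, TRUE)
  expect_gt(mean(cover), 0.8)
  sim <- simulate(fit_tiny, nsim = 2, seed = 2)
  expect_true(all(c("draw", "value") %in% names(sim)))
})
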