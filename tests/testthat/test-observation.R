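test_that("sigmoid link hits its midpoint, plateau and a logistic value", {
  lk <- link_params(0, 100, slope = 1, midpoint = 0)
  expect_equal(sigmoid_link(0, lk), 50)
  expect_equal(sigmoid_link(1e3, lk), 100, tolerance = 1e-12)
  expect_equal(sigmoid_link(log(3), lk), 75, tolerance = 1e-12)

  lk2 <- link_params(-4, 4, slope = 0.6, midpoint = 0.5)
  expect_equal(sigmoid_link(0.5, lk2), 0)
  x <- seq(-5, 5, by = 0.25)
  y <- sigmoid_link(x, lk2)
  expect_true(all(diff(y) > 0))           # strictly increasing
  expect_true(all(y > -4 & y < 4))        # bounded
  expect_equal(inv_sigmoid_link(y, lk2), x, tolerance = 1e-9)
})

test_that("link parameters are validated", {
  expect_error(link_params(1, 0), "upper")
  expect_error(link_params(0, 1, slope = -1), "slope")
})

test_that("Gaussian log-likelihood matches its closed form", {
  expect_equal(gaussian_loglik(0, 0, 1), -0.5 * log(2 * pi))
  s <- 2.3
  expect_equal(gaussian_loglik(1 + s, 1, s),
               -0.5 * log(2 * pi) - log(s) - 0.5)
  d <- 0.7
  expect_equal(gaussian_loglik(5 + d, 5, 1.1), gaussian_loglik(5 - d, 5, 1.1))
  expect_error(gaussian_loglik(0, 0, 0), "positive")
})

test_that("censored likelihood equals the Gaussian tail mass", {
  expect_equal(censored_gaussian_loglik(1700, 90, 1700), log(0.5))
  s <- 55
  expect_equal(censored_gaussian_loglik(1700 + 3 * s, s, 1700),
               pnorm(3, log.p = TRUE))
  # numeric cross-check of the tail mass by quadrature
  m <- 1650; sg <- 80
  tail_quad <- integrate(function(x) dnorm(x, m, sg), 1700, Inf)$value
  expect_equal(censored_gaussian_loglik(m, sg, 1700), log(tail_quad),
               tolerance = 1e-6)
})

test_that("censored plus uncensored mass integrates to one", {
  m <- 1600; sg <- 120; lim <- 1700
  below <- integrate(function(x) dnorm(x, m, sg), -Inf, lim)$value
  total <- below + exp(censored_gaussian_loglik(m, sg, lim))
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("graded-response category probabilities behave correctly", {
  it <- irt_item(1, c(0, 1), "mem")
  p <- irt_category_probs(0, it)
  expect_equal(unname(p), c(0.5, 0.5 - plogis(-1), plogis(-1)),
               tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # flat item: extremes get half the mass each, middle categories none
  flat <- irt_item(0, c(-1, 0, 1), "lang")
  pf <- irt_category_probs(1.7, flat)
  expect_equal(unname(pf), c(0.5, 0, 0, 0.5))

  # binary item reduces to a 2PL correct-response curve
  bin <- irt_item(1.3, 0.4, "praxis")
  for (th in c(-2, 0, 2)) {
    pb <- irt_category_probs(th, bin)
    expect_equal(unname(pb[2]), plogis(1.3 * (th - 0.4)), tolerance = 1e-12)
    expect_equal(sum(pb), 1, tolerance = 1e-12)
  }

  expect_error(irt_item(1, c(1, 0), "mem"), "ascending")
})

test_that("probability vectors always sum to one over random items", {
  set.seed(9)
  for (rep in 1:50) {
    nth <- sample(1:6, 1)
    it <- irt_item(runif(1, 0.3, 2.5), sort(rnorm(nth)),
                   sample(c("lang", "mem", "praxis"), 1))
    p <- irt_category_probs(rnorm(1, 0, 2), it)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("trait scoring matches a grid-search posterior-mode oracle", {
  set.seed(10)
  bank <- item_bank(list(
    m1 = irt_item(1.2, c(-1, 0, 1), "mem"),
    m2 = irt_item(0.9, c(-0.5, 0.8), "mem"),
    l1 = irt_item(1.1, 0, "lang")))
  resp <- data.frame(item_id = c("m1", "m2"), category = c(2L, 1L))
  sc <- score_traits(resp, bank)
  # 1-D grid oracle on the memory posterior
  grid <- seq(-6, 6, by = 1e-3)
  post <- dnorm(grid, log = TRUE)
  for (r in 1:2) {
    it <- bank$items[[as.character(resp$item_id[r])]]
    post <- post + log(vapply(grid, function(g)
      irt_category_probs(g, it)[resp$category[r] + 1L], 0))
  }
  expect_equal(sc$estimate[sc$domain == "mem"], grid[which.max(post)],
               tolerance = 2e-3)
  expect_true(is.na(sc$estimate[sc$domain == "praxis"]))
  expect_gt(sc$se[sc$domain == "mem"], 0)
})

test_that("uniformly worse responses never decrease the trait estimate", {
  bank <- item_bank(list(
    a = irt_item(1.0, c(-1, 0, 1), "mem"),
    b = irt_item(1.4, c(-0.5, 0.5), "mem")))
  ests <- vapply(0:2, function(shift) {
    resp <- data.frame(item_id = c("a", "b"),
                       category = pmin(c(0L, 0L) + shift, c(3L, 2L)))
    score_traits(resp, bank)$estimate[2]
  }, 0)
  expect_true(all(diff(ests) >= 0))
})

test_that("item responses round-trip through CSV and score into trait rows
           whose standard errors inflate the likelihood", {
  set.seed(15)
  bank <- item_bank(list(
    m1 = irt_item(1.2, c(-1, 0, 1), "mem"),
    m2 = irt_item(1.0, c(-0.5, 0.5), "mem"),
    l1 = irt_item(1.1, c(0, 1), "lang"),
    p1 = irt_item(0.9, 0.2, "praxis")))
  # two subjects, one visit each, responses drawn at their true traits
  resp <- do.call(rbind, lapply(c(s1 = -0.5, s2 = 1), function(tr) {
    cats <- vapply(names(bank$items), function(id) {
      p <- irt_category_probs(tr, bank$items[[id]])
      sample(seq_along(p), 1, prob = p) - 1L
    }, 0L)
    data.frame(item_id = names(bank$items), category = cats)
  }))
  resp$subject_id <- rep(c("s1", "s2"), each = 4)
  resp$time_years <- 0
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(resp, f, row.names = FALSE)
  back <- read_item_responses(f)
  rows <- score_item_responses(back, bank)
  expect_setequal(unique(rows$channel), c("lang", "mem", "praxis"))
  expect_true(all(rows$se > 0))

  # the se column widens the Gaussian term in the joint likelihood
  cfg <- adpm_config()
  sub <- data.frame(subject_id = c("s1", "s2"), site_id = "a", age = 72,
                    apoe4 = 0)
  dg0 <- data.frame(subject_id = character(), time_years = numeric(),
                    label = character())
  co <- adpm_cohort(sub, rows, dg0, cfg)
  pars <- make_params2 <- list(
    velocity = velocity_params(matrix(0, 5, 5)),
    sigma = c(tau = 20, abeta = 80, lang = 0.3, mem = 0.3, praxis = 0.3),
    mu0 = rep(0, 5), tau0 = rep(1, 5),
    clinical = ordered_logit_params(-1, 1, rep(0, 5), c(0, 0)),
    x0 = matrix(0, 2, 5))
  ll <- build_joint_loglik(co, pars, cfg)
  manual <- sum(dnorm(as.numeric(pars$x0), 0, 1, log = TRUE))
  for (i in seq_len(nrow(co$observations))) {
    o <- co$observations[i, ]
    mu <- sigmoid_link(0, cfg$links[[o$channel]])
    manual <- manual + dnorm(o$value, mu,
                             sqrt(pars$sigma[[o$channel]]^2 + o$se^2),
                             log = TRUE)
  }
  expect_equal(ll, manual, tolerance = 1e-10)
  # and the C++ path agrees
  dat <- adpm:::.adpm_pack_data(co, cfg)
  cpp_pars <- list(V = pars$velocity$V, W_age = pars$velocity$W_age,
                   W_apoe = pars$velocity$W_apoe, v0 = pars$velocity$v0,
                   sigma = unname(pars$sigma), mu0 = pars$mu0,
                   tau0 = pars$tau0, beta_x = rep(0, 5), beta_y = c(0, 0),
                   link_slope = dat$link_slope, link_mid = dat$link_mid,
                   c1 = -1, c2 = 1, x0 = pars$x0)
  expect_equal(adpm:::cpp_cohort_loglik(dat, cpp_pars), ll,
               tolerance = 1e-8)
})

test_that("empty responses flag every domain as missing", {
  bank <- item_bank(list(a = irt_item(1, 0, "mem")))
  sc <- score_traits(data.frame(item_id = character(),
                                category = integer()), bank)
  expect_true(all(is.na(sc$estimate)))
})
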