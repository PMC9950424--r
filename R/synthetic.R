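# Synthetic ADNI-like cohort generation from known parameters, so every
# downstream module is testable without access-controlled data.

#' Illustrative "true" population parameters
#'
#' Default ground-truth parameters of the generator.  They are illustrative,
#' not estimates: signs and magnitudes qualitatively mimic the reported AD
#' cascade (high tau accelerates tau and cognitive decline, low CSF
#' amyloid-beta accelerates both; biomarker velocities unaffected by
#' cognition), with latent scales standardized so a disease course spans
#' order-one units per decade.
#'
#' Latent conventions: higher tau / higher cognitive traits = worse; higher
#' latent abeta = more CSF amyloid-beta (healthier).
#'
#' @return List with `velocity` ([velocity_params()]), `mu0`, `tau0`
#'   (population mean/sd of initial states), `sigma` (observation-scale
#'   noise sds) and `clinical` ([ordered_logit_params()]).
#' @export
default_true_params <- function() {
  ch <- adpm_channels()
  V <- matrix(0, 5, 5, dimnames = list(ch, ch))
  V["tau", c("tau", "abeta")] <- c(0.10, -0.08)
  V["abeta", c("tau", "abeta")] <- c(-0.04, -0.03)
  V["lang", c("tau", "abeta", "lang")] <- c(0.10, -0.06, 0.05)
  V["mem", c("tau", "abeta", "mem")] <- c(0.12, -0.08, 0.05)
  V["praxis", c("tau", "abeta", "praxis")] <- c(0.08, -0.05, 0.04)
  W_age <- matrix(0, 5, 5, dimnames = list(ch, ch))
  W_age["tau", "tau"] <- 0.02
  W_age["abeta", "tau"] <- -0.02
  W_age["mem", "tau"] <- 0.02
  W_apoe <- matrix(0, 5, 5, dimnames = list(ch, ch))
  W_apoe["tau", "abeta"] <- -0.04
  W_apoe["abeta", "abeta"] <- -0.03
  v0 <- c(tau = 0.01, abeta = -0.01, lang = 0.01, mem = 0.01, praxis = 0.01)
  list(
    velocity = velocity_params(V, W_age, W_apoe, v0),
    mu0 = c(tau = -0.2, abeta = 0.4, lang = -0.2, mem = -0.2,
            praxis = -0.2),
    tau0 = c(tau = 0.8, abeta = 0.8, lang = 0.7, mem = 0.7, praxis = 0.7),
    sigma = c(tau = 25, abeta = 90, lang = 0.25, mem = 0.25, praxis = 0.25),
    clinical = ordered_logit_params(
      c1 = -0.3, c2 = 2.2,
      beta_x = c(0.7, -0.6, 0.4, 0.8, 0.3),
      beta_y = c(0.2, 0.3))
  )
}

#' Generator configuration
#'
#' Visit schedules emulate the ADNI structure: exponential follow-up
#' durations (cognitive mean ~4 y, max 15; CSF mean ~1.5 y, max 10),
#' baseline plus thinned annual (CSF) or semi-annual-then-annual (cognitive)
#' grids with uniform jitter, annual diagnosis assessments, and upper
#' censoring of amyloid-beta at the assay limit.  `schedule = "regular"`
#' instead observes every channel and the diagnosis at fixed equispaced
#' visits (`regular_visits` over `regular_span` years), the design used for
#' parameter-recovery experiments.
#'
#' @param n_subjects,n_sites Cohort size and number of recruiting sites.
#' @param schedule `"adni"` or `"regular"`.
#' @param regular_visits,regular_span Visit count and span (years) of the
#'   regular schedule.
#' @param followup_cog_mean,followup_cog_max,followup_csf_mean,followup_csf_max
#'   Follow-up duration model (years).
#' @param p_csf,p_cog,p_diag Per-gridpoint retention probabilities.
#' @param age_mean,age_sd,apoe_prev Covariate distribution.
#' @param true_params Ground truth, as [default_true_params()].
#' @param noise_scale Multiplier on all observation noise sds.
#' @param censor Logical: apply the amyloid-beta upper limit.
#' @param seed Master seed recorded in the cohort metadata.
#' @param config An [adpm_config()] supplying links and censoring limits.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 150, n_sites = 6,
                             schedule = c("adni", "regular"),
                             regular_visits = 4, regular_span = 3,
                             followup_cog_mean = 4.2, followup_cog_max = 15,
                             followup_csf_mean = 4.5, followup_csf_max = 10,
                             p_csf = 0.55, p_cog = 0.9, p_diag = 0.95,
                             age_mean = 75, age_sd = 7, apoe_prev = 0.45,
                             true_params = default_true_params(),
                             noise_scale = 1, censor = TRUE, seed = 1,
                             config = adpm_config()) {
  schedule <- match.arg(schedule)
  stopifnot(n_subjects >= 1, n_sites >= 1, regular_visits >= 2,
            noise_scale >= 0, apoe_prev >= 0, apoe_prev <= 1)
  structure(as.list(environment()), class = "generator_config")
}

# deterministic "true" conversion time: first crossing of P(AD) = 0.5 along
# the noiseless trajectory (linear interpolation; NA if never within 30 y)
.true_conversion_time <- function(x0, sys, y, clinical,
                                  grid = seq(0, 30, by = 0.1)) {
  traj <- solve_trajectory(x0, sys, grid)
  p_ad <- probs_along_trajectory(traj, y, clinical)[, "AD"]
  .first_crossing(grid, p_ad, 0.5)
}

.first_crossing <- function(t, p, thr) {
  if (p[1] >= thr) return(t[1])
  ix <- which(p >= thr)
  if (!length(ix)) return(NA_real_)
  i <- ix[1]
  t[i - 1] + (t[i] - t[i - 1]) * (thr - p[i - 1]) / (p[i] - p[i - 1])
}

#' Simulate a synthetic cohort
#'
#' Forward simulation of the full generative model: covariates and initial
#' states are sampled from the population model, latent trajectories solved
#' exactly, channel observations emitted through the sigmoid links with
#' Gaussian noise (amyloid-beta right-censored at the assay limit), and
#' diagnosis labels drawn from the ordered-logit layer.
#'
#' @param gconfig A [generator_config()].
#' @return An `adpm_cohort`; `attr(, "ground_truth")` holds the true
#'   parameters, initial states, and noiseless conversion times.
#' @export
simulate_cohort <- function(gconfig = generator_config()) {
  stopifnot(inherits(gconfig, "generator_config"))
  g <- gconfig
  cfg <- g$config
  tp <- g$true_params
  set.seed(g$seed)

  links <- cfg$links
  limits <- .censor_limits(cfg)
  sig <- tp$sigma * g$noise_scale

  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(g$n_subjects)),
    site_id = sprintf("site%02d", sample(g$n_sites, g$n_subjects,
                                         replace = TRUE)),
    age = round(pmin(pmax(rnorm(g$n_subjects, g$age_mean, g$age_sd), 55),
                     90), 1),
    apoe4 = rbinom(g$n_subjects, 1, g$apoe_prev))

  x0 <- sapply(seq_len(5), function(j)
    rnorm(g$n_subjects, tp$mu0[j], tp$tau0[j]))
  colnames(x0) <- adpm_channels()

  obs_list <- vector("list", g$n_subjects)
  dg_list <- vector("list", g$n_subjects)
  conv <- numeric(g$n_subjects)

  for (s in seq_len(g$n_subjects)) {
    if (g$schedule == "regular") {
      t_csf <- t_cog <- t_dg <-
        seq(0, g$regular_span, length.out = g$regular_visits)
    } else {
      f_cog <- min(rexp(1, 1 / g$followup_cog_mean), g$followup_cog_max)
      f_csf <- min(f_cog, rexp(1, 1 / g$followup_csf_mean),
                   g$followup_csf_max)
      jit <- function(t) pmax(t + runif(length(t), -0.15, 0.15), 0.01)
      grid_csf <- seq_len(floor(f_csf))
      t_csf <- c(0, jit(grid_csf[runif(length(grid_csf)) < g$p_csf]))
      grid_cog <- unique(c(0.5, 1, 1.5, 2, seq(3, max(3, floor(f_cog)))))
      grid_cog <- grid_cog[grid_cog <= f_cog]
      t_cog <- c(0, jit(grid_cog[runif(length(grid_cog)) < g$p_cog]))
      grid_dg <- 0:floor(f_cog)
      t_dg <- grid_dg[c(TRUE, runif(length(grid_dg) - 1) < g$p_diag)]
    }
    y <- covariate_vector(.std_age(subjects$age[s], cfg),
                          subjects$apoe4[s])
    sys <- assemble_system(tp$velocity, y)
    all_t <- sort(unique(c(t_csf, t_cog, t_dg)))
    traj <- solve_trajectory(x0[s, ], sys, all_t)
    at <- function(t) traj[match(t, all_t), , drop = FALSE]

    rows <- list()
    for (ch in c("tau", "abeta")) {
      xs <- at(t_csf)[, ch]
      val <- sigmoid_link(xs, links[[ch]]) + rnorm(length(xs), 0, sig[[ch]])
      cens <- rep(0L, length(val))
      if (g$censor && is.finite(limits[[ch]])) {
        over <- val > limits[[ch]]
        cens[over] <- 1L
        val[over] <- limits[[ch]]
      }
      rows[[ch]] <- data.frame(subject_id = subjects$subject_id[s],
                               time_years = t_csf, channel = ch,
                               value = val, censored = cens)
    }
    for (ch in c("lang", "mem", "praxis")) {
      xs <- at(t_cog)[, ch]
      val <- sigmoid_link(xs, links[[ch]]) + rnorm(length(xs), 0, sig[[ch]])
      rows[[ch]] <- data.frame(subject_id = subjects$subject_id[s],
                               time_years = t_cog, channel = ch,
                               value = val, censored = 0L)
    }
    obs_list[[s]] <- do.call(rbind, rows)

    pr <- probs_along_trajectory(at(t_dg), y, tp$clinical)
    lab <- apply(pr, 1, function(p) sample(.labels, 1, prob = p))
    dg_list[[s]] <- data.frame(subject_id = subjects$subject_id[s],
                               time_years = t_dg, label = lab)
    conv[s] <- .true_conversion_time(x0[s, ], sys, y, tp$clinical)
  }

  cohort <- adpm_cohort(subjects, do.call(rbind, obs_list),
                        do.call(rbind, dg_list), cfg,
                        metadata = list(seed = g$seed,
                                        generator = "adpm synthetic"))
  rownames(x0) <- subjects$subject_id
  attr(cohort, "ground_truth") <- list(
    params = tp, x0 = x0,
    conversion_time = setNames(conv, subjects$subject_id))
  cohort
}

#' Frozen-seed reference cohorts
#'
#' @param scale `"tiny"` (12 subjects / 2 sites, for unit tests), `"small"`
#'   (150 / 6, for recovery experiments) or `"medium"` (600 / 12, for
#'   cross-validation experiments).
#' @param ... Overrides forwarded to [generator_config()].
#' @return An `adpm_cohort` with ground truth attached.
#' @export
make_fixture <- function(scale = c("tiny", "small", "medium"), ...) {
  scale <- match.arg(scale)
  spec <- switch(scale,
                 tiny = list(n_subjects = 12, n_sites = 2, seed = 101),
                 small = list(n_subjects = 150, n_sites = 6, seed = 202),
                 medium = list(n_subjects = 600, n_sites = 12, seed = 303))
  simulate_cohort(do.call(generator_config, c(spec, list(...))))
}
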