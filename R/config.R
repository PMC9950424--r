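# Model configuration: channel links, censoring, priors, age
# standardization and MCMC settings, overridable from R or a YAML file.

#' Model configuration
#'
#' Builds the configuration used by [adpm()], [simulate_cohort()] and the
#' evaluation machinery.  Defaults: sigmoid links anchoring the latent scale
#' (slope fixed at 1 for the CSF channels, 0.6 for the cognitive traits,
#' midpoint 0), right-censoring of amyloid-beta at 1700 pg/mL, age
#' standardized as (age - 75)/10, weakly informative priors, and 2 chains of
#' 1000 warmup + 1000 retained sweeps.
#'
#' @param file Optional YAML file; its entries override the defaults and are
#'   themselves overridden by `...`.
#' @param ... Named overrides of top-level entries (lists are merged one
#'   level deep, e.g. `mcmc = list(iter = 500)`).
#' @return A nested list of class `adpm_config`.
#' @export
adpm_config <- function(file = NULL, ...) {
  cfg <- list(
    channels = adpm_channels(),
    links = list(
      tau   = link_params(0, 700, slope = 1, midpoint = 0),
      abeta = link_params(200, 2000, slope = 1, midpoint = 0),
      lang  = link_params(-4, 4, slope = 0.6, midpoint = 0),
      mem   = link_params(-4, 4, slope = 0.6, midpoint = 0),
      praxis = link_params(-4, 4, slope = 0.6, midpoint = 0)
    ),
    censoring = list(abeta = list(upper = 1700)),
    age = list(center = 75, scale = 10),
    sigma_init = c(tau = 25, abeta = 90, lang = 0.25, mem = 0.25,
                   praxis = 0.25),
    priors = list(
      velocity_sd = 0.5,      # free entries of V, W_c, v0 (1/year)
      mu0_sd = 5,             # population mean of initial states
      tau0_scale = 2.5,       # half-Normal on population sds
      sigma_scale_rel = 0.5,  # half-Normal on noise sds, x channel range/8
      clinical_sd = 5,        # ordered-logit coefficients and first cutpoint
      log_gap_sd = 1.5,       # induced ordered prior on the cutpoint gap
      log_slope_sd = 0.2,     # link slope (log scale), if estimated
      midpoint_sd = 0.5       # link midpoint, if estimated
    ),
    estimate_covariate_effects = TRUE,
    estimate_links = FALSE,
    likelihood_weight = 1,
    label_map = c(SMC = "CN", EMCI = "MCI", LMCI = "MCI"),
    mcmc = list(chains = 2, warmup = 1000, iter = 1000, seed = 1,
                vel_updates = 1, hmc_steps = 8, x0_refresh = TRUE,
                refresh = 0)
  )
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    cfg <- .merge_config(cfg, .rehydrate_config(over))
  }
  dots <- list(...)
  if (length(dots)) cfg <- .merge_config(cfg, dots)
  class(cfg) <- "adpm_config"
  cfg
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !inherits(base[[nm]], "link_params")) {
      for (k in names(over[[nm]])) base[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

# YAML stores links/censoring as plain lists; rebuild the typed objects
.rehydrate_config <- function(over) {
  if (!is.null(over$links)) {
    over$links <- lapply(over$links, function(l) {
      do.call(link_params, l[c("lower", "upper", "slope", "midpoint")])
    })
  }
  if (!is.null(over$sigma_init)) over$sigma_init <- unlist(over$sigma_init)
  if (!is.null(over$label_map)) over$label_map <- unlist(over$label_map)
  over
}

#' Write a configuration to YAML
#'
#' @param config An [adpm_config()] object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_config <- function(config, file) {
  plain <- unclass(config)
  plain$links <- lapply(plain$links, unclass)
  yaml::write_yaml(plain, file)
  invisible(file)
}

# standardized age used by both the dynamics and the clinical layer
.std_age <- function(age, config) (age - config$age$center) / config$age$scale

# per-channel censoring limits in canonical order (NA if uncensored)
.censor_limits <- function(config) {
  lim <- rep(NA_real_, 5)
  names(lim) <- adpm_channels()
  for (ch in names(config$censoring))
    lim[ch] <- config$censoring[[ch]]$upper
  lim
}
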