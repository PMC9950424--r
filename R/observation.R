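# Observation layer: sigmoid links between the latent state and the
# measurement scale, Gaussian / right-censored Gaussian likelihoods, and
# graded-response IRT scoring of cognitive items.

#' Sigmoid link parameters for one observation channel
#'
#' @param lower,upper Asymptotes on the observation scale (`upper > lower`).
#' @param slope Positive slope on the latent scale.
#' @param midpoint Latent value mapped to the centre of the range.
#' @return An object of class `link_params`.
#' @export
link_params <- function(lower, upper, slope = 1, midpoint = 0) {
  if (!(upper > lower)) stop("'upper' must exceed 'lower'", call. = FALSE)
  if (!(slope > 0)) stop("'slope' must be positive", call. = FALSE)
  structure(list(lower = lower, upper = upper, slope = slope,
                 midpoint = midpoint), class = "link_params")
}

#' Sigmoid link from latent units to the observation scale
#'
#' `lower + (upper - lower) * logistic(slope * (x - midpoint))`; strictly
#' increasing and bounded, producing plateau effects at the observation
#' level.
#'
#' @param x Latent value(s).
#' @param link A [link_params()] object.
#' @return Value(s) on the observation scale, in `(lower, upper)`.
#' @export
sigmoid_link <- function(x, link) {
  stopifnot(inherits(link, "link_params"))
  link$lower + (link$upper - link$lower) *
    plogis(link$slope * (x - link$midpoint))
}

#' Inverse of the sigmoid link
#'
#' @param value Observation-scale value(s) strictly inside `(lower, upper)`;
#'   values outside are clamped just inside the range.
#' @param link A [link_params()] object.
#' @return Latent value(s).
#' @export
inv_sigmoid_link <- function(value, link) {
  stopifnot(inherits(link, "link_params"))
  p <- (value - link$lower) / (link$upper - link$lower)
  p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  link$midpoint + qlogis(p) / link$slope
}

#' Gaussian observation log-likelihood
#'
#' @param value Observed value (not censored).
#' @param mean Predicted mean on the observation scale.
#' @param sigma Noise standard deviation (> 0).
#' @return Log-density.
#' @export
gaussian_loglik <- function(value, mean, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be positive", call. = FALSE)
  dnorm(value, mean, sigma, log = TRUE)
}

#' Censored Gaussian observation log-likelihood
#'
#' Log-probability mass beyond a detection limit: for an upper limit U
#' (right censoring, e.g. the amyloid-beta assay ceiling of 1700 pg/mL),
#' `log P(X > U) = log(1 - Phi((U - mean)/sigma))`; symmetric for a lower
#' limit.
#'
#' @param mean,sigma Gaussian parameters on the observation scale.
#' @param limit Detection limit.
#' @param side `"upper"` (right-censored) or `"lower"`.
#' @return Log-probability of exceeding (falling below) the limit.
#' @export
censored_gaussian_loglik <- function(mean, sigma, limit, side = "upper") {
  if (any(sigma <= 0)) stop("'sigma' must be positive", call. = FALSE)
  side <- match.arg(side, c("upper", "lower"))
  pnorm(limit, mean, sigma, lower.tail = (side == "lower"), log.p = TRUE)
}

#' Graded-response IRT item
#'
#' @param discrimination Non-negative discrimination parameter.
#' @param thresholds Strictly ascending category thresholds on the trait
#'   scale; an item with `m` thresholds has `m + 1` ordered categories.
#' @param domain Cognitive domain the item loads on: `"lang"`, `"mem"` or
#'   `"praxis"`.
#' @return An object of class `irt_item`.
#' @export
irt_item <- function(discrimination, thresholds, domain) {
  if (discrimination < 0)
    stop("'discrimination' must be non-negative", call. = FALSE)
  if (length(thresholds) > 1 && any(diff(thresholds) <= 0))
    stop("'thresholds' must be strictly ascending", call. = FALSE)
  domain <- match.arg(domain, c("lang", "mem", "praxis"))
  structure(list(discrimination = discrimination,
                 thresholds = as.numeric(thresholds), domain = domain),
            class = "irt_item")
}

#' Category probabilities of a graded-response item
#'
#' Cumulative model: P(category >= c) = logistic(a (trait - b_c)); category
#' probabilities are successive differences.  By the trait convention used
#' throughout (larger trait = worse cognition), higher categories are worse
#' responses.
#'
#' @param trait Latent trait value.
#' @param item An [irt_item()].
#' @return Probability vector over the `length(thresholds) + 1` categories.
#' @export
irt_category_probs <- function(trait, item) {
  stopifnot(inherits(item, "irt_item"))
  cum <- plogis(item$discrimination * (trait - item$thresholds))
  p <- diff(c(1, cum, 0)) * -1
  names(p) <- paste0("cat", seq_along(p) - 1L)
  p
}

#' An item bank for cognitive scoring
#'
#' @param items List of [irt_item()] objects.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items) {
  stopifnot(length(items) > 0, all(vapply(items, inherits, TRUE, "irt_item")))
  if (is.null(names(items)))
    names(items) <- paste0("item", seq_along(items))
  structure(list(items = items), class = "item_bank")
}

#' Read an item-response table
#'
#' CSV dialect: `subject_id`, `time_years`, `item_id`, `category` (0-based
#' observed category).
#'
#' @param file CSV path.
#' @return Validated data frame.
#' @export
read_item_responses <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_years", "item_id", "category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("item-response file lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(is.finite(df$time_years)) || !all(df$category >= 0))
    stop("invalid time or category values", call. = FALSE)
  df
}

#' Score an item-response table into trait observations
#'
#' Applies [score_traits()] per subject-visit and returns long-format
#' observation rows (channels `lang`, `mem`, `praxis`) ready to be merged
#' into a cohort's observation table.  The per-visit scoring standard error
#' is carried in the `se` column, which the model likelihood adds in
#' quadrature to the channel noise sd (two-stage cognition handling).
#'
#' @param responses Data frame as read by [read_item_responses()].
#' @param bank An [item_bank()].
#' @return Data frame: `subject_id`, `time_years`, `channel`, `value`,
#'   `censored` (always 0), `se`; domains with no responses at a visit are
#'   omitted.
#' @export
score_item_responses <- function(responses, bank) {
  key <- interaction(responses$subject_id, responses$time_years,
                     drop = TRUE)
  rows <- lapply(split(responses, key), function(vis) {
    sc <- score_traits(vis[, c("item_id", "category")], bank)
    sc <- sc[!is.na(sc$estimate), , drop = FALSE]
    if (!nrow(sc)) return(NULL)
    data.frame(subject_id = vis$subject_id[1],
               time_years = vis$time_years[1], channel = sc$domain,
               value = sc$estimate, censored = 0L, se = sc$se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score item responses into domain traits
#'
#' Maximum-a-posteriori trait per cognitive domain under a standard-normal
#' prior, with a curvature-based standard error; the trait estimates can then
#' feed the dynamic model as Gaussian observations with variance
#' sigma^2 + SE^2 (two-stage scoring).
#'
#' @param responses Data frame with columns `item_id` (names in the bank)
#'   and `category` (0-based observed category).
#' @param bank An [item_bank()].
#' @return Data frame with one row per domain: `domain`, `estimate`, `se`,
#'   `n_items`; domains without responses carry `NA` estimates.
#' @export
score_traits <- function(responses, bank) {
  stopifnot(inherits(bank, "item_bank"))
  domains <- c("lang", "mem", "praxis")
  out <- data.frame(domain = domains, estimate = NA_real_, se = NA_real_,
                    n_items = 0L, stringsAsFactors = FALSE)
  if (nrow(responses) == 0) return(out)
  unknown <- setdiff(responses$item_id, names(bank$items))
  if (length(unknown))
    stop("unknown item id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (d in domains) {
    keep <- vapply(as.character(responses$item_id),
                   function(id) bank$items[[id]]$domain == d, TRUE)
    if (!any(keep)) next
    resp <- responses[keep, , drop = FALSE]
    nlp <- function(theta) {
      ll <- dnorm(theta, log = TRUE)
      for (r in seq_len(nrow(resp))) {
        item <- bank$items[[as.character(resp$item_id[r])]]
        p <- irt_category_probs(theta, item)[resp$category[r] + 1L]
        ll <- ll + log(max(p, 1e-300))
      }
      -ll
    }
    opt <- optimize(nlp, c(-8, 8))
    est <- opt$minimum
    h <- 1e-4
    curv <- (nlp(est + h) - 2 * nlp(est) + nlp(est - h)) / h^2
    i <- match(d, domains)
    out$estimate[i] <- est
    out$se[i] <- if (curv > 0) 1 / sqrt(curv) else NA_real_
    out$n_items[i] <- nrow(resp)
  }
  out
}
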