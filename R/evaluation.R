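# Validation machinery: leave-one-site-out cross-validation, discrimination,
# multi-class calibration, decision curves and time-to-conversion errors.

#' Leave-one-site-out folds
#'
#' One fold per recruiting site: that site's subjects form the test set and
#' everyone else the training set.
#'
#' @param cohort An `adpm_cohort`.
#' @return List of folds, each with `test_site`, `train_ids`, `test_ids`.
#' @export
loso_split <- function(cohort) {
  sites <- sort(unique(as.character(cohort$subjects$site_id)))
  if (length(sites) < 2)
    stop("leave-one-site-out needs at least 2 sites; ",
         "consider grouped k-fold instead", call. = FALSE)
  lapply(sites, function(st) {
    test <- cohort$subjects$site_id == st
    list(test_site = st,
         train_ids = as.character(cohort$subjects$subject_id[!test]),
         test_ids = as.character(cohort$subjects$subject_id[test]))
  })
}

.subset_cohort <- function(cohort, ids) {
  adpm_cohort(cohort$subjects[cohort$subjects$subject_id %in% ids, ,
                              drop = FALSE],
              cohort$observations[cohort$observations$subject_id %in% ids, ,
                                  drop = FALSE],
              cohort$diagnoses[cohort$diagnoses$subject_id %in% ids, ,
                               drop = FALSE],
              cohort$config, cohort$metadata)
}

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted one half (equivalent to the rank-sum statistic).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1, logical, or a 2-level factor).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.factor(labels)) - 1L
  if (length(unique(labels)) < 2)
    stop("auroc undefined: both classes must be present", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confidence- and classwise-reliability diagrams
#'
#' Calibration tables for a 3-class probabilistic predictor, assessed at the
#' prediction (assessment) level.  The confidence diagram bins the maximum
#' predicted probability and reports the accuracy of the arg-max class; it
#' is restricted to probabilities above 0.4 since 1/3 is the smallest value
#' the maximum of three probabilities can take.  The classwise diagrams bin
#' the probability assigned to each class and report the frequency of that
#' class.  95% intervals are central posterior intervals of a
#' Beta(1,1)-Binomial model per bin; empty bins carry the prior interval.
#'
#' @param probs Matrix of predicted probabilities (columns CN, MCI, AD).
#' @param truth Character/factor of true labels.
#' @param bin_width Bin width (default 0.2).
#' @param conf_min Lower probability bound of the confidence diagram
#'   (default 0.4).
#' @return List of data frames `confidence` and `classwise` with columns
#'   `bin_lower`, `bin_upper`, `n`, `mean_pred` (the bin's mean predicted
#'   probability, i.e. its point on the calibration diagonal), `accuracy`,
#'   `ci_lower`, `ci_upper` (plus `class` for the classwise table).
#' @export
reliability_diagrams <- function(probs, truth, bin_width = 0.2,
                                 conf_min = 0.4) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3, nrow(probs) == length(truth))
  truth <- as.character(truth)
  breaks <- seq(0, 1, by = bin_width)
  bin_of <- function(p) pmin(pmax(findInterval(p, breaks,
                                               rightmost.closed = TRUE),
                                  1), length(breaks) - 1)
  beta_ci <- function(k, n)
    c(qbeta(0.025, k + 1, n - k + 1), qbeta(0.975, k + 1, n - k + 1))

  tab <- function(p, hit, keep_bins) {
    rows <- lapply(keep_bins, function(b) {
      sel <- bin_of(p) == b
      n <- sum(sel)
      k <- sum(hit[sel])
      ci <- beta_ci(k, n)
      # mean_pred is the bin's point on the calibration diagonal (the
      # within-bin distribution of predictions is generally skewed, so the
      # bin midpoint would be a biased reference)
      data.frame(bin_lower = breaks[b], bin_upper = breaks[b + 1], n = n,
                 mean_pred = if (n > 0) mean(p[sel]) else NA_real_,
                 accuracy = if (n > 0) k / n else NA_real_,
                 ci_lower = ci[1], ci_upper = ci[2])
    })
    do.call(rbind, rows)
  }

  pmax_hat <- apply(probs, 1, max)
  argmax <- colnames(probs)[max.col(probs, ties.method = "first")]
  conf_bins <- which(breaks[-length(breaks)] >= conf_min - 1e-12)
  confidence <- tab(pmax_hat, argmax == truth, conf_bins)

  classwise <- do.call(rbind, lapply(colnames(probs), function(cl) {
    out <- tab(probs[, cl], truth == cl, seq_len(length(breaks) - 1))
    out$class <- cl
    out
  }))
  list(confidence = confidence,
       classwise = classwise[, c("class", setdiff(names(classwise),
                                                  "class"))])
}

#' Decision-curve net benefit
#'
#' Net benefit of treating subjects with predicted dementia probability
#' above a threshold, against the treat-all and treat-none strategies:
#' `NB(p) = TP/N - FP/N * p/(1-p)`.
#'
#' @param p_ad Predicted P(AD).
#' @param truth Binary outcome (1 = AD).
#' @param p_grid Threshold probabilities in (0, 1).
#' @return Data frame: `p_th`, `nb_model`, `nb_all`, `nb_none`.
#' @export
net_benefit <- function(p_ad, truth, p_grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(p_grid > 0 & p_grid < 1))
  truth <- as.integer(truth)
  n <- length(truth)
  prev <- mean(truth)
  out <- lapply(p_grid, function(p) {
    pos <- p_ad > p
    tp <- sum(pos & truth == 1) / n
    fp <- sum(pos & truth == 0) / n
    odds <- p / (1 - p)
    data.frame(p_th = p, nb_model = tp - fp * odds,
               nb_all = prev - (1 - prev) * odds, nb_none = 0)
  })
  do.call(rbind, out)
}

#' Time-to-conversion error analysis
#'
#' Converters are scored by predicted-minus-observed conversion time;
#' non-converters by predicted time minus maximum follow-up (negative values
#' flag premature predicted conversions).  Predicted times beyond the
#' horizon enter as the horizon (right-censored prediction).
#'
#' @param predicted Data frame: `subject_id`, `t50` (NA = beyond horizon),
#'   `horizon`.
#' @param observed Data frame: `subject_id`, `converted` (0/1),
#'   `event_time` (first AD time for converters, max follow-up otherwise).
#' @return List: `errors` (per-subject table) and `cumulative` (data frame
#'   `abs_error`, `fraction` — the cumulative |error| distribution over
#'   converters).
#' @export
conversion_error_analysis <- function(predicted, observed) {
  m <- merge(predicted, observed, by = "subject_id")
  m$t50_eff <- ifelse(is.na(m$t50), m$horizon, m$t50)
  m$error <- m$t50_eff - m$event_time
  conv <- m[m$converted == 1, , drop = FALSE]
  cum <- NULL
  if (nrow(conv)) {
    ae <- sort(abs(conv$error))
    cum <- data.frame(abs_error = ae,
                      fraction = seq_along(ae) / length(ae))
  }
  list(errors = m[, c("subject_id", "converted", "event_time", "t50",
                      "t50_eff", "error")],
       cumulative = cum)
}

#' Leave-one-site-out forecasting experiment
#'
#' For each fold: fit the model on the training sites, condition each
#' test subject's initial state on its first `window` years, forecast
#' forward, and score the predicted label probabilities at every diagnosis
#' assessment after the window.  Aggregates discrimination (AUROC of
#' AD-vs-non-AD, pooled and at fixed horizons), calibration tables,
#' decision curves, and time-to-conversion errors.
#'
#' @param cohort Multi-site `adpm_cohort`.
#' @param config An [adpm_config()]; its `mcmc` settings apply per fold.
#' @param window Conditioning window (years), default `c(0, 2)`.
#' @param horizons Forecast horizons (years) for conversion AUROC.
#' @param conversion_horizon Horizon for time-to-conversion predictions.
#' @param ndraws Posterior draws per forecast.
#' @param n_steps Metropolis steps per draw for each test subject's
#'   initial state (see [estimate_initial_state()]).
#' @param progress Print per-fold progress.
#' @return Object of class `adpm_eval`: `predictions` (one row per scored
#'   assessment), `auroc` (per horizon), `reliability`, `net_benefit`,
#'   `conversion`, `folds`.
#' @export
run_loso_experiment <- function(cohort, config = cohort$config,
                                window = c(0, 2), horizons = c(3, 5, 7),
                                conversion_horizon = 10, ndraws = 100,
                                n_steps = 40, progress = FALSE) {
  folds <- loso_split(cohort)
  preds <- list()
  conv_pred <- list()
  conv_obs <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    if (progress)
      message(sprintf("fold %d/%d (site %s)", f, length(folds),
                      fold$test_site))
    train <- .subset_cohort(cohort, fold$train_ids)
    # master seed fans out deterministically per fold
    fit <- adpm(train, config,
                seed = as.integer(config$mcmc$seed) + 7919L * f)
    for (sid in fold$test_ids) {
      dgs <- cohort$diagnoses[cohort$diagnoses$subject_id == sid, ,
                              drop = FALSE]
      later <- dgs[dgs$time_years > window[2], , drop = FALSE]
      fc <- tryCatch({
        grid_max <- max(conversion_horizon, later$time_years,
                        max(horizons))
        forecast(fit, cohort, sid,
                 grid = seq(0, grid_max + 0.5, by = 1 / 12),
                 window = window, ndraws = ndraws, n_steps = n_steps)
      }, error = function(e) NULL)
      if (is.null(fc)) next
      if (nrow(later)) {
        p <- t(vapply(later$time_years, function(tt) {
          i <- which.min(abs(fc$grid - tt))
          fc$mean_prob[i, ]
        }, numeric(3)))
        preds[[length(preds) + 1]] <- data.frame(
          subject_id = sid, site_id = fold$test_site,
          time_years = later$time_years,
          p_cn = p[, 1], p_mci = p[, 2], p_ad = p[, 3],
          truth = as.character(later$label))
      }
      ttc <- time_to_conversion(fc, horizon = conversion_horizon)
      conv_pred[[length(conv_pred) + 1]] <- data.frame(
        subject_id = sid, t50 = unname(ttc$times["t50"]),
        t30 = unname(ttc$times["t30"]), t70 = unname(ttc$times["t70"]),
        horizon = conversion_horizon)
      ad_times <- dgs$time_years[dgs$label == "AD"]
      conv_obs[[length(conv_obs) + 1]] <- data.frame(
        subject_id = sid, converted = as.integer(length(ad_times) > 0),
        event_time = if (length(ad_times)) min(ad_times)
                     else max(dgs$time_years, 0))
    }
  }
  predictions <- do.call(rbind, preds)
  if (is.null(predictions) || !nrow(predictions))
    stop("no post-window assessments were scored", call. = FALSE)

  # horizon AUROCs: AD-by-horizon among subjects observed that far
  au <- lapply(horizons, function(h) {
    per_sub <- split(predictions, predictions$subject_id)
    rows <- lapply(per_sub, function(df) {
      conv_t <- suppressWarnings(min(df$time_years[df$truth == "AD"]))
      at_risk <- max(df$time_years) >= h || is.finite(conv_t)
      if (!at_risk) return(NULL)
      i <- which.min(abs(df$time_years - h))
      data.frame(label = as.integer(is.finite(conv_t) && conv_t <= h),
                 score = df$p_ad[i])
    })
    rows <- do.call(rbind, rows)
    val <- if (!is.null(rows) && length(unique(rows$label)) == 2)
      auroc(rows$score, rows$label) else NA_real_
    data.frame(horizon = h, auroc = val,
               n = if (is.null(rows)) 0L else nrow(rows))
  })
  auroc_tab <- do.call(rbind, au)
  pooled <- auroc(predictions$p_ad, predictions$truth == "AD")

  rel <- reliability_diagrams(
    as.matrix(predictions[, c("p_cn", "p_mci", "p_ad")]),
    predictions$truth)
  nb <- net_benefit(predictions$p_ad,
                    as.integer(predictions$truth == "AD"))
  conv <- conversion_error_analysis(do.call(rbind, conv_pred),
                                    do.call(rbind, conv_obs))
  structure(list(predictions = predictions, auroc = auroc_tab,
                 auroc_pooled = pooled, reliability = rel,
                 net_benefit = nb, conversion = conv, folds = folds,
                 note = paste("calibration pooled at assessment level;",
                              "within-subject clustering not adjusted")),
            class = "adpm_eval")
}

#' @export
print.adpm_eval <- function(x, ...) {
  cat(sprintf("LOSO evaluation: %d folds, %d scored assessments\n",
              length(x$folds), nrow(x$predictions)))
  cat(sprintf("pooled AD-vs-non-AD AUROC: %.3f\n", x$auroc_pooled))
  print(round(x$auroc, 3))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report An `adpm_eval`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$predictions, file.path(dir, "predictions.csv"),
            row.names = FALSE)
  write.csv(report$reliability$classwise, file.path(dir, "reliability.csv"),
            row.names = FALSE)
  write.csv(report$net_benefit, file.path(dir, "netbenefit.csv"),
            row.names = FALSE)
  write.csv(report$conversion$errors,
            file.path(dir, "conversion_errors.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(auroc_pooled = report$auroc_pooled,
         auroc_by_horizon = report$auroc, note = report$note),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
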