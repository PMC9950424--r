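# Ordered-logit clinical layer: P(label | latent state, covariates).

.labels <- c("CN", "MCI", "AD")

#' Ordered-logit parameters of the diagnosis model
#'
#' The linear predictor is eta = beta_x . x + beta_y . (age_std, apoe4) and
#' the cumulative probabilities are logistic(c1 - eta) and logistic(c2 - eta)
#' for the ordered outcome CN < MCI < AD.
#'
#' @param c1,c2 Cutpoints, `c1 < c2`.
#' @param beta_x Length-5 coefficients on the latent state.
#' @param beta_y Length-2 coefficients on (age_std, apoe4).
#' @return An object of class `ordered_logit_params`.
#' @export
ordered_logit_params <- function(c1, c2, beta_x, beta_y) {
  if (!(c1 < c2)) stop("cutpoints must satisfy c1 < c2", call. = FALSE)
  beta_x <- as.numeric(beta_x)
  beta_y <- as.numeric(beta_y)
  if (length(beta_x) != 5) stop("'beta_x' must have length 5", call. = FALSE)
  if (length(beta_y) != 2) stop("'beta_y' must have length 2", call. = FALSE)
  structure(list(c1 = c1, c2 = c2,
                 beta_x = setNames(beta_x, adpm_channels()),
                 beta_y = setNames(beta_y, c("age_std", "apoe4"))),
            class = "ordered_logit_params")
}

#' Diagnosis label probabilities at a state
#'
#' @param x Latent state (length 5).
#' @param y A [covariate_vector()].
#' @param params An [ordered_logit_params()].
#' @return Named probability vector `(CN, MCI, AD)` summing to 1.
#' @export
label_probs <- function(x, y, params) {
  stopifnot(inherits(params, "ordered_logit_params"),
            inherits(y, "covariate_vector"))
  x <- as.numeric(x)
  if (length(x) != 5) stop("state must have length 5", call. = FALSE)
  eta <- sum(params$beta_x * x) +
    params$beta_y[[1]] * y$age_std + params$beta_y[[2]] * y$apoe4
  p_cn <- plogis(params$c1 - eta)
  p_cum <- plogis(params$c2 - eta)
  setNames(c(p_cn, p_cum - p_cn, 1 - p_cum), .labels)
}

#' Label probabilities along a trajectory
#'
#' Row-wise [label_probs()] over a matrix of states, e.g. the output of
#' [solve_trajectory()].
#'
#' @param traj Matrix of states (rows = times, 5 columns).
#' @param y A [covariate_vector()].
#' @param params An [ordered_logit_params()].
#' @return Matrix `nrow(traj)` x 3 with columns CN, MCI, AD.
#' @export
probs_along_trajectory <- function(traj, y, params) {
  traj <- rbind(traj)
  out <- t(apply(traj, 1, label_probs, y = y, params = params))
  colnames(out) <- .labels
  out
}

#' Map enrollment categories onto the three model labels
#'
#' Multi-arm study enrollment categories are collapsed onto the ordinal
#' CN < MCI < AD outcome.  Default map: SMC -> CN; EMCI, LMCI -> MCI.
#'
#' @param labels Character vector of labels.
#' @param map Named character vector of additional label translations.
#' @return Factor with ordered levels CN < MCI < AD.
#' @export
map_enrollment_labels <- function(labels,
                                  map = c(SMC = "CN", EMCI = "MCI",
                                          LMCI = "MCI")) {
  labels <- as.character(labels)
  hit <- labels %in% names(map)
  labels[hit] <- map[labels[hit]]
  bad <- setdiff(unique(labels), .labels)
  if (length(bad))
    stop("unmappable label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  factor(labels, levels = .labels, ordered = TRUE)
}
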