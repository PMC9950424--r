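# Cohort container and CSV readers/writers.
#
# CSV dialects:
#   observations: subject_id, site_id, time_years, channel, value, censored
#   diagnoses:    subject_id, time_years, label (CN/MCI/AD or enrollment
#                 categories translated by the config label map)
#   subjects:     subject_id, site_id, age, apoe4

#' Construct a validated cohort
#'
#' @param subjects Data frame: `subject_id`, `site_id`, `age` (years at
#'   baseline), `apoe4` (0/1).
#' @param observations Data frame: `subject_id`, `time_years`, `channel`
#'   (one of [adpm_channels()]), `value`, `censored` (0/1), and optionally
#'   `se` — a per-observation standard error (e.g. from two-stage IRT trait
#'   scoring) added in quadrature to the channel noise sd.
#' @param diagnoses Data frame: `subject_id`, `time_years`, `label`.
#' @param config An [adpm_config()]; supplies the censorable channels and
#'   the enrollment-label map.
#' @param metadata Optional provenance list (seed, source files, ...).
#' @return An object of class `adpm_cohort`.
#' @export
adpm_cohort <- function(subjects, observations, diagnoses,
                        config = adpm_config(), metadata = list()) {
  subjects <- as.data.frame(subjects)
  observations <- as.data.frame(observations)
  diagnoses <- as.data.frame(diagnoses)
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  req(subjects, c("subject_id", "site_id", "age", "apoe4"), "subjects")
  req(observations, c("subject_id", "time_years", "channel", "value",
                      "censored"), "observations")
  req(diagnoses, c("subject_id", "time_years", "label"), "diagnoses")
  if (is.null(observations$se)) observations$se <- 0
  observations$se[is.na(observations$se)] <- 0
  if (any(observations$se < 0))
    stop("observation 'se' must be non-negative", call. = FALSE)

  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject ids in the subjects table", call. = FALSE)
  orphan <- setdiff(c(observations$subject_id, diagnoses$subject_id),
                    subjects$subject_id)
  if (length(orphan))
    stop("observations/diagnoses reference unknown subject id(s): ",
         paste(head(orphan), collapse = ", "), call. = FALSE)
  if (!all(is.finite(observations$time_years)) ||
      !all(is.finite(diagnoses$time_years)))
    stop("non-finite observation or diagnosis times", call. = FALSE)
  bad_ch <- setdiff(unique(observations$channel), adpm_channels())
  if (length(bad_ch))
    stop("unknown channel(s): ", paste(bad_ch, collapse = ", "),
         call. = FALSE)
  if (!all(subjects$apoe4 %in% c(0, 1)))
    stop("'apoe4' must be 0 or 1", call. = FALSE)
  censorable <- names(config$censoring)
  if (any(observations$censored == 1 &
          !(observations$channel %in% censorable)))
    stop("censored flags on channels without a censoring limit",
         call. = FALSE)
  diagnoses$label <- map_enrollment_labels(diagnoses$label, config$label_map)

  # re-anchor each subject's clock at its first observation
  first <- tapply(c(observations$time_years, diagnoses$time_years),
                  c(observations$subject_id, diagnoses$subject_id), min)
  observations$time_years <- observations$time_years -
    as.numeric(first[as.character(observations$subject_id)])
  diagnoses$time_years <- diagnoses$time_years -
    as.numeric(first[as.character(diagnoses$subject_id)])

  structure(list(subjects = subjects, observations = observations,
                 diagnoses = diagnoses, config = config,
                 metadata = metadata),
            class = "adpm_cohort")
}

#' @export
print.adpm_cohort <- function(x, ...) {
  cat(sprintf(
    "adpm cohort: %d subjects, %d sites, %d observations, %d diagnoses\n",
    nrow(x$subjects), length(unique(x$subjects$site_id)),
    nrow(x$observations), nrow(x$diagnoses)))
  invisible(x)
}

#' @export
summary.adpm_cohort <- function(object, ...) {
  obs <- object$observations
  per_chan <- function(chs) {
    sel <- obs[obs$channel %in% chs, , drop = FALSE]
    n <- tabulate(factor(sel$subject_id,
                         levels = object$subjects$subject_id))
    fu <- tapply(sel$time_years, factor(sel$subject_id,
                 levels = object$subjects$subject_id), max)
    fu[is.na(fu)] <- 0
    c(mean_visits = mean(n), max_visits = max(n),
      mean_followup = mean(fu), max_followup = max(fu))
  }
  # CSF channels share visits, as do the cognitive traits; count visit times
  visits <- function(chs) {
    sel <- obs[obs$channel %in% chs, c("subject_id", "time_years")]
    sel <- unique(sel)
    n <- tabulate(factor(sel$subject_id,
                         levels = object$subjects$subject_id))
    fu <- tapply(sel$time_years, factor(sel$subject_id,
                 levels = object$subjects$subject_id), max)
    fu[is.na(fu)] <- 0
    c(mean_visits = mean(n), max_visits = max(n),
      mean_followup = mean(fu), max_followup = max(fu))
  }
  res <- list(
    n_subjects = nrow(object$subjects),
    n_sites = length(unique(object$subjects$site_id)),
    csf = visits(c("tau", "abeta")),
    cognition = visits(c("lang", "mem", "praxis")),
    censored_abeta = mean(obs$censored[obs$channel == "abeta"] == 1),
    labels = table(object$diagnoses$label)
  )
  class(res) <- "summary.adpm_cohort"
  res
}

#' @export
print.summary.adpm_cohort <- function(x, ...) {
  cat(sprintf("subjects: %d   sites: %d\n", x$n_subjects, x$n_sites))
  cat(sprintf("CSF visits/subject: %.2f (max %d), follow-up %.2f (max %.1f) y\n",
              x$csf["mean_visits"], as.integer(x$csf["max_visits"]),
              x$csf["mean_followup"], x$csf["max_followup"]))
  cat(sprintf("cognitive visits/subject: %.2f (max %d), follow-up %.2f (max %.1f) y\n",
              x$cognition["mean_visits"],
              as.integer(x$cognition["max_visits"]),
              x$cognition["mean_followup"], x$cognition["max_followup"]))
  cat(sprintf("censored abeta fraction: %.3f\n", x$censored_abeta))
  cat("diagnosis labels:\n")
  print(x$labels)
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' Malformed observation rows (unknown channel, non-numeric value, duplicate
#' subject/time/channel) are rejected with a message rather than aborting
#' the load; missing required columns are a hard error.
#'
#' @param observations_file,diagnoses_file,subjects_file CSV paths.
#' @param config An [adpm_config()].
#' @return An `adpm_cohort`; the rejection report is in
#'   `metadata$rejected_rows`.
#' @export
read_cohort <- function(observations_file, diagnoses_file, subjects_file,
                        config = adpm_config()) {
  obs <- read.csv(observations_file, stringsAsFactors = FALSE)
  dg <- read.csv(diagnoses_file, stringsAsFactors = FALSE)
  sub <- read.csv(subjects_file, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_years", "channel", "value", "censored")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observations file lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  val <- suppressWarnings(as.numeric(obs$value))
  bad <- which(!(obs$channel %in% adpm_channels()) |
                 (is.na(val) & obs$censored != 1) |
                 duplicated(obs[c("subject_id", "time_years", "channel")]))
  if (length(bad)) {
    message(sprintf("read_cohort: rejected %d malformed row(s): lines %s",
                    length(bad),
                    paste(head(bad + 1L), collapse = ", ")))
    obs <- obs[-bad, , drop = FALSE]
  }
  obs$value <- suppressWarnings(as.numeric(obs$value))
  adpm_cohort(sub, obs, dg, config,
              metadata = list(
                source = c(observations_file, diagnoses_file, subjects_file),
                rejected_rows = bad))
}

#' Write a cohort to CSV files
#'
#' @param cohort An `adpm_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(observations = file.path(dir, "observations.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"),
             subjects = file.path(dir, "subjects.csv"))
  fmt <- function(df) {   # 17 significant digits: doubles round-trip exactly
    for (cl in names(df))
      if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
    df
  }
  write.csv(fmt(cohort$observations), paths["observations"],
            row.names = FALSE, quote = FALSE)
  dg <- cohort$diagnoses
  dg$label <- as.character(dg$label)
  write.csv(fmt(dg), paths["diagnoses"], row.names = FALSE, quote = FALSE)
  write.csv(fmt(cohort$subjects), paths["subjects"], row.names = FALSE,
            quote = FALSE)
  invisible(paths)
}
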