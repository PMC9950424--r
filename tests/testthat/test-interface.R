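test_that("write/read round-trips a cohort exactly", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(file.path(dir, "observations.csv"),
                      file.path(dir, "diagnoses.csv"),
                      file.path(dir, "subjects.csv"), co$config)
  expect_identical(back$observations$value, co$observations$value)
  expect_identical(back$observations$time_years, co$observations$time_years)
  expect_equal(back$observations$channel, co$observations$channel)
  expect_equal(as.character(back$diagnoses$label),
               as.character(co$diagnoses$label))
  expect_identical(back$subjects$age, co$subjects$age)
})

test_that("malformed rows are rejected with a report, not an abort", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  obs_file <- file.path(dir, "observations.csv")
  lines <- readLines(obs_file)
  bad <- paste(co$subjects$subject_id[1], "0.25", "notachannel", "1.0",
               "0", sep = ",")
  writeLines(c(lines[1], bad, lines[-1]), obs_file)
  expect_message(
    back <- read_cohort(obs_file, file.path(dir, "diagnoses.csv"),
                        file.path(dir, "subjects.csv"), co$config),
    "rejected 1")
  expect_equal(nrow(back$observations), nrow(co$observations))
  expect_equal(back$metadata$rejected_rows, 1L)
})

test_that("missing required columns are a hard error", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  obs <- read.csv(file.path(dir, "observations.csv"))
  write.csv(obs[, setdiff(names(obs), "channel")],
            file.path(dir, "observations.csv"), row.names = FALSE)
  expect_error(read_cohort(file.path(dir, "observations.csv"),
                           file.path(dir, "diagnoses.csv"),
                           file.path(dir, "subjects.csv"), co$config),
               "channel")
})

test_that("cohort validation catches structural problems", {
  co <- tiny_cohort()
  bad_obs <- co$observations
  bad_obs$subject_id[1] <- "ghost"
  expect_error(adpm_cohort(co$subjects, bad_obs, co$diagnoses, co$config),
               "unknown subject")
  bad_obs2 <- co$observations
  bad_obs2$censored[bad_obs2$channel == "mem"][1] <- 1
  expect_error(adpm_cohort(co$subjects, bad_obs2, co$diagnoses, co$config),
               "censor")
  expect_error(adpm_cohort(co$subjects[, -3], co$observations,
                           co$diagnoses, co$config), "lacks column")
})

test_that("times are re-anchored to each subject's first record", {
  cfg <- adpm_config()
  sub <- data.frame(subject_id = c("a", "b"), site_id = "s", age = 70,
                    apoe4 = 0)
  obs <- data.frame(subject_id = c("a", "a", "b"),
                    time_years = c(2.5, 4, 1), channel = "tau",
                    value = c(200, 250, 300), censored = 0L)
  dg <- data.frame(subject_id = "b", time_years = 0.5, label = "MCI")
  co <- adpm_cohort(sub, obs, dg, cfg)
  expect_equal(co$observations$time_years, c(0, 1.5, 0.5))
  expect_equal(co$diagnoses$time_years, 0)
})

test_that("configs round-trip through YAML", {
  cfg <- adpm_config(estimate_links = TRUE,
                     mcmc = list(iter = 123, seed = 99))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- adpm_config(file = f)
  expect_equal(back$mcmc$iter, 123)
  expect_equal(back$mcmc$seed, 99)
  expect_true(back$estimate_links)
  expect_equal(back$links$abeta$upper, cfg$links$abeta$upper)
  expect_equal(back$censoring$abeta$upper, 1700)
})

test_that("the command-line driver simulates and reports failures", {
  cli <- system.file("cli", "adpm.R", package = "adpm")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  out <- system2("Rscript",
                 c(cli, "simulate", "--out", file.path(dir, "sim"),
                   "--subjects", "8", "--sites", "2", "--seed", "4"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "sim", "observations.csv")))
  expect_true(file.exists(file.path(dir, "sim", "run_info.json")))
  # same seed twice: identical artifacts
  system2("Rscript",
          c(cli, "simulate", "--out", file.path(dir, "sim2"),
            "--subjects", "8", "--sites", "2", "--seed", "4"),
          stdout = TRUE, stderr = TRUE)
  expect_identical(readLines(file.path(dir, "sim", "observations.csv")),
                   readLines(file.path(dir, "sim2", "observations.csv")))
  # predict without a fit: explicit dependency error, non-zero exit
  status <- suppressWarnings(
    system2("Rscript",
            c(cli, "predict", "--data", file.path(dir, "sim"),
              "--fit", file.path(dir, "nofit"), "--out",
              file.path(dir, "pred")),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(status, "status")))
  expect_true(any(grepl("fit.rds", status)))
})
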