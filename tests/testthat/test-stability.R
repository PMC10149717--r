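test_that("switching degree follows the distinct-cluster rule", {
  expect_equal(switching_degree(c(1, 1, 1)), 0)
  expect_equal(switching_degree(c(1, 2, 1)), 1)
  expect_equal(switching_degree(c(1, 2, 3, 1), mode = "stool"), 2)
  expect_equal(switching_degree(c(1, 2, 3, 4), mode = "stool"), 2)  # "3 or more"
  expect_equal(switching_degree(c(2, 3, 2), mode = "milk"), 1)
  expect_error(switching_degree(1), ">= 2")
  # invariance under relabeling of the cluster alphabet
  withr::with_seed(4, {
    for (i in 1:20) {
      labs <- sample(1:4, 5, replace = TRUE)
      perm <- sample(4)
      expect_equal(switching_degree(labs), switching_degree(perm[labs]))
    }
  })
})

test_that("switching records exclude short series and 12-month stool samples", {
  meta <- tiny_meta()
  labels <- c(s1 = 1, s2 = 2, s3 = 2)
  rec <- switching_records(labels, meta, mode = "stool")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$degree, 1)
  expect_equal(rec$n_samples, 3)
  expect_equal(rec$last_sample_age_days, 180)

  # 12m exclusion: a 12m sample does not count toward stool stability
  meta12 <- tiny_meta()
  meta12$timepoint[5] <- "12m"; meta12$age_days[5] <- 365
  rec12 <- switching_records(c(s1 = 1, s2 = 1, s3 = 2), meta12, mode = "stool")
  expect_equal(rec12$degree, 0)
  expect_equal(rec12$n_samples, 2)
  # ... but milk mode keeps all timepoints
  recm <- switching_records(c(m1 = 1, m2 = 2), meta12, mode = "milk")
  expect_equal(recm$degree, 1)

  expect_error(suppressMessages(
    switching_records(c(s1 = 1), meta[3, , drop = FALSE], mode = "stool")))
})

test_that("persistent archetypes yield degree 0 for every subject", {
  cfg <- cohort_sim_config(n_dyads = 12, n_asvs = 60,
                           timepoints = c("6w", "4m", "6m", "9m"),
                           timepoint_probs = c("6w" = 1, "4m" = 1, "6m" = 1,
                                               "9m" = 1),
                           archetype_switch_prob = 0,
                           dirichlet_concentration = 500,
                           depth_log_mean = log(20000), depth_log_sd = 0.3,
                           seed = 17)
  co <- simulate_cohort(cfg)
  D <- gunifrac(co$milk_table, co$tree)
  fit <- pam_cluster(D, 3)
  rec <- switching_records(fit$labels, co$metadata, mode = "milk")
  expect_true(all(rec$degree == 0))
})

test_that("within-subject distances are smaller than between for persistent subjects", {
  cfg <- cohort_sim_config(n_dyads = 25, n_asvs = 60,
                           timepoints = c("6w", "4m", "6m"),
                           timepoint_probs = c("6w" = 1, "4m" = 1, "6m" = 1),
                           archetype_switch_prob = 0,
                           depth_log_mean = log(20000), depth_log_sd = 0.3,
                           seed = 23)
  co <- simulate_cohort(cfg)
  D <- gunifrac(co$milk_table, co$tree)
  subj <- co$metadata$dyad_id[match(rownames(D), co$metadata$sample_id)]
  wb <- within_between_distance_test(D, subj)
  expect_lt(wb$median_within, wb$median_between)
  expect_lt(wb$p, 0.01)

  # all-identical samples: H = 0
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  wb0 <- within_between_distance_test(Z, c("a", "a", "b", "b"))
  expect_equal(wb0$H, 0)
  expect_error(within_between_distance_test(Z, c("a", "b", "c", "d")),
               "within")
})

test_that("permuted subject labels give a calibrated within/between test", {
  co <- simulate_cohort(cohort_sim_config(
    n_dyads = 20, n_asvs = 50, timepoints = c("6w", "4m"),
    timepoint_probs = c("6w" = 1, "4m" = 1), archetype_switch_prob = 0,
    depth_log_mean = log(10000), depth_log_sd = 0.3, seed = 29))
  D <- gunifrac(co$milk_table, co$tree)
  subj <- co$metadata$dyad_id[match(rownames(D), co$metadata$sample_id)]
  ps <- vapply(1:60, function(i) {
    within_between_distance_test(D, withr::with_seed(i, sample(subj)))$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps < 0.05), 0.20)  # close to nominal under the null
})

test_that("predictor screening applies the continuous/categorical rule", {
  withr::with_seed(61, {
    rec <- data.frame(degree = rep(0:2, each = 20),
                      assoc_num = rep(0:2, each = 20) + rnorm(60, 0, 0.3),
                      null_num = rnorm(60),
                      assoc_cat = ifelse(rep(0:2, each = 20) > 0, "y", "n"),
                      null_cat = sample(c("y", "n"), 60, replace = TRUE))
  })
  sc <- screen_switching_predictors(rec, c("assoc_num", "null_num",
                                           "assoc_cat", "null_cat"))
  expect_true(sc$retained[sc$predictor == "assoc_num"])
  expect_true(sc$retained[sc$predictor == "assoc_cat"])
  expect_false(sc$retained[sc$predictor == "null_num"])
})

test_that("multinomial switching model is a faithful MLE and flags problems", {
  # intercept-only: predicted category probabilities = observed frequencies
  withr::with_seed(71, {
    rec <- data.frame(degree = sample(0:2, 90, replace = TRUE,
                                      prob = c(.5, .3, .2)),
                      x = rnorm(90), last_sample_age_days = runif(90, 200, 400))
  })
  fit <- nnet::multinom(factor(degree) ~ 1, data = rec, trace = FALSE)
  expect_equal(unname(colMeans(stats::fitted(fit))),
               as.numeric(table(rec$degree) / nrow(rec)), tolerance = 1e-4)

  # planted effect: antibiotics double the switching odds
  hits <- 0L
  for (seed in 1:20) {
    withr::with_seed(seed + 900, {
      n <- 300
      abx <- sample(c("yes", "no"), n, replace = TRUE)
      lin <- ifelse(abx == "yes", log(3), 0)
      pr1 <- exp(lin) / (1 + exp(lin) + exp(lin - 0.5))
      pr2 <- exp(lin - 0.5) / (1 + exp(lin) + exp(lin - 0.5))
      u <- runif(n)
      deg <- ifelse(u < pr1, 1, ifelse(u < pr1 + pr2, 2, 0))
      rec2 <- data.frame(degree = deg, prenatal_antibiotics = abx,
                         last_sample_age_days = runif(n, 200, 400))
    })
    m <- multinomial_switching_model(rec2, "prenatal_antibiotics")
    co <- m$coefficients
    row <- co[co$degree == "1" & grepl("antibiotics", co$term), ]
    if (row$or > 1 && row$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 16)  # >= 80% power at this planted effect

  rec3 <- data.frame(degree = rep(0:1, 10), constant = "x",
                     last_sample_age_days = runif(20, 200, 400))
  expect_error(suppressWarnings(multinomial_switching_model(rec3, "constant")),
               "constant")
})

test_that("separation is reported with an instability flag, not hidden", {
  withr::with_seed(81, {
    rec <- data.frame(degree = rep(c(0, 1), each = 15),
                      sep = rep(c("a", "b"), each = 15),
                      last_sample_age_days = runif(30, 200, 400))
  })
  fit <- suppressWarnings(multinomial_switching_model(rec, "sep"))
  expect_true(any(fit$coefficients$unstable[grepl("sep", fit$coefficients$term)]))
})
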