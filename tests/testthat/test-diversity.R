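test_that("relative abundance normalizes rows and flags empty samples", {
  expect_equal(relative_abundance(c(5, 5)), c(0.5, 0.5))
  expect_equal(relative_abundance(c(10, 0, 0)), c(1, 0, 0))
  expect_equal(relative_abundance(c(1, 2, 3)), c(1, 2, 3) / 6)
  m <- rbind(a = c(1, 1), b = c(0, 0)); colnames(m) <- c("x", "y")
  expect_error(relative_abundance(m), "b")
})

test_that("taxon aggregation conserves reads and pools unmapped ASVs", {
  counts <- matrix(c(3L, 7L, 2L), 1, dimnames = list("s1", c("a1", "a2", "a3")))
  tax <- data.frame(asv_id = c("a1", "a2", "a3"),
                    genus = c("Streptococcus", "Streptococcus", "Veillonella"),
                    family = c("Streptococcaceae", "Streptococcaceae",
                               "Veillonellaceae"))
  agg <- aggregate_by_taxon(counts, tax, "genus")
  expect_equal(agg[1, "Streptococcus"], 10)
  expect_equal(rowSums(agg), rowSums(counts))

  # all-distinct genera: identity up to relabeling
  tax2 <- data.frame(asv_id = c("a1", "a2", "a3"), genus = c("g1", "g2", "g3"),
                     family = "f")
  agg2 <- aggregate_by_taxon(counts, tax2, "genus")
  expect_equal(sort(as.vector(agg2)), sort(as.vector(counts)))

  # unmapped ASV pooled under the sentinel, totals conserved
  expect_warning(agg3 <- aggregate_by_taxon(counts, tax2[1:2, ], "genus"),
                 "unassigned")
  expect_equal(agg3[1, "unassigned"], 2)
  expect_equal(rowSums(agg3), rowSums(counts))
})

test_that("alpha diversity matches closed forms (incl. the logit sentinel)", {
  d <- alpha_diversity(c(5, 5))
  expect_equal(d$sdi, 0.5)
  expect_equal(d$shdi, log(2))
  expect_equal(d$observed_asvs, 2L)
  expect_equal(d$logit_sdi, 0)

  d4 <- alpha_diversity(c(7, 7, 7, 7))
  expect_equal(d4$sdi, 0.75)
  expect_equal(d4$shdi, log(4))
  expect_equal(d4$observed_asvs, 4L)

  d1 <- alpha_diversity(c(0, 9, 0))
  expect_equal(d1$sdi, 0)
  expect_equal(d1$shdi, 0)
  expect_equal(d1$observed_asvs, 1L)
  expect_equal(d1$logit_sdi, -Inf)

  # vegan cross-check on random profiles + scale invariance
  withr::with_seed(8, {
    for (i in 1:5) {
      x <- rpois(20, 5) + 1
      d <- alpha_diversity(x)
      expect_equal(d$shdi, unname(vegan::diversity(x, "shannon")))
      expect_equal(d$sdi, unname(vegan::diversity(x, "simpson")))
      d7 <- alpha_diversity(7L * x)
      expect_equal(d$sdi, d7$sdi)
      expect_equal(d$shdi, d7$shdi)
    }
  })
})

test_that("logit transform inverts the logistic function", {
  x <- seq(0.01, 0.99, by = 0.07)
  lg <- alpha_diversity(rbind(cbind(x, 1 - x)))  # sdi of 2-taxon profile
  p <- 1 / (1 + exp(-lg$logit_sdi))
  expect_equal(p, lg$sdi, tolerance = 1e-12)
})

test_that("rarefaction is exact at full depth and hypergeometric in law", {
  x <- c(A = 3L, B = 2L, C = 5L)
  expect_identical(rarefy_counts(x, 10, seed = 1), x)
  expect_equal(rarefy_counts(c(A = 1000L, B = 0L), 10, seed = 1),
               c(A = 10L, B = 0L))
  expect_error(rarefy_counts(x, 11), "depth")
  expect_identical(rarefy_counts(x, 5, seed = 42), rarefy_counts(x, 5, seed = 42))

  # moments vs hypergeometric at counts (500, 500), depth 100
  reps <- vapply(1:2000, function(i) rarefy_counts(c(500L, 500L), 100,
                                                   seed = i)[1], numeric(1))
  m <- 100 * 500 / 1000
  v <- 100 * 0.5 * 0.5 * (1000 - 100) / (1000 - 1)
  expect_lt(abs(mean(reps) - m), 3 * sqrt(v / 2000))
  expect_equal(stats::var(reps), v, tolerance = 0.15)
})

test_that("observed richness is non-decreasing in rarefaction depth (in expectation)", {
  x <- withr::with_seed(2, stats::rpois(50, 2))
  names(x) <- paste0("t", seq_along(x))
  obs_at <- function(depth) mean(vapply(1:100, function(i) {
    sum(rarefy_counts(x, depth, seed = i) > 0)
  }, numeric(1)))
  expect_lt(obs_at(10), obs_at(40))
  expect_lt(obs_at(40), obs_at(80))
})

test_that("most abundant taxon uses the lexicographic tie rule", {
  expect_equal(most_abundant_taxon(c(Streptococcus = .6, Staphylococcus = .4)),
               "Streptococcus")
  expect_warning(top <- most_abundant_taxon(c(b = .5, a = .5)), "tie")
  expect_equal(top, "a")
  expect_equal(most_abundant_taxon(c(only = 1)), "only")
  expect_error(most_abundant_taxon(numeric(0)), "nonempty")
})

test_that("diversity-age model recovers a planted slope and handles edge cases", {
  # constant metric: zero slope, p ~ 1
  fit0 <- suppressWarnings(diversity_age_model(rep(1.5, 30), rep(1:10, 3),
                                               rep(1:3, each = 10)))
  expect_equal(fit0$slope_per_100d, 0, tolerance = 1e-10)
  expect_gt(fit0$p, 0.9)

  # two subjects on parallel perfect lines of slope 1/day
  age <- c(0, 10, 20, 0, 10, 20)
  y <- c(0, 10, 20, 5, 15, 25)
  fit1 <- suppressWarnings(diversity_age_model(y, age, rep(1:2, each = 3)))
  expect_equal(fit1$slope_per_100d, 100, tolerance = 1e-6)

  # parameter recovery: logit_sdi = 0.47 (age/100) + subject + noise
  hits <- 0L
  for (seed in 1:100) {
    withr::with_seed(seed, {
      n_sub <- 150
      b <- rnorm(n_sub, 0, 0.5)
      age <- rep(c(42, 180, 365), n_sub)
      subj <- rep(seq_len(n_sub), each = 3)
      y <- 0.47 * age / 100 + b[subj] + rnorm(length(age), 0, 0.3)
    })
    fit <- diversity_age_model(y, age, subj)
    if (fit$ci[1] <= 0.47 && 0.47 <= fit$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})
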