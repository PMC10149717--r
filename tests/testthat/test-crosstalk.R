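test_that("Fisher enumeration matches hand hypergeometrics and the reference", {
  res <- fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2), method = "enumerate")
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)
  expect_equal(res$total_prob, 1, tolerance = 1e-9)
  expect_equal(res$n_tables, 5)  # a = 0..4

  # identical rows: exact independence, p = 1
  expect_equal(fisher_exact_rxc(matrix(c(4, 4, 2, 2), 2, byrow = TRUE),
                                method = "enumerate")$p, 1)
  # 2x2 diagonal singleton table
  expect_equal(fisher_exact_rxc(diag(2), method = "enumerate")$p, 1)

  # r x c agreement with stats::fisher.test on random small tables
  withr::with_seed(5, {
    for (i in 1:20) {
      tab <- matrix(rpois(6, 3) + 1, 2, 3)
      mine <- fisher_exact_rxc(tab, method = "enumerate")
      expect_equal(mine$total_prob, 1, tolerance = 1e-9)
      expect_equal(mine$p, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
    }
  })
  expect_error(fisher_exact_rxc(matrix(c(1, 0, 2, 0), 2)), "margin")
})

test_that("Fisher Monte Carlo agrees with enumeration within 3 SE", {
  withr::with_seed(6, tab <- matrix(rpois(12, 2) + 1, 3, 4))
  en <- fisher_exact_rxc(tab, method = "enumerate")
  mc <- fisher_exact_rxc(tab, method = "monte_carlo", n_sim = 1e5, seed = 2)
  se <- sqrt(en$p * (1 - en$p) / 1e5)
  expect_lt(abs(mc$p - en$p), 3 * se)
  # auto switches to Monte Carlo above the enumeration budget
  big <- matrix(50, 4, 4)
  expect_equal(fisher_exact_rxc(big, method = "auto", n_sim = 100,
                                max_tables = 1000)$method, "monte_carlo")
})

test_that("type association respects the minimum-dyads rule and strata", {
  milk <- setNames(rep(1:2, each = 10), paste0("d", 1:20))
  stool <- setNames(rep(1:2, 10), paste0("d", 1:20))
  res <- type_association(milk, stool, min_dyads = 10)
  expect_true(res$overall$p >= 0 && res$overall$p <= 1)
  expect_equal(sum(res$overall$table), 20)

  expect_message(res9 <- type_association(milk[1:9], stool[1:9], min_dyads = 10),
                 "skipping")
  expect_null(res9$overall)

  strata <- setNames(rep(c("v", "c"), c(12, 8)), paste0("d", 1:20))
  expect_message(res_s <- type_association(milk, stool, strata = strata,
                                           min_dyads = 10), "skipping c")
  expect_named(res_s$strata, "v")
  expect_equal(res_s$skipped, "c")
})

test_that("coupled types are detected; independent types are calibrated", {
  # power: milk type determines stool type with 0.9 fidelity
  withr::with_seed(7, {
    milk <- sample(1:3, 120, replace = TRUE)
    stool <- ifelse(runif(120) < 0.9, milk, sample(1:3, 120, replace = TRUE))
  })
  names(milk) <- names(stool) <- paste0("d", 1:120)
  expect_lt(type_association(milk, stool)$overall$p, 0.001)

  # calibration: independent labels, p approximately uniform
  ps <- vapply(1:60, function(seed) {
    withr::with_seed(seed + 100, {
      m <- setNames(sample(1:2, 40, replace = TRUE), paste0("d", 1:40))
      s <- setNames(sample(1:2, 40, replace = TRUE), paste0("d", 1:40))
    })
    p <- type_association(m, s)$overall$p
    if (is.null(p)) NA_real_ else p
  }, numeric(1))
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.12)
})

test_that("covariate distance is Euclidean over coded covariates", {
  meta <- data.frame(formula_exposed = c("no", "no"),
                     delivery_mode = c("vaginal", "vaginal"),
                     maternal_bmi = c(24, 24), maternal_age = c(30, 30),
                     prenatal_antibiotics = c("no", "no"),
                     infant_sex = c("male", "male"),
                     row.names = c("d1", "d2"))
  D <- suppressWarnings(covariate_distance(rbind(meta,
    data.frame(formula_exposed = "no", delivery_mode = "cesarean",
               maternal_bmi = 24, maternal_age = 30,
               prenatal_antibiotics = "no", infant_sex = "male",
               row.names = "d3"))))
  expect_equal(D["d1", "d2"], 0)
  expect_equal(D["d1", "d3"], 1)  # one binary indicator apart
  expect_warning(covariate_distance(data.frame(a = c(1, 1, 1), b = c(1, 2, 3),
                                               row.names = paste0("d", 1:3)),
                                    covariates = c("a", "b")), "dropped")

  # standardized continuous covariates: two columns, Euclidean combination
  meta2 <- data.frame(a = c(0, 3, 1, -1), b = c(0, 4, 2, -2),
                      row.names = paste0("d", 1:4))
  za <- scale(meta2$a); zb <- scale(meta2$b)
  D2 <- covariate_distance(meta2, covariates = c("a", "b"))
  expect_equal(D2["d1", "d2"],
               sqrt((za[2] - za[1])^2 + (zb[2] - zb[1])^2), tolerance = 1e-12)
  expect_error(covariate_distance(meta2, covariates = "zz"), "not found")
})

test_that("Mantel test has the exact self-correlation and affine properties", {
  pts <- withr::with_seed(3, matrix(rnorm(24), 12))
  D <- as.matrix(dist(pts)); dimnames(D) <- list(paste0("d", 1:12), paste0("d", 1:12))
  self <- mantel_test(D, D, n_perm = 199, seed = 1)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$p, 1 / 200)

  aff <- mantel_test(D, 2 * D + 0.3 * (D > 0), n_perm = 99, seed = 1)
  expect_equal(aff$r, 1, tolerance = 1e-6)
  expect_error(mantel_test(D, D[c(2, 1, 3:12), c(2, 1, 3:12)]), "mismatch")
})

test_that("partial Mantel removes a constructed confounder and degrades gracefully", {
  withr::with_seed(13, {
    z <- matrix(rnorm(30), 15)
    Dz <- as.matrix(dist(z))
    # x and y both driven by the confounder z plus small independent noise
    Dx <- as.matrix(dist(z + matrix(rnorm(30, sd = 0.1), 15)))
    Dy <- as.matrix(dist(z + matrix(rnorm(30, sd = 0.1), 15)))
  })
  ids <- paste0("d", 1:15)
  dimnames(Dz) <- dimnames(Dy) <- dimnames(Dx) <- list(ids, ids)
  plain <- mantel_test(Dx, Dy, n_perm = 199, seed = 5)
  part <- adjusted_mantel(Dx, Dy, Dz, n_perm = 199, seed = 5)
  expect_gt(plain$r, 0.8)
  expect_lt(abs(part$r), 0.35)  # confounding removed

  # constant Dz falls back to the plain test with identical r
  Dc <- matrix(1, 15, 15); diag(Dc) <- 0; dimnames(Dc) <- list(ids, ids)
  expect_warning(fb <- adjusted_mantel(Dx, Dy, Dc, n_perm = 199, seed = 5),
                 "constant")
  expect_equal(fb$r, plain$r, tolerance = 1e-12)

  # an unrelated third matrix barely changes the correlation
  withr::with_seed(14, Du <- as.matrix(dist(matrix(rnorm(30), 15))))
  dimnames(Du) <- list(ids, ids)
  pu <- adjusted_mantel(Dx, Dy, Du, n_perm = 99, seed = 5)
  expect_lt(abs(pu$r - plain$r), 0.1)
})

test_that("prevalence/abundance filter is strict at both boundaries", {
  rel <- matrix(0.001, 20, 3, dimnames = list(paste0("s", 1:20), c("t1", "t2", "t3")))
  rel[1:2, 1] <- 0.01   # exactly 10% of subjects above: removed
  rel[1:3, 2] <- 0.01   # 15%: kept
  rel[, 3] <- 0.005     # exactly at the abundance boundary: removed
  expect_equal(filter_prevalent_asvs(rel), "t2")
  expect_error(filter_prevalent_asvs(rel[0, , drop = FALSE]), "empty")
})

test_that("BH q-values match the hand computation and are monotone", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qvalues(0.37), 0.37)
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  expect_identical(qvalues(numeric(0)), numeric(0))
  withr::with_seed(15, p <- runif(50)^2)
  q <- qvalues(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")

  # Storey variant: BH scaled by the estimated null proportion
  qs <- qvalues(p, method = "storey")
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  expect_equal(qs, pmin(1, pi0 * q))
  expect_true(all(qs <= q + 1e-15))
})

test_that("taxa correlation screen finds planted pairs and is rank-invariant", {
  withr::with_seed(16, {
    n <- 100
    milk <- matrix(runif(n * 4, 0, 0.3), n,
                   dimnames = list(paste0("d", 1:n), paste0("M", 1:4)))
    stool <- matrix(runif(n * 4, 0, 0.3), n,
                    dimnames = list(paste0("d", 1:n), paste0("S", 1:4)))
    stool[, 1] <- 0.05 + 0.8 * milk[, 2] + runif(n, 0, 0.05)  # planted pair
  })
  tc <- taxa_correlations(milk, stool)
  planted <- tc$results[tc$results$milk_taxon == "M2" &
                          tc$results$stool_taxon == "S1", ]
  expect_true(planted$significant)
  null_rows <- tc$results[!(tc$results$milk_taxon == "M2" &
                              tc$results$stool_taxon == "S1"), ]
  expect_lte(mean(null_rows$significant), 0.10)
  expect_equal(planted$rho,
               unname(cor(milk[, "M2"], stool[, "S1"], method = "spearman")))

  # center/scale invariance: Spearman is rank-based
  tc2 <- taxa_correlations(scale(milk), scale(stool))
  expect_equal(tc2$results$rho, tc$results$rho, tolerance = 1e-12)
  expect_equal(tc$mean_abs_rho, mean(abs(tc$results$rho)))

  # monotone pair: rho = 1
  m1 <- matrix(1:6 / 10, 6, 1, dimnames = list(paste0("d", 1:6), "M"))
  s1 <- matrix((1:6)^2 / 100, 6, 1, dimnames = list(paste0("d", 1:6), "S"))
  expect_equal(taxa_correlations(m1, s1)$results$rho, 1)

  # constant taxon vectors are skipped with a message
  milk_c <- milk; milk_c[, 3] <- 0.1
  expect_message(tc3 <- taxa_correlations(milk_c, stool), "constant")
  expect_false(any(tc3$results$milk_taxon == "M3"))
})
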