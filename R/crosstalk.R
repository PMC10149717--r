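log_table_prob <- function(tab, const) {
  # multivariate hypergeometric probability of a margin-fixed table:
  # prod(r_i!) prod(c_j!) / (N! prod(t_ij!)), on the log scale
  const - sum(lgamma(tab + 1))
}

enumerate_tables <- function(row_sums, col_sums, fun) {
  # visit every non-negative integer matrix with the given margins,
  # filling cells row-wise; last row/column entries are forced
  r <- length(row_sums); c <- length(col_sums)
  tab <- matrix(0L, r, c)
  rec <- function(i, j, row_rem, col_rem) {
    if (i == r) {  # last row forced by column remainders
      if (any(col_rem < 0)) return(invisible())
      tab[r, ] <<- col_rem
      fun(tab)
      return(invisible())
    }
    if (j == c) {  # last cell of the row forced by the row remainder
      if (row_rem > col_rem[c]) return(invisible())
      tab[i, c] <<- row_rem
      col2 <- col_rem; col2[c] <- col2[c] - row_rem
      rec(i + 1, 1, row_sums[i + 1], col2)
      return(invisible())
    }
    hi <- min(row_rem, col_rem[j])
    for (v in 0:hi) {
      tab[i, j] <<- v
      col2 <- col_rem; col2[j] <- col2[j] - v
      rec(i, j + 1, row_rem - v, col2)
    }
    invisible()
  }
  rec(1, 1, row_sums[1], col_sums)
  invisible()
}

count_tables_bound <- function(row_sums, col_sums) {
  # upper bound on the number of margin-fixed tables: each row is a weak
  # composition of its sum into c parts
  c <- length(col_sums)
  exp(sum(lchoose(row_sums + c - 1, c - 1)))
}

#' Fisher's exact test for r x c contingency tables
#'
#' `method = "enumerate"`: full enumeration of all tables with the observed
#' margins; the p-value sums the multivariate hypergeometric probabilities
#' of tables no more probable than the observed one (two-sided,
#' probability-ordering rule). The enumeration also verifies that the table
#' probabilities sum to 1 (tolerance 1e-9). `method = "monte_carlo"`: tables
#' are drawn from the margin-fixed null (Patefield's algorithm via
#' [stats::r2dtable()]) and the p-value is the add-one estimator
#' `(n_sim * phat + 1) / (n_sim + 1)`. `method = "auto"` enumerates unless
#' the table count bound exceeds `max_tables`.
#'
#' @param tab non-negative integer matrix; all row and column margins must
#'   be positive (drop empty categories first).
#' @param method `"auto"`, `"enumerate"` or `"monte_carlo"`.
#' @param n_sim Monte-Carlo sample size.
#' @param seed integer seed (Monte Carlo only).
#' @param max_tables enumeration budget for `"auto"`.
#' @return list with `p`, `method`, and for enumeration `n_tables` and
#'   `total_prob` (the normalization check).
#' @export
fisher_exact_rxc <- function(tab, method = c("auto", "enumerate", "monte_carlo"),
                             n_sim = 10000, seed = 1, max_tables = 2e5) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("table must hold counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero margin; drop empty row/column categories first")
  }
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(tab) + 1)
  lp_obs <- log_table_prob(tab, const)
  if (method == "auto") {
    method <- if (count_tables_bound(rs, cs) <= max_tables) "enumerate" else "monte_carlo"
  }
  if (method == "enumerate") {
    acc <- new.env()
    acc$p <- 0; acc$tot <- 0; acc$n <- 0L
    tol <- lp_obs + 1e-7  # relative tolerance on the probability ordering
    enumerate_tables(rs, cs, function(t2) {
      lp <- log_table_prob(t2, const)
      pr <- exp(lp)
      acc$tot <- acc$tot + pr
      acc$n <- acc$n + 1L
      if (lp <= tol) acc$p <- acc$p + pr
    })
    if (abs(acc$tot - 1) > 1e-9) {
      stop(sprintf("enumeration failed normalization: sum P = %.12f", acc$tot))
    }
    list(p = min(1, acc$p), method = "enumerate", n_tables = acc$n,
         total_prob = acc$tot)
  } else {
    sims <- withr::with_seed(seed, stats::r2dtable(n_sim, rs, cs))
    hits <- vapply(sims, function(t2) log_table_prob(t2, const) <= lp_obs + 1e-7,
                   logical(1))
    list(p = (sum(hits) + 1) / (n_sim + 1), method = "monte_carlo",
         n_sim = n_sim)
  }
}

#' Association between milk and stool microbiome types
#'
#' Builds the milk-type x stool-type contingency table over dyads carrying
#' both labels and applies the exact test, overall and within optional
#' strata. A stratum (or the overall analysis) with fewer than `min_dyads`
#' dyads is skipped with a message, never silently dropped.
#'
#' @param milk_labels named milk type per dyad (names = dyad ids).
#' @param stool_labels named stool type per dyad.
#' @param strata optional named factor per dyad (e.g. delivery mode).
#' @param min_dyads minimum dyads per tested (sub)table (default 10).
#' @param ... passed to [fisher_exact_rxc()].
#' @return list with `overall` (`table`, `p`) and, when strata are given,
#'   `strata` (per-level results) and `skipped` (levels below threshold).
#' @export
type_association <- function(milk_labels, stool_labels, strata = NULL,
                             min_dyads = 10, ...) {
  dyads <- intersect(names(milk_labels), names(stool_labels))
  test_one <- function(ids, label) {
    if (length(ids) < min_dyads) {
      message("skipping ", label, ": ", length(ids), " dyads < ", min_dyads)
      return(NULL)
    }
    tab <- table(milk = as.character(milk_labels[ids]),
                 stool = as.character(stool_labels[ids]))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (any(dim(tab) < 2)) {
      message("skipping ", label, ": degenerate table")
      return(NULL)
    }
    c(list(table = tab), fisher_exact_rxc(tab, ...))
  }
  res <- list(overall = test_one(dyads, "overall"))
  if (!is.null(strata)) {
    lev <- unique(as.character(strata[dyads]))
    per <- lapply(lev, function(l) test_one(dyads[strata[dyads] == l], l))
    names(per) <- lev
    res$strata <- per[!vapply(per, is.null, logical(1))]
    res$skipped <- lev[vapply(per, is.null, logical(1))]
  }
  res
}

#' Euclidean covariate distance matrix between dyads
#'
#' Categorical covariates are binary-coded (one indicator per non-reference
#' level, missingness as its own level), continuous covariates standardized
#' to unit variance; the distance is plain Euclidean. Covariates without
#' variation are dropped with a warning.
#'
#' @param meta data.frame, one row per dyad, with rownames = dyad ids.
#' @param covariates columns to use (default: the confounder set used for
#'   the adjusted Mantel analysis).
#' @return validated distance matrix over dyads.
#' @export
covariate_distance <- function(meta,
                               covariates = c("formula_exposed", "delivery_mode",
                                              "maternal_bmi", "maternal_age",
                                              "prenatal_antibiotics", "infant_sex")) {
  cols <- list()
  for (v in covariates) {
    x <- meta[[v]]
    if (is.null(x)) stop("covariate not found: ", v)
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("covariate without variation dropped: ", v)
      next
    }
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(scale(x))
    } else {
      f <- factor(x)
      for (l in levels(f)[-1]) cols[[paste(v, l, sep = ".")]] <- as.numeric(f == l)
    }
  }
  if (!length(cols)) stop("no usable covariates")
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(meta)
  D <- as.matrix(stats::dist(X))
  diag(D) <- 0
  validate_distance_matrix(D)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal dissimilarities, with a
#' one-sided (greater) permutation p-value: rows/columns of `Dy` are
#' permuted jointly and `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param Dx,Dy validated distance matrices over the same ids, in the same
#'   order.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `mantel_result` with `r` (echoed as `z_statistic`),
#'   `p`, `n_perm`, `n`.
#' @export
mantel_test <- function(Dx, Dy, n_perm = 10000, seed = 1) {
  validate_distance_matrix(Dx); validate_distance_matrix(Dy)
  if (!identical(rownames(Dx), rownames(Dy))) stop("mismatched ids between matrices")
  if (nrow(Dx) < 3) stop("Mantel test needs n >= 3")
  fit <- withr::with_seed(seed, {
    vegan::mantel(stats::as.dist(Dx), stats::as.dist(Dy),
                  method = "pearson", permutations = n_perm)
  })
  structure(list(r = unname(fit$statistic), z_statistic = unname(fit$statistic),
                 p = fit$signif, n_perm = n_perm, n = nrow(Dx)),
            class = "mantel_result")
}

#' Partial Mantel test adjusting for a covariate distance matrix
#'
#' Partial correlation of `Dx` and `Dy` given `Dz` over the off-diagonal
#' entries, permutation scheme as in [mantel_test()]. A constant `Dz`
#' carries no information; the test then falls back to the plain Mantel
#' test with a warning.
#'
#' @param Dx,Dy,Dz validated distance matrices over the same ids.
#' @inheritParams mantel_test
#' @return `mantel_result` (with `adjusted = TRUE` unless it fell back).
#' @export
adjusted_mantel <- function(Dx, Dy, Dz, n_perm = 10000, seed = 1) {
  validate_distance_matrix(Dz)
  if (!identical(rownames(Dx), rownames(Dz))) stop("mismatched ids between matrices")
  zv <- Dz[upper.tri(Dz)]
  if (stats::sd(zv) == 0) {
    warning("constant covariate distances; plain Mantel test used")
    res <- mantel_test(Dx, Dy, n_perm = n_perm, seed = seed)
    res$adjusted <- FALSE
    return(res)
  }
  fit <- withr::with_seed(seed, {
    vegan::mantel.partial(stats::as.dist(Dx), stats::as.dist(Dy),
                          stats::as.dist(Dz), method = "pearson",
                          permutations = n_perm)
  })
  structure(list(r = unname(fit$statistic), z_statistic = unname(fit$statistic),
                 p = fit$signif, n_perm = n_perm, n = nrow(Dx), adjusted = TRUE),
            class = "mantel_result")
}

#' Prevalence/abundance filter for the correlation screen
#'
#' Within one (sample type, timepoint) group, a taxon is kept iff strictly
#' more than `prevalence` of subjects have relative abundance strictly
#' greater than `abundance` (both inequalities strict: a taxon at exactly
#' the boundary is removed).
#'
#' @param rel samples x taxa relative-abundance matrix for one group.
#' @param prevalence subject-fraction threshold (default 0.10).
#' @param abundance relative-abundance threshold (default 0.005).
#' @return character vector of retained taxon ids.
#' @export
filter_prevalent_asvs <- function(rel, prevalence = 0.10, abundance = 0.005) {
  if (!nrow(rel)) stop("empty group")
  frac <- colMeans(rel > abundance)
  colnames(rel)[frac > prevalence]
}

#' False-discovery-rate q-values
#'
#' `"bh"` (default): Benjamini-Hochberg step-up adjusted values with
#' monotonicity enforcement, `q >= p` elementwise. `"storey"`: the BH
#' values scaled by the null-proportion estimate
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))` at `lambda = 0.5`
#' (Storey q-values are never larger than BH ones).
#'
#' @param pvals p-values in \[0, 1\].
#' @param method `"bh"` or `"storey"`.
#' @param lambda tuning parameter of the Storey pi0 estimate.
#' @return q-values aligned with `pvals`.
#' @export
qvalues <- function(pvals, method = c("bh", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(pvals > lambda, na.rm = TRUE) / (1 - lambda))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Milk-stool taxa correlation screen
#'
#' Spearman correlation between every (milk taxon, stool taxon) pair across
#' dyads at one timepoint pair, after the prevalence/abundance filter has
#' been applied to each side. Mean-centering/scaling of relative abundances
#' leaves every rank-based correlation unchanged, so it is not repeated
#' here. Q-values are computed over the pair's whole test family; pairs
#' with a constant vector on either side are skipped (with a message).
#'
#' @param milk_rel dyads x milk-taxa relative abundances (rows = dyad ids).
#' @param stool_rel dyads x stool-taxa relative abundances, same row order.
#' @param q_threshold significance flag threshold (default 0.1).
#' @return list with `results` (milk_taxon, stool_taxon, rho, p, q,
#'   significant), `mean_abs_rho`, `n_dyads`, `n_skipped`.
#' @export
taxa_correlations <- function(milk_rel, stool_rel, q_threshold = 0.1) {
  if (!identical(rownames(milk_rel), rownames(stool_rel))) {
    stop("milk and stool tables must be over the same dyads, in order")
  }
  if (nrow(milk_rel) < 5) stop("need >= 5 dyads")
  const_m <- apply(milk_rel, 2, function(x) stats::sd(x) == 0)
  const_s <- apply(stool_rel, 2, function(x) stats::sd(x) == 0)
  n_skipped <- sum(const_m) * ncol(stool_rel) +
    sum(const_s) * ncol(milk_rel) - sum(const_m) * sum(const_s)
  if (any(const_m) || any(const_s)) {
    message("skipping pairs involving constant taxa (",
            sum(const_m), " milk, ", sum(const_s), " stool)")
  }
  mm <- milk_rel[, !const_m, drop = FALSE]
  ss <- stool_rel[, !const_s, drop = FALSE]
  grid <- expand.grid(m = colnames(mm), s = colnames(ss),
                      stringsAsFactors = FALSE)
  rho <- numeric(nrow(grid)); p <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ct <- suppressWarnings(stats::cor.test(mm[, grid$m[i]], ss[, grid$s[i]],
                                           method = "spearman", exact = FALSE))
    rho[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  q <- qvalues(p)
  res <- data.frame(milk_taxon = grid$m, stool_taxon = grid$s, rho = rho,
                    p = p, q = q, significant = q < q_threshold,
                    stringsAsFactors = FALSE)
  list(results = res, mean_abs_rho = mean(abs(rho)), n_dyads = nrow(milk_rel),
       n_skipped = n_skipped)
}
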