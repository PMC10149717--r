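#' Cluster-switching degree of one subject
#'
#' Degree 0: all of the subject's samples fall in one cluster; degree 1:
#' samples span two clusters; degree 2: three clusters (milk, where three
#' types is the maximum) or three **or more** (stool). The score depends
#' only on the set of distinct labels, not on the order of switches.
#'
#' @param labels cluster labels of one subject's samples, in any order.
#' @param mode `"milk"` or `"stool"` (same rule; documented separately
#'   because milk caps at three types).
#' @return integer degree in `{0, 1, 2}`.
#' @export
switching_degree <- function(labels, mode = c("stool", "milk")) {
  mode <- match.arg(mode)
  if (length(labels) < 2) stop("switching degree needs >= 2 samples")
  min(length(unique(labels)) - 1L, 2L)
}

#' Per-subject switching records from a cluster assignment
#'
#' Subjects with fewer than 2 samples are excluded (with a message). The
#' age of the subject's last sample is carried along as the timing
#' adjustment variable for the multinomial model; the covariate snapshot is
#' taken from the subject's first metadata row.
#'
#' @param labels named cluster labels (names = sample ids).
#' @param meta validated metadata for the labeled samples.
#' @param mode `"milk"` or `"stool"`.
#' @param exclude_timepoints visit codes dropped before scoring (default
#'   drops 12-month samples for stool, which cluster separately).
#' @return data.frame of switching records, one row per retained subject.
#' @export
switching_records <- function(labels, meta, mode = c("stool", "milk"),
                              exclude_timepoints = NULL) {
  mode <- match.arg(mode)
  if (is.null(exclude_timepoints)) {
    exclude_timepoints <- if (mode == "stool") "12m" else character()
  }
  meta <- validate_metadata(meta)
  meta <- meta[match(names(labels), meta$sample_id), ]
  keep <- !(meta$timepoint %in% exclude_timepoints)
  meta <- meta[keep, , drop = FALSE]; labels <- labels[keep]
  out <- list(); dropped <- 0L
  for (d in unique(meta$dyad_id)) {
    ix <- which(meta$dyad_id == d)
    if (length(ix) < 2) { dropped <- dropped + 1L; next }
    first <- meta[ix[1], ]
    out[[length(out) + 1L]] <- data.frame(
      subject_id = d, n_samples = length(ix),
      n_distinct_clusters = length(unique(labels[ix])),
      degree = switching_degree(labels[ix], mode),
      last_sample_age_days = max(meta$age_days[ix]),
      delivery_mode = first$delivery_mode, infant_sex = first$infant_sex,
      formula_exposed = first$formula_exposed,
      maternal_bmi = first$maternal_bmi, maternal_age = first$maternal_age,
      prenatal_antibiotics = first$prenatal_antibiotics,
      stringsAsFactors = FALSE)
  }
  if (dropped) message(dropped, " subject(s) with < 2 samples excluded")
  if (!length(out)) stop("no subject has >= 2 samples")
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Within- versus between-subject community distances
#'
#' Partitions all pairwise dissimilarities into same-subject and
#' different-subject sets and compares them with the Kruskal-Wallis
#' rank-sum test; a lower within-subject median indicates longitudinal
#' community persistence.
#'
#' @param D validated distance matrix over longitudinally collected samples.
#' @param subject_ids subject of each sample (aligned with `D`'s rows).
#' @return list with `H`, `p`, `median_within`, `median_between`,
#'   `n_within`, `n_between`.
#' @export
within_between_distance_test <- function(D, subject_ids) {
  validate_distance_matrix(D)
  stopifnot(length(subject_ids) == nrow(D))
  ut <- upper.tri(D)
  same <- outer(subject_ids, subject_ids, "==")[ut]
  d <- D[ut]
  if (!any(same)) stop("no within-subject pairs (need >= 2 samples per subject)")
  if (!any(!same)) stop("no between-subject pairs (need >= 2 subjects)")
  if (length(unique(d)) == 1) {  # all distances tied: no evidence either way
    kt <- list(statistic = c(H = 0), p.value = 1)
  } else {
    kt <- stats::kruskal.test(d, factor(same, levels = c(FALSE, TRUE),
                                        labels = c("between", "within")))
  }
  list(H = unname(kt$statistic), p = kt$p.value,
       median_within = stats::median(d[same]),
       median_between = stats::median(d[!same]),
       n_within = sum(same), n_between = sum(!same))
}

#' Univariate screen of switching predictors
#'
#' Continuous predictors are tested against the switching degree with the
#' Kruskal-Wallis rank-sum test, categorical predictors with Fisher's exact
#' test; predictors with p below the threshold are retained for the
#' adjusted multinomial model.
#'
#' @param records switching records from [switching_records()].
#' @param predictors candidate predictor column names.
#' @param threshold retention p-value threshold (default 0.1).
#' @return data.frame (predictor, p, retained), ordered as supplied.
#' @export
screen_switching_predictors <- function(records, predictors, threshold = 0.1) {
  p <- vapply(predictors, function(v) {
    x <- records[[v]]
    if (is.numeric(x)) {
      stats::kruskal.test(x, factor(records$degree))$p.value
    } else {
      tab <- table(x, records$degree)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (any(dim(tab) < 2)) return(1)
      stats::fisher.test(tab, simulate.p.value = prod(dim(tab)) > 16,
                         B = 10000)$p.value
    }
  }, numeric(1))
  data.frame(predictor = predictors, p = p, retained = p < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multinomial logistic model of the switching degree
#'
#' Maximum-likelihood multinomial logit with no switching (degree 0) as the
#' reference outcome, adjusted for the timing of the last collected sample.
#' Reports odds ratios with Wald 95% confidence intervals per predictor and
#' degree level. When fewer than 3 outcome categories are observed the
#' model degrades to binary logistic regression with a warning. Quasi- or
#' complete separation is reported, not hidden: rows whose log-OR confidence
#' interval spans more than `instability_width` log-odds units are flagged
#' `unstable`.
#'
#' @param records switching records.
#' @param predictors predictor column names (constant columns are an error).
#' @param adjust_for timing adjustment column (default last-sample age).
#' @param instability_width CI width (log-odds) beyond which an estimate is
#'   flagged as separation-driven.
#' @return list with `coefficients` (outcome level, term, or, ci_lo, ci_hi,
#'   p, unstable), `model`, `n`.
#' @export
multinomial_switching_model <- function(records, predictors,
                                        adjust_for = "last_sample_age_days",
                                        instability_width = 10) {
  for (v in c(predictors, adjust_for)) {
    if (length(unique(records[[v]])) < 2) {
      stop("predictor constant across subjects: ", v)
    }
  }
  df <- records
  df$degree <- factor(df$degree)
  for (v in predictors) if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  if (nlevels(df$degree) < 3) {
    warning("fewer than 3 switching categories observed; binary model fitted")
  }
  fml <- stats::as.formula(paste("degree ~",
                                 paste(c(predictors, adjust_for), collapse = " + ")))
  fit <- nnet::multinom(fml, data = df, trace = FALSE, maxit = 500)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, 1, dimnames = list(levels(df$degree)[2], names(cf)))
  vc <- stats::vcov(fit)
  out <- list()
  for (lev in rownames(cf)) {
    for (term in colnames(cf)) {
      if (term == "(Intercept)") next
      est <- cf[lev, term]
      vname <- if (nrow(cf) > 1) paste(lev, term, sep = ":") else term
      se <- sqrt(vc[vname, vname])
      zp <- 2 * stats::pnorm(-abs(est / se))
      out[[length(out) + 1L]] <- data.frame(
        degree = lev, term = term, or = exp(est),
        ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
        p = zp, unstable = (2 * 1.96 * se) > instability_width,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  list(coefficients = res, model = fit, n = nrow(df))
}
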