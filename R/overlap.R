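#' Overlap proportion of a stool sample with a milk presence set
#'
#' Fraction of the infant stool sample's reads belonging to ASVs that were
#' also detected in the paired mother's milk:
#' `sum(stool counts over ASVs in milk_present) / sum(all stool counts)`.
#'
#' @param stool_counts named count vector for one stool sample (sum > 0).
#' @param milk_present character vector of ASV ids detected in milk.
#' @return fraction in \[0, 1\].
#' @export
overlap_proportion <- function(stool_counts, milk_present) {
  tot <- sum(stool_counts)
  if (tot == 0) stop("empty stool sample")
  if (is.null(names(stool_counts))) stop("stool counts must be named by ASV")
  sum(stool_counts[names(stool_counts) %in% milk_present]) / tot
}

milk_presence_set <- function(milk_table, sample_id, min_presence = 1) {
  colnames(milk_table)[milk_table[sample_id, ] >= min_presence]
}

#' Dyad overlap records over all admissible milk-stool pairs
#'
#' One record per (dyad, milk sample, stool sample at the same or a later
#' visit); a dyad observed at several timepoint pairs contributes several
#' records. `milk_present` is the set of ASVs with count >= `min_presence`
#' (default 1: any detected read) in that milk sample. With
#' `nearest_only = TRUE` each stool sample is paired only with the latest
#' milk sample at or before its visit.
#'
#' @param milk_table,stool_table count matrices sharing the ASV vocabulary.
#' @param meta validated metadata covering both tables' samples.
#' @param min_presence minimum milk count for an ASV to count as present.
#' @param nearest_only keep only the nearest preceding milk per stool sample.
#' @return data.frame of overlap records with covariates snapshot.
#' @export
paired_overlap_table <- function(milk_table, stool_table, meta,
                                 min_presence = 1, nearest_only = FALSE) {
  meta <- validate_metadata(meta)
  pairing <- dyad_pairing(meta)
  pairing <- pairing[pairing$milk_sample %in% rownames(milk_table) &
                       pairing$stool_sample %in% rownames(stool_table), ,
                     drop = FALSE]
  if (nearest_only && nrow(pairing)) {
    keep <- unlist(lapply(split(seq_len(nrow(pairing)), pairing$stool_sample),
                          function(ix) {
      r <- timepoint_rank(pairing$milk_timepoint[ix])
      ix[which.max(r)]
    }))
    pairing <- pairing[sort(keep), , drop = FALSE]
  }
  ov <- numeric(nrow(pairing))
  for (i in seq_len(nrow(pairing))) {
    present <- milk_presence_set(milk_table, pairing$milk_sample[i], min_presence)
    ov[i] <- overlap_proportion(stool_table[pairing$stool_sample[i], ], present)
  }
  cov <- meta[match(pairing$stool_sample, meta$sample_id),
              c("age_days", "delivery_mode", "infant_sex", "formula_exposed",
                "maternal_bmi", "maternal_age", "prenatal_antibiotics")]
  out <- cbind(pairing, overlap = ov, cov)
  rownames(out) <- NULL
  out
}

random_derangement <- function(n) {
  if (n < 2) stop("a derangement needs n >= 2")
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Random-dyad null distribution of the overlap proportion
#'
#' Repeatedly shuffles the milk-stool pairing across dyads at one timepoint
#' (derangements: no stool ever keeps its true milk), recomputes the overlap
#' for every shuffled pair and pools the values across draws.
#'
#' @param milk_table,stool_table count matrices.
#' @param meta validated metadata.
#' @param timepoint visit code at which dyads are shuffled.
#' @param n_draws number of random pairings to pool.
#' @param seed integer seed.
#' @param min_presence minimum milk count defining presence.
#' @return list of class `overlap_null`: `values`, `observed` (true-pair
#'   overlaps at this timepoint), `n_draws`, `timepoint`, `seed`.
#' @export
random_dyad_null <- function(milk_table, stool_table, meta, timepoint,
                             n_draws = 1000, seed = 1, min_presence = 1) {
  meta <- validate_metadata(meta)
  sub <- meta[meta$timepoint == timepoint, ]
  milk <- sub[sub$compartment == "milk" & sub$sample_id %in% rownames(milk_table), ]
  stool <- sub[sub$compartment == "stool" & sub$sample_id %in% rownames(stool_table), ]
  dyads <- intersect(milk$dyad_id, stool$dyad_id)
  if (length(dyads) < 2) stop("need >= 2 dyads with both samples at ", timepoint)
  milk_ids <- milk$sample_id[match(dyads, milk$dyad_id)]
  stool_ids <- stool$sample_id[match(dyads, stool$dyad_id)]
  present <- lapply(milk_ids, function(s) milk_presence_set(milk_table, s, min_presence))
  observed <- vapply(seq_along(dyads), function(i) {
    overlap_proportion(stool_table[stool_ids[i], ], present[[i]])
  }, numeric(1))
  values <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_draws), function(b) {
      perm <- random_derangement(length(dyads))
      stopifnot(all(perm != seq_along(dyads)))  # never a true pairing
      vapply(seq_along(dyads), function(i) {
        overlap_proportion(stool_table[stool_ids[i], ], present[[perm[i]]])
      }, numeric(1))
    }))
  })
  structure(list(values = values, observed = observed, n_draws = n_draws,
                 timepoint = timepoint, seed = seed, n_dyads = length(dyads)),
            class = "overlap_null")
}

#' Kolmogorov-Smirnov comparison of observed and null overlap distributions
#'
#' Two-sample K-S: `D = sup |ECDF_obs - ECDF_null|` with the asymptotic
#' two-sided p-value.
#'
#' @param observed true-dyad overlap fractions.
#' @param null an `overlap_null` (or a plain numeric vector of null values).
#' @return list with `D`, `p`, `n_observed`, `n_null`.
#' @export
ks_compare <- function(observed, null) {
  values <- if (inherits(null, "overlap_null")) null$values else null
  if (!length(observed) || !length(values)) stop("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(observed, values, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_observed = length(observed), n_null = length(values))
}

#' Mixed-effects model of the overlap proportion on infant covariates
#'
#' Linear mixed model of the overlap, expressed in percentage points
#' (0-100), with a random intercept per dyad to account for repeated
#' timepoint pairs. `covariates = NULL` fits the fully adjusted model
#' (delivery mode + formula exposure + infant sex + infant age); a single
#' covariate name fits the unadjusted model for that variable. Records with
#' formula status `"missing"` are dropped whenever formula exposure enters
#' the model.
#'
#' @param records overlap records from [paired_overlap_table()].
#' @param covariates covariate name(s) to include, or `NULL` for the fully
#'   adjusted model.
#' @return list with `coefficients` (term, estimate in percentage points,
#'   ci_lo, ci_hi, p), `n_records`, `n_dyads`, `model`.
#' @export
overlap_covariate_model <- function(records, covariates = NULL) {
  adjusted <- is.null(covariates)
  if (adjusted) covariates <- c("delivery_mode", "formula_exposed",
                                "infant_sex", "age_days")
  if ("formula_exposed" %in% covariates) {
    records <- records[records$formula_exposed != "missing", , drop = FALSE]
  }
  if (nrow(records) < 2 || length(unique(records$dyad_id)) < 2) {
    stop("need >= 2 records over >= 2 dyads")
  }
  df <- records
  df$overlap_pct <- 100 * df$overlap
  refs <- c(delivery_mode = "vaginal", infant_sex = "female",
            formula_exposed = "no", prenatal_antibiotics = "no")
  for (v in intersect(covariates, names(refs))) {
    df[[v]] <- factor(df[[v]])
    if (refs[[v]] %in% levels(df[[v]])) df[[v]] <- stats::relevel(df[[v]], refs[[v]])
  }
  rhs <- paste(covariates, collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), df)
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  if (length(unique(df$dyad_id)) < nrow(df)) {
    fml <- stats::as.formula(paste("overlap_pct ~", rhs, "+ (1 | dyad_id)"))
    fit <- lmerTest::lmer(fml, data = df,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    # one record per dyad: nothing is repeated, ordinary regression applies
    fit <- stats::lm(stats::as.formula(paste("overlap_pct ~", rhs)), data = df)
  }
  co <- stats::coef(summary(fit))
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  p <- co[, "Pr(>|t|)"]
  bad <- !is.finite(p)  # zero-variance response: a null effect, not a failure
  se[!is.finite(se)] <- 0
  p[bad] <- ifelse(abs(est[bad]) < 1e-12, 1, NA)
  coefs <- data.frame(term = rownames(co), estimate = est,
                      ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                      p = p, row.names = NULL, stringsAsFactors = FALSE)
  list(coefficients = coefs, n_records = nrow(df),
       n_dyads = length(unique(df$dyad_id)), model = fit)
}
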