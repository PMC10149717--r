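#' Relative abundance profiles
#'
#' Converts counts to within-sample proportions. Rows must have positive
#' totals; all-zero samples are an error (they carry no community signal).
#'
#' @param counts count vector (one sample) or samples x taxa matrix.
#' @return proportions of the same shape; each sample sums to 1.
#' @export
relative_abundance <- function(counts) {
  if (is.matrix(counts)) {
    rs <- rowSums(counts)
    if (any(rs == 0)) {
      stop("empty sample(s): ", paste(rownames(counts)[rs == 0], collapse = ", "))
    }
    return(sweep(counts, 1, rs, "/"))
  }
  if (sum(counts) == 0) stop("empty sample: all counts are zero")
  counts / sum(counts)
}

#' Aggregate an ASV table to a taxonomic rank
#'
#' Counts of ASVs sharing a genus (or family) label are summed; ASVs missing
#' from the taxonomy are pooled under the sentinel `"unassigned"` with a
#' warning. Per-sample totals are conserved exactly.
#'
#' @param counts samples x ASVs count matrix.
#' @param taxonomy data.frame with columns asv_id and the requested rank.
#' @param rank `"genus"` or `"family"`.
#' @return samples x taxa count matrix.
#' @export
aggregate_by_taxon <- function(counts, taxonomy, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  validate_count_table(counts)
  lab <- taxonomy[[rank]][match(colnames(counts), taxonomy$asv_id)]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " ASV(s) missing from taxonomy; pooled as 'unassigned'")
    lab[is.na(lab)] <- "unassigned"
  }
  groups <- sort(unique(lab))
  out <- matrix(0, nrow(counts), length(groups),
                dimnames = list(rownames(counts), groups))
  for (g in groups) {
    out[, g] <- rowSums(counts[, lab == g, drop = FALSE])
  }
  out
}

#' Alpha diversity per sample
#'
#' Computes, for each sample row: Simpson's diversity `sdi = 1 - sum(p^2)`
#' (in \[0, 1)), Shannon diversity `shdi = -sum(p log p)` in nats, the
#' number of observed ASVs, and `logit_sdi = log(sdi / (1 - sdi))`
#' (`-Inf` sentinel when sdi = 0, i.e. a single-taxon sample).
#'
#' @param counts count vector or samples x taxa count matrix.
#' @return data.frame with columns sample_id, sdi, shdi, observed_asvs,
#'   logit_sdi.
#' @export
alpha_diversity <- function(counts) {
  if (!is.matrix(counts)) counts <- matrix(counts, 1, dimnames = list("sample", NULL))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  p <- relative_abundance(counts)
  sdi <- 1 - rowSums(p^2)
  sdi <- pmin(pmax(sdi, 0), 1)  # guard tiny negative fp error
  shdi <- apply(p, 1, function(x) -sum(x[x > 0] * log(x[x > 0])))
  obs <- rowSums(counts > 0)
  logit_sdi <- ifelse(sdi > 0 & sdi < 1, log(sdi / (1 - sdi)), -Inf)
  data.frame(sample_id = rownames(counts), sdi = sdi, shdi = shdi,
             observed_asvs = as.integer(obs), logit_sdi = logit_sdi,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rarefy a sample to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric), so
#' the output sums exactly to `depth`; reproducible under `seed`.
#'
#' @param counts count vector (one sample).
#' @param depth target depth, at most `sum(counts)`.
#' @param seed integer seed.
#' @return integer count vector of the same length and names.
#' @export
rarefy_counts <- function(counts, depth, seed = 1) {
  if (depth > sum(counts)) stop("rarefaction depth exceeds sample depth")
  withr::with_seed(seed, {
    pool <- rep.int(seq_along(counts), counts)
    take <- pool[sample.int(length(pool), depth)]
  })
  out <- tabulate(take, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Most abundant taxon of a profile
#'
#' Returns the label with maximal proportion; exact ties break
#' lexicographically (with a warning naming the tie).
#'
#' @param profile named proportion (or count) vector at genus/family level.
#' @return single taxon label.
#' @export
most_abundant_taxon <- function(profile) {
  if (!length(profile) || is.null(names(profile))) {
    stop("profile must be a named, nonempty vector")
  }
  top <- names(profile)[profile == max(profile)]
  if (length(top) > 1) {
    top <- sort(top)
    warning("tie for most abundant taxon (", paste(top, collapse = ", "),
            "); lexicographically first used")
  }
  top[1]
}

#' Diversity-versus-age mixed model
#'
#' Random-intercept linear model of an alpha-diversity metric on infant age,
#' with the slope reported per 100 days of life. P-values use the
#' Satterthwaite approximation. Non-finite metric values (the `-Inf` logit
#' sentinel of single-taxon samples) are excluded with a message. When the
#' random intercept cannot be estimated (e.g. one sample per subject) the
#' model falls back to ordinary least squares with a warning.
#'
#' @param metric numeric metric per sample.
#' @param age_days age at collection per sample.
#' @param subject_ids grouping factor (repeated measures per subject).
#' @return list with `slope_per_100d`, `ci` (95% Wald), `p`, `n`, `model`.
#' @export
diversity_age_model <- function(metric, age_days, subject_ids) {
  keep <- is.finite(metric)
  if (any(!keep)) message(sum(!keep), " sample(s) with non-finite metric excluded")
  df <- data.frame(y = metric[keep], a100 = age_days[keep] / 100,
                   subject = factor(subject_ids[keep]))
  if (nlevels(df$subject) < 2 || nrow(df) < 3) {
    stop("need >= 2 subjects and >= 3 samples")
  }
  fit <- tryCatch(
    lmerTest::lmer(y ~ a100 + (1 | subject), data = df,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (is.null(fit) || max(table(df$subject)) == 1) {
    warning("random intercept not estimable; ordinary regression used")
    fit <- stats::lm(y ~ a100, data = df)
    co <- summary(fit)$coefficients
    est <- co["a100", "Estimate"]; se <- co["a100", "Std. Error"]
    p <- co["a100", "Pr(>|t|)"]
  } else {
    co <- stats::coef(summary(fit))
    est <- co["a100", "Estimate"]; se <- co["a100", "Std. Error"]
    p <- co["a100", "Pr(>|t|)"]
  }
  if (!is.finite(p) || se == 0) p <- if (abs(est) < 1e-12) 1 else p
  list(slope_per_100d = est, ci = est + c(-1, 1) * 1.96 * se, p = p,
       n = nrow(df), model = fit)
}
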