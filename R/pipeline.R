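fnv1a_hash <- function(x) {
  # tiny stable config fingerprint (polynomial rolling hash, 31-bit)
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_seed <- function(seed, stage) {
  # independent per-stage streams from one global seed
  offsets <- c(simulate = 0L, diversity = 101L, distance = 202L,
               typing = 303L, overlap = 404L, stability = 505L,
               crosstalk = 606L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Pipeline run configuration
#'
#' Bundles the simulation (or input paths), the analysis thresholds quoted
#' throughout the method (minimum library size 1000 reads, prevalence 0.10,
#' abundance 0.005, q < 0.1, at least 10 dyads per tested association), the
#' GUniFrac alpha, the cluster counts per compartment, and the seed.
#'
#' @param sim a [cohort_sim_config()] (simulated input), or `NULL` when
#'   `paths` supplies files.
#' @param paths optional named list (counts_milk, counts_stool, meta, tree)
#'   of input files; overrides `sim`.
#' @param alpha GUniFrac weighting exponent.
#' @param k_milk,k_stool_all,k_stool_6w,k_stool_12m PAM cluster counts
#'   (defaults: milk 3; all-stool 6; 6-week stool 4; 12-month stool 2).
#' @param min_reads library-size filter.
#' @param null_draws random-pairing draws for the overlap null.
#' @param n_perm Mantel permutations.
#' @param prevalence,abundance correlation-screen filter thresholds.
#' @param q_threshold q-value significance threshold.
#' @param min_dyads minimum dyads per tested association.
#' @param seed global seed, expanded into per-stage streams.
#' @param out_dir output directory (created if absent).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = cohort_sim_config(), paths = NULL, alpha = 0.5,
                       k_milk = 3, k_stool_all = 6, k_stool_6w = 4,
                       k_stool_12m = 2, min_reads = 1000, null_draws = 1000,
                       n_perm = 10000, prevalence = 0.10, abundance = 0.005,
                       q_threshold = 0.1, min_dyads = 10, seed = 1,
                       out_dir = tempfile("dyadlink_run_")) {
  cfg <- as.list(environment())
  stopifnot(cfg$alpha >= 0, cfg$alpha <= 1, cfg$min_reads >= 0,
            cfg$null_draws >= 1, cfg$n_perm >= 1,
            cfg$prevalence >= 0, cfg$prevalence < 1,
            cfg$abundance >= 0, cfg$abundance < 1,
            cfg$q_threshold > 0, cfg$q_threshold <= 1, cfg$min_dyads >= 1)
  class(cfg) <- "run_config"
  cfg
}

skip_rec <- function(report, stage, what, reason) {
  report$skipped[[length(report$skipped) + 1L]] <-
    list(stage = stage, analysis = what, reason = reason)
  report
}

#' Run the full dyadic analysis pipeline
#'
#' Simulates (or loads) a cohort, applies the library-size filter, then runs
#' every stage in order: alpha diversity + diversity-versus-age model,
#' GUniFrac distance matrices, PAM typing per compartment, the dyad overlap
#' analysis with its random-pairing null and covariate models, longitudinal
#' stability scoring, and the cross-compartment association stage (exact
#' type association, Mantel tests per timepoint pair, taxa correlation
#' screen). Every analysis skipped for a sample-size (or other) reason is
#' enumerated in the report. Outputs (CSV/TSV + `report.json`, stamped with
#' the config hash and seed) are written under `config$out_dir`; a rerun
#' with the same config is byte-identical.
#'
#' @param config a [run_config()].
#' @return the report (list), invisibly also written as JSON.
#' @export
run_all <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("config must come from run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hashed <- unclass(config)
  hashed$out_dir <- NULL  # the output location is not part of the analysis
  report <- list(config_hash = fnv1a_hash(hashed), seed = config$seed,
                 skipped = list())

  ## ---- input
  if (!is.null(config$paths)) {
    milk <- read_count_table(config$paths$counts_milk)
    stool <- read_count_table(config$paths$counts_stool)
    meta <- read_metadata(config$paths$meta)
    tree <- read_tree(config$paths$tree)
    cohort <- list(milk_table = milk, stool_table = stool, metadata = meta,
                   tree = tree, truth = NULL)
  } else {
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    cohort <- simulate_cohort(sim)
  }
  milk <- suppressMessages(filter_low_depth_samples(cohort$milk_table, config$min_reads))
  stool <- suppressMessages(filter_low_depth_samples(cohort$stool_table, config$min_reads))
  meta <- cohort$metadata
  meta <- meta[meta$sample_id %in% c(rownames(milk), rownames(stool)), ]
  aligned <- align_table_tree_metadata(rbind(milk, stool), cohort$tree, meta)
  report$n <- list(dyads = length(unique(meta$dyad_id)),
                   milk_samples = nrow(milk), stool_samples = nrow(stool),
                   asvs = ncol(milk),
                   removed_low_depth = (nrow(cohort$milk_table) - nrow(milk)) +
                     (nrow(cohort$stool_table) - nrow(stool)))

  ## ---- diversity
  div <- rbind(cbind(alpha_diversity(milk), compartment = "milk"),
               cbind(alpha_diversity(stool), compartment = "stool"))
  div <- merge(div, meta[, c("sample_id", "dyad_id", "timepoint", "age_days")],
               by = "sample_id", sort = TRUE)
  utils::write.csv(div, file.path(config$out_dir, "diversity.csv"),
                   row.names = FALSE, quote = FALSE)
  sdiv <- div[div$compartment == "stool", ]
  report$diversity <- lapply(c(logit_sdi = "logit_sdi", shdi = "shdi",
                               observed_asvs = "observed_asvs"), function(mcol) {
    fit <- suppressWarnings(suppressMessages(
      diversity_age_model(sdiv[[mcol]], sdiv$age_days, sdiv$dyad_id)))
    list(slope_per_100d = fit$slope_per_100d, ci = fit$ci, p = fit$p, n = fit$n)
  })

  ## ---- distances
  D_milk <- gunifrac(milk, cohort$tree, alpha = config$alpha)
  D_stool <- gunifrac(stool, cohort$tree, alpha = config$alpha)
  write_distance_matrix(D_milk, file.path(config$out_dir, "gunifrac_milk.tsv"))
  write_distance_matrix(D_stool, file.path(config$out_dir, "gunifrac_stool.tsv"))

  ## ---- typing
  tp_of <- function(ids) meta$timepoint[match(ids, meta$sample_id)]
  typing_seed <- stage_seed(config$seed, "typing")
  types <- list()
  types$milk <- assign_microbiome_types(D_milk, config$k_milk, seed = typing_seed)
  types$stool_all <- assign_microbiome_types(D_stool, config$k_stool_all,
                                             seed = typing_seed)
  for (spec in list(list(name = "stool_6w", tp = "6w", k = config$k_stool_6w),
                    list(name = "stool_12m", tp = "12m", k = config$k_stool_12m))) {
    ids <- rownames(D_stool)[tp_of(rownames(D_stool)) == spec$tp]
    if (length(ids) >= max(3, spec$k + 1)) {
      types[[spec$name]] <- assign_microbiome_types(
        D_stool[ids, ids, drop = FALSE], spec$k, seed = typing_seed)
    } else {
      report <- skip_rec(report, "typing", spec$name, "too few samples")
    }
  }
  lab_df <- do.call(rbind, lapply(names(types), function(nm) {
    data.frame(analysis = nm, sample_id = names(types[[nm]]$labels),
               label = unname(types[[nm]]$labels),
               medoid = names(types[[nm]]$labels) %in% types[[nm]]$medoid_ids,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(lab_df, file.path(config$out_dir, "clusters.csv"),
                   row.names = FALSE, quote = FALSE)
  report$typing <- lapply(types, function(t) {
    list(k = t$k, total_cost = t$total_cost, silhouette = t$silhouette)
  })
  for (nm in intersect(c("stool_6w", "stool_12m", "milk"), names(types))) {
    ids <- names(types[[nm]]$labels)
    sdi <- div$sdi[match(ids, div$sample_id)]
    report$typing[[nm]]$diversity_kw <-
      diversity_by_cluster_test(sdi, types[[nm]]$labels)[c("H", "p")]
  }

  ## ---- overlap
  ov_seed <- stage_seed(config$seed, "overlap")
  records <- paired_overlap_table(milk, stool, meta)
  utils::write.csv(records, file.path(config$out_dir, "overlap.csv"),
                   row.names = FALSE, quote = FALSE)
  report$overlap <- list(n_records = nrow(records),
                         median_overlap = stats::median(records$overlap))
  n6w <- sum(meta$timepoint == "6w" & meta$compartment == "stool")
  nulls <- tryCatch(random_dyad_null(milk, stool, meta, "6w",
                                     n_draws = config$null_draws, seed = ov_seed),
                    error = function(e) NULL)
  if (!is.null(nulls)) {
    ks <- ks_compare(nulls$observed, nulls)
    report$overlap$ks_6w <- list(D = ks$D, p = ks$p, n_dyads = nulls$n_dyads,
                                 median_true = stats::median(nulls$observed),
                                 median_null = stats::median(nulls$values))
  } else {
    report <- skip_rec(report, "overlap", "ks_6w", "fewer than 2 complete dyads at 6w")
  }
  fit_cov <- function(covs) tryCatch(
    suppressWarnings(suppressMessages(overlap_covariate_model(records, covs))),
    error = function(e) NULL)
  mods <- list(unadjusted_delivery = fit_cov("delivery_mode"),
               unadjusted_sex = fit_cov("infant_sex"),
               unadjusted_formula = fit_cov("formula_exposed"),
               adjusted = fit_cov(NULL))
  report$overlap$models <- lapply(mods[!vapply(mods, is.null, logical(1))],
                                  function(m) m$coefficients)

  ## ---- stability
  report$stability <- list()
  for (mode in c("milk", "stool")) {
    fit <- types[[if (mode == "milk") "milk" else "stool_all"]]
    recs <- tryCatch(suppressMessages(
      switching_records(fit$labels, meta, mode = mode)), error = function(e) NULL)
    if (is.null(recs)) {
      report <- skip_rec(report, "stability", mode, "no subject with >= 2 samples")
      next
    }
    D <- if (mode == "milk") D_milk else {
      ids <- rownames(D_stool)[tp_of(rownames(D_stool)) != "12m"]
      D_stool[ids, ids, drop = FALSE]
    }
    ids <- rownames(D)[meta$dyad_id[match(rownames(D), meta$sample_id)] %in%
                         recs$subject_id]
    wb <- within_between_distance_test(D[ids, ids, drop = FALSE],
                                       meta$dyad_id[match(ids, meta$sample_id)])
    screen <- screen_switching_predictors(
      recs, c("maternal_age", "maternal_bmi", "prenatal_antibiotics",
              "delivery_mode", "infant_sex", "last_sample_age_days"))
    mm <- if (length(unique(recs$degree)) >= 2 &&
              any(screen$retained & screen$predictor != "last_sample_age_days")) {
      keep <- screen$predictor[screen$retained & screen$predictor != "last_sample_age_days"]
      tryCatch(suppressWarnings(multinomial_switching_model(recs, keep)),
               error = function(e) NULL)
    }
    report$stability[[mode]] <- list(
      n_subjects = nrow(recs),
      degree_freq = as.list(table(factor(recs$degree, levels = 0:2)) / nrow(recs)),
      within_between = wb[c("H", "p", "median_within", "median_between")],
      screen = screen,
      multinomial = if (!is.null(mm)) mm$coefficients)
    utils::write.csv(recs, file.path(config$out_dir,
                                     paste0("stability_", mode, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }

  ## ---- crosstalk
  ct_seed <- stage_seed(config$seed, "crosstalk")
  report$crosstalk <- list()
  dyad_of <- function(ids) meta$dyad_id[match(ids, meta$sample_id)]
  if (!is.null(types$stool_6w)) {
    ids6 <- rownames(D_milk)[tp_of(rownames(D_milk)) == "6w"]
    milk_lab <- types$milk$labels[ids6]
    names(milk_lab) <- dyad_of(ids6)
    stool_lab <- types$stool_6w$labels
    names(stool_lab) <- dyad_of(names(types$stool_6w$labels))
    dmeta <- unique(meta[meta$compartment == "stool",
                         c("dyad_id", "delivery_mode", "infant_sex")])
    strata_dm <- stats::setNames(dmeta$delivery_mode, dmeta$dyad_id)
    assoc <- suppressMessages(type_association(
      milk_lab, stool_lab, strata = strata_dm, min_dyads = config$min_dyads,
      method = "auto", n_sim = 10000, seed = ct_seed))
    report$crosstalk$type_association_6w <- list(
      p = if (!is.null(assoc$overall)) assoc$overall$p,
      strata_p = lapply(assoc$strata, `[[`, "p"), skipped = assoc$skipped)
  } else {
    report <- skip_rec(report, "crosstalk", "type_association_6w",
                       "no 6-week stool typing")
  }

  ## Mantel per timepoint pair (stool at same or later visit)
  dmeta_all <- meta[meta$compartment == "stool", ]
  dmeta_all <- dmeta_all[!duplicated(dmeta_all$dyad_id), ]
  rownames(dmeta_all) <- dmeta_all$dyad_id
  mantel_res <- list()
  for (mtp in TIMEPOINT_LEVELS) {
    for (stp in TIMEPOINT_LEVELS[timepoint_rank(TIMEPOINT_LEVELS) >=
                                 timepoint_rank(mtp)]) {
      mids <- rownames(D_milk)[tp_of(rownames(D_milk)) == mtp]
      sids <- rownames(D_stool)[tp_of(rownames(D_stool)) == stp]
      common <- intersect(dyad_of(mids), dyad_of(sids))
      key <- paste0(mtp, "_vs_", stp)
      if (length(common) < config$min_dyads) {
        if (length(common) > 0) {
          report <- skip_rec(report, "crosstalk", paste0("mantel_", key),
                             sprintf("%d dyads < %d", length(common),
                                     config$min_dyads))
        }
        next
      }
      mi <- mids[match(common, dyad_of(mids))]
      si <- sids[match(common, dyad_of(sids))]
      Dm <- D_milk[mi, mi]; dimnames(Dm) <- list(common, common)
      Ds <- D_stool[si, si]; dimnames(Ds) <- list(common, common)
      plain <- mantel_test(Dm, Ds, n_perm = config$n_perm, seed = ct_seed)
      Dz <- covariate_distance(dmeta_all[common, , drop = FALSE])
      adj <- suppressWarnings(adjusted_mantel(Dm, Ds, Dz,
                                              n_perm = config$n_perm,
                                              seed = ct_seed))
      mantel_res[[key]] <- list(n_dyads = length(common),
                                r = plain$r, p = plain$p,
                                r_adjusted = adj$r, p_adjusted = adj$p)
    }
  }
  report$crosstalk$mantel <- mantel_res

  ## taxa correlation screen at the 6-week pair
  tc <- tryCatch({
    mids <- rownames(milk)[tp_of(rownames(milk)) == "6w"]
    sids <- rownames(stool)[tp_of(rownames(stool)) == "6w"]
    common <- intersect(dyad_of(mids), dyad_of(sids))
    if (length(common) < 5) stop("fewer than 5 complete dyads at 6w")
    mi <- mids[match(common, dyad_of(mids))]
    si <- sids[match(common, dyad_of(sids))]
    m_rel <- relative_abundance(milk[mi, , drop = FALSE])
    s_rel <- relative_abundance(stool[si, , drop = FALSE])
    m_keep <- filter_prevalent_asvs(m_rel, config$prevalence, config$abundance)
    s_keep <- filter_prevalent_asvs(s_rel, config$prevalence, config$abundance)
    rownames(m_rel) <- rownames(s_rel) <- common
    suppressMessages(taxa_correlations(m_rel[, m_keep, drop = FALSE],
                                       s_rel[, s_keep, drop = FALSE],
                                       q_threshold = config$q_threshold))
  }, error = function(e) e)
  if (inherits(tc, "error")) {
    report <- skip_rec(report, "crosstalk", "taxa_correlations_6w",
                       conditionMessage(tc))
  } else {
    utils::write.csv(tc$results,
                     file.path(config$out_dir, "taxa_correlations_6w.csv"),
                     row.names = FALSE, quote = FALSE)
    report$crosstalk$taxa_correlations_6w <- list(
      mean_abs_rho = tc$mean_abs_rho, n_dyads = tc$n_dyads,
      n_pairs = nrow(tc$results), n_significant = sum(tc$results$significant))
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
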