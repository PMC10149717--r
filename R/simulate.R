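#' Configuration for the synthetic mother-infant cohort generator
#'
#' The generator emulates the dyadic design the downstream analysis assumes:
#' each dyad contributes paired milk and stool samples at a subset of the
#' five visits; milk communities are drawn around one of `k_milk` archetype
#' profiles and stool communities around one of `k_stool` archetypes; a
#' fraction `transfer_fraction` of each stool composition is drawn from the
#' paired milk community (restricted to ASVs observed in the milk sample, so
#' sequencing depth attenuates observed sharing); reads are multinomial at
#' lognormal depths.
#'
#' Covariates shift the per-dyad transfer fraction additively (cesarean
#' delivery, male sex, formula exposure), with the realized value clipped to
#' \[0, 1\] and recorded in the cohort's truth slot.
#'
#' @param n_dyads number of mother-infant dyads.
#' @param timepoints visit codes used (subset of [TIMEPOINT_LEVELS]).
#' @param timepoint_probs per-visit inclusion probability for each dyad
#'   (named, same length as `timepoints`).
#' @param n_asvs number of ASVs shared by both compartments' tables.
#' @param k_milk,k_stool number of milk / stool community archetypes.
#' @param dirichlet_concentration Dirichlet precision around an archetype
#'   profile; larger = tighter communities.
#' @param archetype_support_frac fraction of ASVs in each archetype's
#'   support (archetypes are sparse, as real communities are).
#' @param milk_archetypes,stool_archetypes optional explicit archetype
#'   profile matrices (k x n_asvs, rows summing to 1); override the random
#'   supports.
#' @param transfer_fraction baseline fraction `s` of stool composition drawn
#'   from the paired milk community.
#' @param transfer_lag 0 = contemporaneous milk is the source; 1 = the milk
#'   sample one visit earlier (falling back to contemporaneous when absent).
#' @param effect_cesarean,effect_male,effect_formula additive shifts to `s`.
#' @param s_dyad_sd sd of dyad-level Gaussian noise on `s`.
#' @param archetype_switch_prob per-visit probability that a subject's
#'   community jumps to a different archetype.
#' @param depth_log_mean,depth_log_sd lognormal sequencing-depth parameters.
#' @param p_cesarean,p_male,p_formula_yes,p_formula_missing,p_prenatal_abx
#'   covariate prevalences.
#' @param n_genera,n_families size of the synthetic taxonomy.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return a validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_dyads = 150,
                              timepoints = TIMEPOINT_LEVELS,
                              timepoint_probs = c("6w" = 1, "4m" = 0.12,
                                                  "6m" = 0.12, "9m" = 0.12,
                                                  "12m" = 0.7),
                              n_asvs = 300,
                              k_milk = 3,
                              k_stool = 4,
                              dirichlet_concentration = 50,
                              archetype_support_frac = 0.25,
                              milk_archetypes = NULL,
                              stool_archetypes = NULL,
                              transfer_fraction = 0.30,
                              transfer_lag = 0,
                              effect_cesarean = 0.10,
                              effect_male = 0.10,
                              effect_formula = -0.13,
                              s_dyad_sd = 0.05,
                              archetype_switch_prob = 0.2,
                              depth_log_mean = log(60000),
                              depth_log_sd = 0.7,
                              p_cesarean = 0.27,
                              p_male = 0.529,
                              p_formula_yes = 0.13,
                              p_formula_missing = 0.14,
                              p_prenatal_abx = 0.20,
                              n_genera = 40,
                              n_families = 12,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_dyads >= 1, cfg$n_asvs >= 2,
            cfg$k_milk >= 1, cfg$k_stool >= 1,
            cfg$dirichlet_concentration > 0,
            cfg$transfer_lag %in% c(0, 1),
            cfg$depth_log_sd >= 0, cfg$s_dyad_sd >= 0,
            cfg$archetype_switch_prob >= 0, cfg$archetype_switch_prob <= 1)
  if (!all(cfg$timepoints %in% TIMEPOINT_LEVELS)) {
    stop("timepoints must be drawn from ", paste(TIMEPOINT_LEVELS, collapse = "/"))
  }
  if (is.null(names(cfg$timepoint_probs))) names(cfg$timepoint_probs) <- cfg$timepoints
  if (!all(cfg$timepoints %in% names(cfg$timepoint_probs))) {
    stop("timepoint_probs must cover every timepoint")
  }
  if (cfg$transfer_fraction < 0 || cfg$transfer_fraction > 1) {
    stop("transfer_fraction must lie in [0, 1]")
  }
  for (ef in c("effect_cesarean", "effect_male", "effect_formula")) {
    if (cfg[[ef]] > 0 && cfg$transfer_fraction + cfg[[ef]] > 1) {
      stop("transfer_fraction + ", ef, " exceeds 1")
    }
  }
  for (nm in c("milk_archetypes", "stool_archetypes")) {
    A <- cfg[[nm]]
    if (!is.null(A)) {
      if (!is.matrix(A) || ncol(A) != cfg$n_asvs) stop(nm, " must be k x n_asvs")
      if (any(A < 0) || max(abs(rowSums(A) - 1)) > 1e-8) {
        stop(nm, " rows must be probability vectors")
      }
    }
  }
  if (!is.null(cfg$milk_archetypes)) cfg$k_milk <- nrow(cfg$milk_archetypes)
  if (!is.null(cfg$stool_archetypes)) cfg$k_stool <- nrow(cfg$stool_archetypes)
  class(cfg) <- "cohort_sim_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- rep(0, length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

random_archetypes <- function(k, n_asvs, support_frac) {
  n_sup <- max(2L, round(support_frac * n_asvs))
  A <- matrix(0, k, n_asvs)
  for (a in seq_len(k)) {
    sup <- sample.int(n_asvs, n_sup)
    w <- stats::rgamma(n_sup, shape = 0.5, rate = 1)
    A[a, sup] <- w / sum(w)
  }
  A
}

#' Simulate a rooted phylogeny over the synthetic ASVs
#'
#' Random rooted binary topology with exponential(rate 1) branch lengths;
#' leaves are labeled `ASV0001 ...`.
#'
#' @param n_asvs number of leaves (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree with `n_asvs` leaves and `2 n_asvs - 2` edges.
#' @export
simulate_tree <- function(n_asvs, seed = 1) {
  if (n_asvs < 2) stop("a phylogeny needs at least 2 leaves")
  withr::with_seed(seed, {
    tree <- ape::rtree(n_asvs, rooted = TRUE, br = stats::rexp)
  })
  tree$tip.label <- sprintf("ASV%04d", seq_len(n_asvs))
  tree
}

#' Simulate a mother-infant cohort
#'
#' See [cohort_sim_config()] for the generative model. The returned truth
#' slot records every latent quantity needed for recovery tests: the per-dyad
#' realized transfer fraction, per-sample archetype labels and the config.
#'
#' @param config a [cohort_sim_config()].
#' @return list of class `simulated_cohort` with elements `milk_table`,
#'   `stool_table`, `metadata`, `taxonomy`, `tree`, `truth`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  if (!inherits(config, "cohort_sim_config")) {
    stop("config must come from cohort_sim_config()")
  }
  cfg <- config
  tree <- simulate_tree(cfg$n_asvs, seed = cfg$seed)
  asv_ids <- tree$tip.label
  withr::with_seed(cfg$seed + 1L, {
    A_milk <- if (is.null(cfg$milk_archetypes)) {
      random_archetypes(cfg$k_milk, cfg$n_asvs, cfg$archetype_support_frac)
    } else cfg$milk_archetypes
    A_stool <- if (is.null(cfg$stool_archetypes)) {
      random_archetypes(cfg$k_stool, cfg$n_asvs, cfg$archetype_support_frac)
    } else cfg$stool_archetypes

    genus <- sprintf("G%02d", sample.int(cfg$n_genera, cfg$n_asvs, replace = TRUE))
    fam_of_genus <- sprintf("F%02d",
                            sample.int(cfg$n_families, cfg$n_genera, replace = TRUE))
    taxonomy <- data.frame(asv_id = asv_ids, genus = genus,
                           family = fam_of_genus[as.integer(substring(genus, 2))],
                           stringsAsFactors = FALSE)

    tps <- cfg$timepoints[order(timepoint_rank(cfg$timepoints))]
    meta_rows <- list(); milk_rows <- list(); stool_rows <- list()
    truth_dyads <- list(); truth_samples <- list()

    for (d in seq_len(cfg$n_dyads)) {
      dyad_id <- sprintf("D%03d", d)
      delivery <- if (stats::runif(1) < cfg$p_cesarean) "cesarean" else "vaginal"
      sex <- if (stats::runif(1) < cfg$p_male) "male" else "female"
      u <- stats::runif(1)
      formula <- if (u < cfg$p_formula_yes) "yes" else
        if (u < cfg$p_formula_yes + cfg$p_formula_missing) "missing" else "no"
      bmi <- round(stats::rnorm(1, 25.9, 4.5), 1)
      mage <- round(stats::rnorm(1, 31.9, 4.2), 1)
      abx <- if (stats::runif(1) < cfg$p_prenatal_abx) "yes" else "no"

      s_prime <- cfg$transfer_fraction +
        (delivery == "cesarean") * cfg$effect_cesarean +
        (sex == "male") * cfg$effect_male +
        (formula == "yes") * cfg$effect_formula +
        stats::rnorm(1, 0, cfg$s_dyad_sd)
      s_prime <- min(1, max(0, s_prime))

      visit <- stats::runif(length(tps)) < cfg$timepoint_probs[tps]
      if (!any(visit)) visit[1] <- TRUE
      vtps <- tps[visit]

      arch_m <- integer(0); arch_s <- integer(0)
      milk_comp <- list(); milk_counts <- list()
      for (j in seq_along(vtps)) {
        arch_m[j] <- if (j == 1) sample.int(cfg$k_milk, 1) else
          maybe_switch(arch_m[j - 1], cfg$k_milk, cfg$archetype_switch_prob)
        arch_s[j] <- if (j == 1) sample.int(cfg$k_stool, 1) else
          maybe_switch(arch_s[j - 1], cfg$k_stool, cfg$archetype_switch_prob)
        milk_comp[[j]] <- rdirichlet1(cfg$dirichlet_concentration * A_milk[arch_m[j], ])
        depth <- max(1L, round(stats::rlnorm(1, cfg$depth_log_mean, cfg$depth_log_sd)))
        milk_counts[[j]] <- as.integer(stats::rmultinom(1, depth, milk_comp[[j]]))
      }
      for (j in seq_along(vtps)) {
        src <- if (cfg$transfer_lag == 1 && j > 1) j - 1 else j
        present <- milk_counts[[src]] > 0
        m_r <- milk_comp[[src]] * present
        m_r <- if (sum(m_r) > 0) m_r / sum(m_r) else m_r
        g <- rdirichlet1(cfg$dirichlet_concentration * A_stool[arch_s[j], ])
        q <- s_prime * m_r + (1 - s_prime) * g
        depth <- max(1L, round(stats::rlnorm(1, cfg$depth_log_mean, cfg$depth_log_sd)))
        stool_counts <- as.integer(stats::rmultinom(1, depth, q))

        tp <- vtps[j]
        age <- max(0, round(TIMEPOINT_AGE_DAYS[tp] + stats::rnorm(1, 0, 3)))
        for (comp in c("milk", "stool")) {
          sid <- sprintf("%s_%s_%s", dyad_id, comp, tp)
          meta_rows[[length(meta_rows) + 1L]] <- data.frame(
            sample_id = sid, dyad_id = dyad_id, compartment = comp,
            timepoint = tp, age_days = age, delivery_mode = delivery,
            infant_sex = sex, formula_exposed = formula, maternal_bmi = bmi,
            maternal_age = mage, prenatal_antibiotics = abx,
            stringsAsFactors = FALSE)
          truth_samples[[length(truth_samples) + 1L]] <- data.frame(
            sample_id = sid, compartment = comp,
            archetype = if (comp == "milk") arch_m[j] else arch_s[j],
            stringsAsFactors = FALSE)
        }
        milk_rows[[sprintf("%s_milk_%s", dyad_id, tp)]] <- milk_counts[[j]]
        stool_rows[[sprintf("%s_stool_%s", dyad_id, tp)]] <- stool_counts
      }
      truth_dyads[[d]] <- data.frame(
        dyad_id = dyad_id, s_prime = s_prime, delivery_mode = delivery,
        infant_sex = sex, formula_exposed = formula,
        prenatal_antibiotics = abx, stringsAsFactors = FALSE)
    }
  })
  milk_table <- do.call(rbind, milk_rows)
  stool_table <- do.call(rbind, stool_rows)
  colnames(milk_table) <- colnames(stool_table) <- asv_ids
  cohort <- list(
    milk_table = validate_count_table(milk_table),
    stool_table = validate_count_table(stool_table),
    metadata = validate_metadata(do.call(rbind, meta_rows)),
    taxonomy = taxonomy,
    tree = tree,
    truth = list(dyads = do.call(rbind, truth_dyads),
                 samples = do.call(rbind, truth_samples),
                 milk_archetypes = A_milk, stool_archetypes = A_stool,
                 config = cfg))
  class(cohort) <- "simulated_cohort"
  cohort
}

maybe_switch <- function(current, k, prob) {
  if (k == 1 || stats::runif(1) >= prob) return(current)
  others <- setdiff(seq_len(k), current)
  others[sample.int(length(others), 1)]
}

#' @method print simulated_cohort
#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated mother-infant cohort:",
      nrow(x$truth$dyads), "dyads,",
      nrow(x$milk_table), "milk and", nrow(x$stool_table), "stool samples,",
      ncol(x$milk_table), "ASVs\n")
  invisible(x)
}
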