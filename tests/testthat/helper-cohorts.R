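# Small cohort configurations used across tests. Sizes are simulation-study
# choices documented in the methods vignette.

small_cohort_config <- function(seed, n_dyads = 30, n_asvs = 80, s = 0.3, ...) {
  cohort_sim_config(n_dyads = n_dyads, n_asvs = n_asvs,
                    timepoints = "6w", timepoint_probs = c("6w" = 1),
                    transfer_fraction = s,
                    depth_log_mean = log(20000), depth_log_sd = 0.5,
                    seed = seed, ...)
}

# Global-null cohort: no transfer, no covariate effects, archetypes assigned
# independently of dyad identity.
null_cohort_config <- function(seed, n_dyads = 40, n_asvs = 80) {
  small_cohort_config(seed, n_dyads = n_dyads, n_asvs = n_asvs, s = 0,
                      effect_cesarean = 0, effect_male = 0, effect_formula = 0,
                      s_dyad_sd = 0)
}

# Disjoint-support archetypes: milk archetypes live on the first half of the
# ASVs, stool archetypes on the second half, so the observed overlap equals
# the realized transfer fraction exactly.
disjoint_archetypes <- function(k_milk, k_stool, n_asvs, seed) {
  withr::with_seed(seed, {
    half <- n_asvs %/% 2
    mk <- matrix(0, k_milk, n_asvs)
    st <- matrix(0, k_stool, n_asvs)
    for (a in seq_len(k_milk)) {
      sup <- sample(seq_len(half), max(2, round(0.5 * half)))
      w <- stats::rgamma(length(sup), 0.5)
      mk[a, sup] <- w / sum(w)
    }
    for (a in seq_len(k_stool)) {
      sup <- sample((half + 1):n_asvs, max(2, round(0.5 * half)))
      w <- stats::rgamma(length(sup), 0.5)
      st[a, sup] <- w / sum(w)
    }
    list(milk = mk, stool = st)
  })
}

tiny_meta <- function() {
  data.frame(
    sample_id = c("m1", "m2", "s1", "s2", "s3"),
    dyad_id = c("d1", "d1", "d1", "d1", "d1"),
    compartment = c("milk", "milk", "stool", "stool", "stool"),
    timepoint = c("6w", "4m", "6w", "4m", "6m"),
    age_days = c(42, 120, 42, 120, 180),
    delivery_mode = "vaginal", infant_sex = "male", formula_exposed = "no",
    maternal_bmi = 24, maternal_age = 30, prenatal_antibiotics = "no",
    stringsAsFactors = FALSE)
}
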