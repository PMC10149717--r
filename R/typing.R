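#' Partitioning around medoids (exact on small instances, BUILD + SWAP above)
#'
#' K-medoids on a precomputed dissimilarity matrix. When the medoid-set
#' space is small (`choose(n, k) <= exact_budget`, default 2000) the globally optimal
#' medoid set is found by exhaustive enumeration; above that budget
#' classical PAM is used: greedy BUILD initialization, then SWAP steps
#' applying the single (medoid, non-medoid) exchange with the largest cost
#' decrease until no exchange improves the total cost. Single-swap local
#' search can terminate in a local optimum (the reference implementation
#' does too, on the same instances), which is why small problems are solved
#' exactly. Either way the result is deterministic: ties in assignment
#' break toward the lower medoid index, ties between equally good medoid
#' sets toward lower indices. Total cost is the sum over samples of the
#' distance to their cluster's medoid.
#'
#' @param D validated distance matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed unused (the algorithm is deterministic); kept so call sites
#'   can treat all clustering entry points uniformly.
#' @param exact_budget largest `choose(n, k)` solved by enumeration.
#' @return list of class `pam_clustering`: `labels` (named integer vector in
#'   1..k), `medoid_ids`, `k`, `total_cost`, `iterations`, `exact`.
#' @export
pam_cluster <- function(D, k, seed = 1, exact_budget = 2000) {
  validate_distance_matrix(D)
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must lie in [1, n_samples]")
  nearest <- function(med) do.call(pmin, lapply(med, function(m) D[, m]))
  cost_of <- function(med) sum(nearest(med))
  if (choose(n, k) <= exact_budget) {
    sets <- utils::combn(n, k)
    costs <- vapply(seq_len(ncol(sets)), function(j) cost_of(sets[, j]),
                    numeric(1))
    med <- sets[, which.min(costs)]  # which.min: lexicographically first tie
    labels <- apply(D[, med, drop = FALSE], 1, which.min)
    names(labels) <- rownames(D)
    return(structure(list(labels = labels, medoid_ids = rownames(D)[med],
                          k = k, total_cost = cost_of(med), iterations = 0L,
                          exact = TRUE),
                     class = "pam_clustering"))
  }
  # BUILD: first medoid minimizes total distance; then greedy gain
  med <- which.min(rowSums(D))
  while (length(med) < k) {
    dn <- nearest(med)  # current nearest-medoid dist
    gain <- vapply(seq_len(n), function(cand) {
      if (cand %in% med) return(-Inf)
      sum(pmax(dn - D[, cand], 0))
    }, numeric(1))
    med <- c(med, which.max(gain))
  }
  cost <- cost_of(med)
  it <- 0L
  repeat {
    it <- it + 1L
    best <- list(delta = 0, med = med)
    for (mi in seq_along(med)) {
      for (cand in seq_len(n)) {
        if (cand %in% med) next
        trial <- med; trial[mi] <- cand
        delta <- cost_of(trial) - cost
        if (delta < best$delta - 1e-12) best <- list(delta = delta, med = trial)
      }
    }
    if (best$delta >= 0) break
    stopifnot(cost_of(best$med) <= cost)  # SWAP never increases cost
    med <- best$med
    cost <- cost_of(med)
  }
  med <- sort(med)
  labels <- apply(D[, med, drop = FALSE], 1, which.min)  # first = lower medoid
  names(labels) <- rownames(D)
  structure(list(labels = labels, medoid_ids = rownames(D)[med], k = k,
                 total_cost = cost_of(med), iterations = it, exact = FALSE),
            class = "pam_clustering")
}

#' Mean silhouette width of a clustering
#'
#' Quantitative surrogate for "least overlap on PCoA plots": higher mean
#' silhouette means better-separated clusters. `NA` for k = 1 (undefined).
#'
#' @param D validated distance matrix.
#' @param labels integer cluster labels aligned with `D`'s rows.
#' @return mean silhouette width, or `NA` when fewer than 2 clusters.
#' @export
mean_silhouette <- function(D, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(labels), dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Gap statistic for choosing the number of clusters
#'
#' `Gap(k) = mean_b log(W*_kb) - log(W_k)` where `W` is the within-cluster
#' dispersion `sum_r (1/(2 n_r)) sum_{i,j in C_r} d_ij^2` under PAM labels.
#' Reference datasets are drawn uniformly over the bounding box of the PCoA
#' embedding of `D` (distances are the primitive here, not raw features).
#' `s_k` carries the `sqrt(1 + 1/B)` simulation-error factor.
#'
#' The suggested k uses [cluster::maxSE()]. The default rule,
#' `"globalSEmax"`, takes the smallest k whose gap is within one `s_k` of
#' the global maximum; the classical one-SE-of-the-next rule
#' (`"Tibs2001SEmax"`, smallest k with `Gap(k) >= Gap(k+1) - s_{k+1}`) is
#' available but both it and `"firstSEmax"` degenerate toward k = 1 when
#' clusters are so separated that the gap curve is flat below the true k.
#'
#' @param D validated distance matrix.
#' @param k_range candidate cluster counts (within `[1, n - 1]`).
#' @param n_reference number of reference datasets B (>= 10 recommended).
#' @param seed integer seed for the reference draws.
#' @param rule k-selection rule passed to [cluster::maxSE()].
#' @return list of class `gap_statistic`: data.frame `table` (k, gap, s_k,
#'   log_w), `suggested_k`, `n_reference`, `rule`.
#' @export
gap_statistic <- function(D, k_range = 1:8, n_reference = 20, seed = 1,
                          rule = c("globalSEmax", "firstSEmax", "Tibs2001SEmax",
                                   "firstmax", "globalmax")) {
  rule <- match.arg(rule)
  validate_distance_matrix(D)
  n <- nrow(D)
  if (max(D) == 0) stop("gap statistic undefined for all-identical data")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > n - 1) stop("k_range must lie in [1, n-1]")
  emb <- pcoa(D, n_axes = min(n - 1, max(2, sum(pcoa(D, 2)$relative_eig > 0.01))))
  Y <- emb$coordinates
  lo <- apply(Y, 2, min); hi <- apply(Y, 2, max)

  wk <- function(Dm, labels) {
    sum(vapply(split(seq_along(labels), labels), function(ix) {
      sum(Dm[ix, ix, drop = FALSE]^2) / (2 * length(ix))
    }, numeric(1)))
  }
  log_w <- vapply(k_range, function(k) log(wk(D, pam_cluster(D, k)$labels)),
                  numeric(1))
  log_wstar <- matrix(NA_real_, n_reference, length(k_range))
  withr::with_seed(seed, {
    for (b in seq_len(n_reference)) {
      Z <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
      DZ <- as.matrix(stats::dist(Z))
      dimnames(DZ) <- list(rownames(D), rownames(D))
      for (ki in seq_along(k_range)) {
        log_wstar[b, ki] <- log(wk(DZ, pam_cluster(DZ, k_range[ki])$labels))
      }
    }
  })
  gap <- colMeans(log_wstar) - log_w
  s_k <- apply(log_wstar, 2, stats::sd) * sqrt(1 + 1 / n_reference)
  suggested <- k_range[cluster::maxSE(gap, s_k, method = rule)]
  structure(list(table = data.frame(k = k_range, gap = gap, s_k = s_k,
                                    log_w = log_w),
                 suggested_k = suggested, n_reference = n_reference,
                 rule = rule),
            class = "gap_statistic")
}

#' Assign microbiome types by PAM at an analyst-chosen k
#'
#' The number of types is an explicit analyst input (community typing on
#' ordination plots is a visual call); the result bundles gap-statistic
#' diagnostics and the mean silhouette width as quantitative guidance.
#'
#' @param D validated distance matrix.
#' @param k number of microbiome types.
#' @param seed seed for the gap-statistic reference draws.
#' @param gap_k_range candidate k values for the diagnostic (`NULL` skips it).
#' @param n_reference reference datasets for the gap diagnostic.
#' @return `pam_clustering` with extra fields `silhouette` and `gap`.
#' @export
assign_microbiome_types <- function(D, k, seed = 1, gap_k_range = NULL,
                                    n_reference = 20) {
  fit <- pam_cluster(D, k, seed = seed)
  fit$silhouette <- mean_silhouette(D, fit$labels)
  fit$gap <- if (!is.null(gap_k_range)) {
    gap_statistic(D, k_range = gap_k_range, n_reference = n_reference, seed = seed)
  }
  fit
}

#' Kruskal-Wallis test of a diversity metric across clusters
#'
#' @param values per-sample metric (e.g. Simpson's diversity).
#' @param labels cluster labels, at least 2 non-empty clusters.
#' @return list with `H` (tie-corrected statistic), `p` (chi-square
#'   approximation), `df`, per-cluster `medians`.
#' @export
diversity_by_cluster_test <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 clusters")
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, df = nlevels(droplevels(labels)) - 1,
                medians = tapply(values, labels, stats::median)))
  }
  kt <- stats::kruskal.test(values, labels)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter),
       medians = tapply(values, labels, stats::median))
}
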