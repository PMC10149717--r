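#' Branch decomposition of community profiles on a phylogeny
#'
#' For each branch i of the rooted tree (the root itself has no branch) and
#' each sample A, computes the subtree proportion
#' `p[A, i] = sum of relative abundances of leaves descending from i`,
#' by a single post-order accumulation. This is the decomposition the
#' generalized UniFrac distance is built on.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param prop samples x leaves relative-abundance matrix (column names must
#'   be a subset relation: every profile column must be a tree leaf; tree
#'   leaves absent from the profile count as zero).
#' @return list with `p` (samples x branches matrix) and `b` (branch lengths,
#'   one per column of `p`).
#' @export
branch_proportions <- function(tree, prop) {
  validate_tree(tree)
  if (!is.matrix(prop)) prop <- matrix(prop, 1, dimnames = list("s", names(prop)))
  extra <- setdiff(colnames(prop), tree$tip.label)
  if (length(extra)) {
    stop("profile taxa absent from the tree: ", paste(extra, collapse = ", "))
  }
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  V <- matrix(0, nrow(prop), nnode)
  idx <- match(tr$tip.label, colnames(prop))
  has <- !is.na(idx)
  V[, which(has)] <- prop[, idx[has], drop = FALSE]
  for (i in seq_len(nrow(tr$edge))) {
    V[, tr$edge[i, 1]] <- V[, tr$edge[i, 1]] + V[, tr$edge[i, 2]]
  }
  p <- V[, tr$edge[, 2], drop = FALSE]
  rownames(p) <- rownames(prop)
  list(p = p, b = tr$edge.length)
}

#' Generalized UniFrac distance between two branch-decomposed samples
#'
#' `d = sum_i b_i (pA_i + pB_i)^alpha |pA_i - pB_i| / (pA_i + pB_i) /
#'      sum_i b_i (pA_i + pB_i)^alpha`,
#' over branches with `pA_i + pB_i > 0` (branches unoccupied by both samples
#' are excluded from both sums). `alpha` in \[0, 1\] interpolates between
#' presence-weighted (0) and abundance-weighted (1) UniFrac; 0.5 gives the
#' moderate weighting of rare and abundant lineages used for typing.
#'
#' @param pA,pB branch-proportion vectors from [branch_proportions()] on the
#'   same tree.
#' @param b branch lengths aligned with `pA`/`pB`.
#' @param alpha weighting exponent in \[0, 1\].
#' @return distance in \[0, 1\].
#' @export
gunifrac_pair <- function(pA, pB, b, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  tot <- pA + pB
  occ <- tot > 0
  if (!any(occ)) stop("both profiles are empty")
  w <- b[occ] * tot[occ]^alpha
  num <- sum(w * abs(pA[occ] - pB[occ]) / tot[occ])
  den <- sum(w)
  if (den == 0) return(0)
  num / den
}

#' Generalized UniFrac distance matrix
#'
#' Converts counts to per-sample proportions (unrarefied), decomposes them
#' on the tree, and computes all pairwise generalized UniFrac distances.
#'
#' @param counts samples x ASVs count matrix; every sample must be nonempty.
#' @param tree rooted phylogeny covering the table's ASVs.
#' @param alpha weighting exponent (default 0.5).
#' @return validated symmetric distance matrix with zero diagonal.
#' @export
gunifrac <- function(counts, tree, alpha = 0.5) {
  validate_count_table(counts)
  if (any(rowSums(counts) == 0)) {
    stop("empty sample(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  }
  prop <- relative_abundance(counts)
  bp <- branch_proportions(tree, prop)
  n <- nrow(prop)
  D <- matrix(0, n, n, dimnames = list(rownames(prop), rownames(prop)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- gunifrac_pair(bp$p[i, ], bp$p[j, ], bp$b, alpha)
    }
  }
  validate_distance_matrix(D)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centering of squared dissimilarities followed by eigen
#' decomposition. Coordinates are built from positive eigenvalues only;
#' negative eigenvalues (non-Euclidean input) are retained in the report but
#' never yield imaginary axes.
#'
#' @param D validated distance matrix.
#' @param n_axes number of axes to return (at most `n - 1`).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   ordered decreasing), `relative_eig` (over positive eigenvalues).
#' @export
pcoa <- function(D, n_axes = 2) {
  validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 samples")
  if (n_axes > n - 1) stop("n_axes must be at most n_samples - 1")
  B <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  ev <- eg$values
  pos <- which(ev > max(ev[1], 0) * 1e-12)
  k <- min(n_axes, length(pos))
  coords <- matrix(0, n, n_axes,
                   dimnames = list(rownames(D), paste0("PCo", seq_len(n_axes))))
  if (k > 0) {
    coords[, seq_len(k)] <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(ev[pos[seq_len(k)]]), k)
  }
  list(coordinates = coords, eigenvalues = ev,
       relative_eig = pmax(ev, 0) / sum(pmax(ev, 0)))
}
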