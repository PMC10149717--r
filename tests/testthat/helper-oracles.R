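# Independent oracles, deliberately coded along different paths than the
# implementations they check.

# GUniFrac by explicit descendant enumeration: for every edge, find its
# descendant leaf set by walking the edge list, sum leaf proportions, then
# apply the distance formula term by term.
oracle_gunifrac <- function(tree, propA, propB, alpha) {
  ntip <- length(tree$tip.label)
  desc_leaves <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_leaves))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- tree$tip.label[desc_leaves(tree$edge[e, 2])]
    pA <- sum(propA[leaves], na.rm = TRUE)
    pB <- sum(propB[leaves], na.rm = TRUE)
    tot <- pA + pB
    if (tot > 0) {
      w <- tree$edge.length[e] * tot^alpha
      num <- num + w * abs(pA - pB) / tot
      den <- den + w
    }
  }
  num / den
}

# Weighted normalized UniFrac from its own derivation (numerator over edges,
# denominator as leaf-depth weighted abundances); equals the alpha = 1 case.
oracle_weighted_unifrac <- function(tree, propA, propB) {
  ntip <- length(tree$tip.label)
  desc_leaves <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_leaves))
  }
  num <- 0
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- tree$tip.label[desc_leaves(tree$edge[e, 2])]
    num <- num + tree$edge.length[e] *
      abs(sum(propA[leaves], na.rm = TRUE) - sum(propB[leaves], na.rm = TRUE))
  }
  depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  names(depths) <- tree$tip.label
  den <- sum(depths * (propA[tree$tip.label] + propB[tree$tip.label]), na.rm = TRUE)
  num / den
}

# Exhaustive k-medoids: minimum total cost over all medoid subsets.
oracle_pam_exhaustive <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(D[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

random_profile <- function(leaves) {
  p <- stats::rexp(length(leaves))
  stats::setNames(p / sum(p), leaves)
}

random_instance_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE, br = stats::rexp)
  tr$tip.label <- paste0("L", seq_len(n_leaves))
  tr
}
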