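#' Ordered visit vocabulary
#'
#' The five-visit schedule used throughout: 6 weeks, 4, 6, 9 and 12 months.
#' The vocabulary is closed; metadata with any other code is rejected.
#'
#' @format Character vector of length 5, in visit order.
#' @export
TIMEPOINT_LEVELS <- c("6w", "4m", "6m", "9m", "12m")

#' Default target age (days since birth) for each visit
#' @format Named numeric vector over [TIMEPOINT_LEVELS].
#' @export
TIMEPOINT_AGE_DAYS <- c("6w" = 42, "4m" = 120, "6m" = 180, "9m" = 270,
                        "12m" = 365)

timepoint_rank <- function(tp) {
  r <- match(tp, TIMEPOINT_LEVELS)
  if (anyNA(r)) {
    stop("unknown timepoint code(s): ",
         paste(unique(tp[is.na(r)]), collapse = ", "))
  }
  r
}

#' Validate an ASV count table
#'
#' A count table is an integer matrix with samples as rows and ASVs as
#' columns (orientation is fixed; no transposition is attempted). Row and
#' column names must be unique and all entries non-negative integers.
#'
#' @param counts matrix of read counts, samples x ASVs.
#' @return The validated matrix (invisibly typed as integer-valued numeric).
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("count table must be a numeric matrix (samples x ASVs)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table must carry sample (row) and ASV (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids in count table")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids in count table")
  if (anyNA(counts)) stop("count table contains missing values")
  if (any(counts < 0)) stop("count table contains negative entries")
  if (any(counts != round(counts))) stop("count table contains non-integer entries")
  counts
}

#' Read an ASV count table from TSV
#'
#' First row holds ASV ids, first column holds sample ids; all remaining
#' cells must parse as non-negative integers.
#'
#' @param path path to a tab-separated file.
#' @return samples x ASVs integer matrix with dimnames.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty count table file: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2 || nrow(df) < 1) stop("count table needs >= 1 sample and >= 1 ASV")
  sample_ids <- df[[1]]
  asv_ids <- colnames(df)[-1]
  cells <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("cell at sample '%s', ASV '%s' does not parse as a count",
                 sample_ids[bad[1]], asv_ids[bad[2]]))
  }
  dimnames(num) <- list(sample_ids, asv_ids)
  validate_count_table(num)
}

#' Write an ASV count table as TSV
#'
#' Round-trips bit-identically with [read_count_table()].
#'
#' @param counts samples x ASVs matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree (newick)
#'
#' Leaf labels must be unique and all branch lengths non-negative;
#' zero-length branches are retained. Newick comments (`[...]`) are rejected.
#'
#' @param path path to a newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- paste(readLines(path, warn = FALSE), collapse = "")
  if (grepl("\\[", raw)) stop("newick comments are not supported")
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = raw)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("unparseable newick in ", path)
  validate_tree(tree)
}

#' Validate a phylogenetic tree for use as a UniFrac backbone
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly validated.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  tree
}

#' Write a tree as newick
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Required columns: `sample_id`, `dyad_id`, `compartment` (milk/stool),
#' `timepoint` (6w/4m/6m/9m/12m), `age_days`, plus the covariates
#' `delivery_mode` (vaginal/cesarean), `infant_sex` (male/female),
#' `formula_exposed` (yes/no/missing), `maternal_bmi`, `maternal_age`,
#' `prenatal_antibiotics` (yes/no). Missing formula status is an explicit
#' category, not NA.
#'
#' @param path path to a CSV file.
#' @return a data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(meta)
}

#' Validate a sample metadata table
#' @param meta data.frame as described in [read_metadata()].
#' @return the validated data.frame.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "dyad_id", "compartment", "timepoint", "age_days",
            "delivery_mode", "infant_sex", "formula_exposed",
            "maternal_bmi", "maternal_age", "prenatal_antibiotics")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (!all(meta$compartment %in% c("milk", "stool"))) {
    stop("compartment must be 'milk' or 'stool'")
  }
  timepoint_rank(meta$timepoint)
  if (any(meta$age_days < 0)) stop("age_days must be non-negative")
  if (!all(meta$delivery_mode %in% c("vaginal", "cesarean"))) {
    stop("delivery_mode must be 'vaginal' or 'cesarean'")
  }
  if (!all(meta$infant_sex %in% c("male", "female"))) {
    stop("infant_sex must be 'male' or 'female'")
  }
  if (!all(meta$formula_exposed %in% c("yes", "no", "missing"))) {
    stop("formula_exposed must be 'yes', 'no' or 'missing'")
  }
  if (!all(meta$prenatal_antibiotics %in% c("yes", "no"))) {
    stop("prenatal_antibiotics must be 'yes' or 'no'")
  }
  meta
}

#' Write sample metadata as CSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(validate_metadata(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASV taxonomy table from CSV
#'
#' Columns: `asv_id`, `family`, `genus`. Unassigned ranks must carry the
#' sentinel label `"unassigned"` (blank cells are converted to it).
#'
#' @param path path to a CSV file.
#' @return data.frame with one row per ASV.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("asv_id", "family", "genus")
  miss <- setdiff(need, colnames(tax))
  if (length(miss)) stop("taxonomy lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tax$asv_id)) stop("duplicate asv ids in taxonomy")
  for (rk in c("family", "genus")) {
    tax[[rk]][is.na(tax[[rk]]) | tax[[rk]] == ""] <- "unassigned"
  }
  tax
}

#' Validate a square distance matrix
#'
#' Symmetric within 1e-12, exactly zero diagonal, all entries non-negative.
#'
#' @param D square numeric matrix with matching dimnames.
#' @return the matrix, invisibly validated.
#' @export
validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    stop("distance matrix must carry identical row and column ids")
  }
  if (any(D < 0)) stop("negative dissimilarities")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be exactly zero")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric (tol 1e-12)")
  D
}

#' Read / write a distance matrix as square TSV
#'
#' Ids are stored in the first row and first column.
#'
#' @param path file path.
#' @return [read_distance_matrix()]: the validated matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE, row.names = 1)
  D <- as.matrix(df)
  colnames(D) <- colnames(df)
  validate_distance_matrix(D)
}

#' @param D validated square distance matrix.
#' @rdname read_distance_matrix
#' @export
write_distance_matrix <- function(D, path) {
  validate_distance_matrix(D)
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove samples with insufficient sequencing depth
#'
#' Samples with strictly fewer than `min_reads` total reads are dropped
#' ("fewer than" is strict: a sample at exactly the threshold is retained).
#' ASV columns are unchanged. Removed sample ids are reported via `message()`.
#'
#' @param counts samples x ASVs count matrix.
#' @param min_reads minimum acceptable library size (default 1000).
#' @return the filtered count matrix (possibly with zero rows).
#' @export
filter_low_depth_samples <- function(counts, min_reads = 1000) {
  validate_count_table(counts)
  stopifnot(min_reads >= 0)
  depth <- rowSums(counts)
  drop <- depth < min_reads
  if (any(drop)) {
    message("removed ", sum(drop), " low-depth sample(s): ",
            paste(rownames(counts)[drop], collapse = ", "))
  }
  counts[!drop, , drop = FALSE]
}

#' Dyad pairing index
#'
#' Enumerates all admissible (milk sample, stool sample) pairs within each
#' dyad: the stool sample must be collected at the same or a subsequent
#' visit, never before the milk sample. Every admissible pair is a row, so a
#' dyad with one milk and three later stool samples contributes three pairs.
#'
#' @param meta validated metadata covering both compartments.
#' @return data.frame with columns dyad_id, milk_sample, stool_sample,
#'   milk_timepoint, stool_timepoint.
#' @export
dyad_pairing <- function(meta) {
  meta <- validate_metadata(meta)
  milk <- meta[meta$compartment == "milk", ]
  stool <- meta[meta$compartment == "stool", ]
  out <- list()
  for (d in unique(meta$dyad_id)) {
    m <- milk[milk$dyad_id == d, ]
    s <- stool[stool$dyad_id == d, ]
    if (!nrow(m) || !nrow(s)) next
    grid <- expand.grid(mi = seq_len(nrow(m)), si = seq_len(nrow(s)))
    keep <- timepoint_rank(s$timepoint[grid$si]) >= timepoint_rank(m$timepoint[grid$mi])
    if (!any(keep)) next
    grid <- grid[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      dyad_id = d,
      milk_sample = m$sample_id[grid$mi],
      stool_sample = s$sample_id[grid$si],
      milk_timepoint = m$timepoint[grid$mi],
      stool_timepoint = s$timepoint[grid$si],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(dyad_id = character(), milk_sample = character(),
                      stool_sample = character(), milk_timepoint = character(),
                      stool_timepoint = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate a (count table, tree, metadata) triple
#'
#' Checks that every table ASV is a tree leaf and every table sample has a
#' metadata row; on success returns the triple together with the dyad
#' pairing index built from the metadata.
#'
#' @param counts samples x ASVs count matrix (may combine compartments).
#' @param tree phylogeny over (at least) the table's ASVs.
#' @param meta metadata covering (at least) the table's samples.
#' @return list with elements `counts`, `tree`, `meta`, `pairing`.
#' @export
align_table_tree_metadata <- function(counts, tree, meta) {
  validate_count_table(counts)
  validate_tree(tree)
  meta <- validate_metadata(meta)
  missing_leaves <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing_leaves)) {
    stop("ASV(s) absent from the tree: ", paste(missing_leaves, collapse = ", "))
  }
  missing_meta <- setdiff(rownames(counts), meta$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) without metadata: ", paste(missing_meta, collapse = ", "))
  }
  list(counts = counts, tree = tree, meta = meta, pairing = dyad_pairing(meta))
}
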