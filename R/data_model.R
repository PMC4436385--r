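# Core data structures: the labelled two-class feature table, the training-set
# size grid, and the run configuration shared by every stage of the pipeline.

#' Construct a two-class feature dataset
#'
#' The central container for a pilot (or validation) cohort: a numeric feature
#' matrix, a two-level class label per row, unique sample identifiers, and an
#' optional group identifier (patient or image) used for grouped two-stage
#' sampling of pixel- or voxel-level data.
#'
#' @param features numeric matrix (rows = samples, columns = features); all
#'   values must be finite.
#' @param label vector coercible to a factor with exactly two levels.
#' @param sample_id character vector of unique row identifiers; defaults to
#'   `"s1"`, `"s2"`, ...
#' @param group_id optional character vector of group (patient/image)
#'   identifiers; must be supplied for every row or none.
#' @param positive_class optional label level to treat as the first class
#'   (\eqn{\omega_1}); defaults to the lexicographically first level.
#' @return an object of class `feature_dataset`.
#' @export
feature_dataset <- function(features, label, sample_id = NULL, group_id = NULL,
                            positive_class = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || ncol(features) < 1L)
    stop("'features' must be a numeric matrix with at least one column")
  if (anyNA(features) || any(!is.finite(features)))
    stop("feature values must be finite; found NA/NaN/Inf in columns: ",
         paste(unique(colnames(features)[which(!is.finite(features), arr.ind = TRUE)[, 2]]),
               collapse = ", "))
  label <- as.character(label)
  if (length(label) != nrow(features))
    stop("'label' length (", length(label), ") != number of rows (", nrow(features), ")")
  lev <- sort(unique(label))
  if (length(lev) != 2L)
    stop("label must have exactly two levels, found ", length(lev), ": ",
         paste(lev, collapse = ", "))
  if (!is.null(positive_class)) {
    if (!positive_class %in% lev)
      stop("positive_class '", positive_class, "' is not a label level")
    lev <- c(positive_class, setdiff(lev, positive_class))
  }
  label <- factor(label, levels = lev)
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(features)))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (!is.null(group_id)) {
    group_id <- as.character(group_id)
    if (length(group_id) != nrow(features) || anyNA(group_id))
      stop("group_id must be all-or-none: every row needs a group id or none")
    }
  structure(
    list(features = features, label = label, sample_id = sample_id,
         group_id = group_id),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat("<feature_dataset> ", n_samples(x), " samples, ", ncol(x$features),
      " features\n", sep = "")
  cat("  classes: ", paste(sprintf("%s (%d)", levels(x$label), table(x$label)),
                           collapse = ", "), "\n", sep = "")
  if (!is.null(x$group_id))
    cat("  groups:  ", length(unique(x$group_id)), "\n", sep = "")
  invisible(x)
}

#' Number of samples in a feature dataset
#' @param data a `feature_dataset`.
#' @return integer row count.
#' @export
n_samples <- function(data) nrow(data$features)

#' Subset a feature dataset by row indices
#' @param data a `feature_dataset`.
#' @param idx integer row indices.
#' @return a `feature_dataset` restricted to `idx` (row order follows `idx`).
#' @export
subset_rows <- function(data, idx) {
  structure(
    list(features = data$features[idx, , drop = FALSE],
         label = data$label[idx],
         sample_id = data$sample_id[idx],
         group_id = if (is.null(data$group_id)) NULL else data$group_id[idx]),
    class = "feature_dataset"
  )
}

#' Read a feature table from delimited text
#'
#' Loads a CSV with a header row into a validated [feature_dataset()]. Column
#' roles are declared explicitly so exported CAD feature tables can be mapped
#' without editing the file.
#'
#' @param path path to a CSV file.
#' @param sample_id,label,group_id column names holding the row identifier,
#'   the class label, and (optionally) the group identifier.
#' @param features character vector of feature column names; by default every
#'   column not assigned another role.
#' @param positive_class optional level to treat as \eqn{\omega_1}.
#' @return a `feature_dataset`.
#' @export
load_feature_table <- function(path, sample_id = "sample_id", label = "label",
                               group_id = NULL, features = NULL,
                               positive_class = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(sample_id, label, group_id))
    if (!col %in% names(tab)) stop("missing column '", col, "' in ", path)
  if (is.null(features))
    features <- setdiff(names(tab), c(sample_id, label, group_id))
  missing_feat <- setdiff(features, names(tab))
  if (length(missing_feat))
    stop("missing feature columns: ", paste(missing_feat, collapse = ", "))
  for (col in features)
    if (!is.numeric(tab[[col]]))
      stop("feature column '", col, "' is not numeric")
  gid <- if (is.null(group_id)) NULL else {
    g <- as.character(tab[[group_id]])
    g[!nzchar(g)] <- NA_character_
    if (anyNA(g) && !all(is.na(g)))
      stop("group_id must be all-or-none: column '", group_id,
           "' has missing values in rows ",
           paste(head(which(is.na(g)), 5), collapse = ", "))
    if (all(is.na(g))) NULL else g
  }
  feature_dataset(as.matrix(tab[, features, drop = FALSE]),
                  label = tab[[label]], sample_id = tab[[sample_id]],
                  group_id = gid, positive_class = positive_class)
}

#' Write a feature dataset to CSV
#'
#' Round-trips through [load_feature_table()]: identifiers, labels and
#' features are preserved exactly up to decimal formatting of the features.
#'
#' @param data a `feature_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  tab <- data.frame(sample_id = data$sample_id, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(data$group_id)) tab$group_id <- data$group_id
  tab$label <- as.character(data$label)
  feat <- data$features
  if (is.null(colnames(feat))) colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  tab <- cbind(tab, as.data.frame(feat))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Construct a training-set size grid
#'
#' @param sizes strictly increasing positive integers, the sizes
#'   \eqn{N = \{n_1, \dots, n_N\}} at which error rates are estimated.
#' @return an integer vector of class `size_grid`.
#' @export
size_grid <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || anyNA(sizes) || any(sizes < 1L))
    stop("sizes must be positive integers")
  if (any(diff(sizes) <= 0L)) stop("sizes must be strictly increasing")
  structure(sizes, class = "size_grid")
}

#' Check that every size fits the available training pool
#'
#' Each training-set size must satisfy \eqn{1 \le n \le |N|} for the smallest
#' training pool it will be used with (pool of samples, or of groups when
#' sampling is grouped).
#'
#' @param grid a [size_grid()].
#' @param pool_size size of the smallest training pool under the chosen
#'   K-fold partition.
#' @return `grid`, unchanged, if feasible; otherwise an error listing the
#'   infeasible sizes.
#' @export
validate_size_grid <- function(grid, pool_size) {
  if (!inherits(grid, "size_grid")) grid <- size_grid(grid)
  bad <- grid[grid > pool_size]
  if (length(bad))
    stop("training-set sizes exceed the training pool (", pool_size, "): ",
         paste(bad, collapse = ", "))
  grid
}

#' Configuration for a repeated-random-sampling run
#'
#' Bundles the resampling protocol parameters. The defaults reproduce the
#' standard protocol: `K = 4` folds, `R = 10` cross-validation repeats,
#' `T1 = 50` subsampling trials per size, `T2 = 50` permutation trials per
#' subsampling trial, significance level 0.05.
#'
#' @param K number of cross-validation folds (>= 2).
#' @param R number of cross-validation repeats (>= 1).
#' @param T1 subsampling trials per training-set size (>= 1).
#' @param T2 permutation trials per subsampling trial (>= 1).
#' @param alpha significance level for the permutation filter, in (0, 1).
#' @param classifier a [classifier_spec()].
#' @param seed root RNG seed; all stage seeds are derived from it.
#' @param grouped logical; partition and subsample at the group (patient)
#'   level, training and testing on all rows (pixels/metavoxels) of the
#'   selected groups.
#' @param stratified_subsets draw training subsets class-stratified (default);
#'   see Details.
#' @param run_permutation compute the permutation null alongside the actual
#'   errors (default `TRUE`).
#' @param null_subsets `"fresh"` draws a new random subset of the training
#'   pool for every null replicate (default); `"same"` reuses the rows of the
#'   corresponding actual subset.
#' @param null_labels `"permute"` shuffles the subset's true labels,
#'   preserving class proportions (default); `"iid"` assigns labels by fair
#'   coin flips.
#'
#' @details Subsets are drawn class-stratified by default because the
#'   framework targets class-balanced pilot cohorts and trains at sizes small
#'   enough that unstratified draws would frequently be single-class and
#'   untrainable. Unstratified draws are retried (up to 100 times) when they
#'   come out single-class.
#'
#' @return an object of class `rrs_config`.
#' @export
rrs_config <- function(K = 4L, R = 10L, T1 = 50L, T2 = 50L, alpha = 0.05,
                       classifier = classifier_spec("knn"), seed = 1L,
                       grouped = FALSE, stratified_subsets = TRUE,
                       run_permutation = TRUE,
                       null_subsets = c("fresh", "same"),
                       null_labels = c("permute", "iid")) {
  K <- as.integer(K); R <- as.integer(R)
  T1 <- as.integer(T1); T2 <- as.integer(T2)
  if (is.na(K) || K < 2L) stop("K must be an integer >= 2")
  if (is.na(R) || R < 1L) stop("R must be an integer >= 1")
  if (is.na(T1) || T1 < 1L) stop("T1 must be an integer >= 1")
  if (is.na(T2) || T2 < 1L) stop("T2 must be an integer >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!inherits(classifier, "classifier_spec"))
    stop("'classifier' must be a classifier_spec")
  structure(
    list(K = K, R = R, T1 = T1, T2 = T2, alpha = alpha,
         classifier = classifier, seed = as.integer(seed),
         grouped = isTRUE(grouped),
         stratified_subsets = isTRUE(stratified_subsets),
         run_permutation = isTRUE(run_permutation),
         null_subsets = match.arg(null_subsets),
         null_labels = match.arg(null_labels)),
    class = "rrs_config"
  )
}

#' @export
print.rrs_config <- function(x, ...) {
  cat("<rrs_config> K=", x$K, " R=", x$R, " T1=", x$T1, " T2=", x$T2,
      " alpha=", x$alpha, " seed=", x$seed,
      if (x$grouped) " [grouped]" else "", "\n", sep = "")
  cat("  classifier: ", format(x$classifier), "\n", sep = "")
  invisible(x)
}
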