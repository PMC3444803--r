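# Iterative linear-SVM-weight feature selection with group merging:
# append one feature group at a time, grid-search C by internal 10-fold
# CV, train, rank by |w|, keep the top half (ceiling), merge with the
# next group.  Groups flagged as whole-brain-scale are appended without
# the drop step (they contribute too few features to thin further).

#' Rank features by absolute linear-SVM weight
#'
#' @param model a `linear_svm` fit.
#' @return permutation of `seq_along(w)`: indices sorted by `|w|`
#'   descending, ties broken by ascending original index.
#' @export
rank_by_weight <- function(model) {
  stopifnot(inherits(model, "linear_svm"))
  if (length(model$w) == 0L) stop("model has no features")
  order(-abs(model$w))  # stable sort: ties keep ascending original index
}

#' Keep the top half of a feature ordering
#'
#' @param ordering permutation of `1..n_features` (best first).
#' @param n_features total feature count.
#' @return the first `ceiling(n_features / 2)` indices of `ordering`.
#' @export
keep_top_half <- function(ordering, n_features = length(ordering)) {
  if (length(ordering) != n_features ||
      !setequal(ordering, seq_len(n_features)))
    stop("ordering must be a permutation of 1..n_features")
  ordering[seq_len(ceiling(n_features / 2))]
}

#' Iterative SVM-weight feature selection over feature groups
#'
#' Processes feature groups in order.  For each group: append its columns
#' to the current survivor set, find the best penalty C by grid search
#' with internal 10-fold cross-validation, train a linear SVM with that C,
#' rank the current columns by absolute weight, and keep the top half
#' (ceiling).  Groups flagged `whole_brain` are appended without the drop
#' step.  Deterministic given `seed`.
#'
#' Run this on training data only; nesting it inside each outer
#' cross-validation fold (see [cross_validate()]) is what keeps the
#' reported accuracy honest.
#'
#' @param X subjects x features matrix (training split).
#' @param y two-class labels.
#' @param groups list of disjoint column-index vectors, in merge order.
#' @param whole_brain logical per group (default all FALSE): append
#'   without dropping.
#' @param C_grid penalty candidates for each internal grid search.
#' @param seed seed for the internal fold plans.
#' @param subject_ids optional row ids; internal grid-search folds are
#'   keyed to them (row-permutation invariance).
#' @return list with `selected` (surviving column indices of `X`, in
#'   ranked order from the last iteration), `X` (reduced matrix),
#'   `C` (best C of the final iteration), `weights` (|w| of the survivors
#'   at selection time), `history` (survivor count after each group).
#' @export
combine_groups <- function(X, y, groups, whole_brain = NULL,
                           C_grid = default_C_grid(), seed = 1L,
                           subject_ids = NULL) {
  X <- as.matrix(X)
  if (length(groups) == 0L) stop("need at least one feature group")
  if (any(lengths(groups) == 0L)) stop("empty feature group")
  all_cols <- unlist(groups)
  if (anyDuplicated(all_cols)) stop("feature groups must be disjoint")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (is.null(whole_brain)) whole_brain <- rep(FALSE, length(groups))
  if (length(whole_brain) != length(groups))
    stop("whole_brain flags must match the number of groups")

  current <- integer(0)
  history <- integer(length(groups))
  best_C <- NA_real_
  absw <- numeric(0)
  for (k in seq_along(groups)) {
    current <- c(current, as.integer(groups[[k]]))
    Xk <- X[, current, drop = FALSE]
    gs <- grid_search_C(Xk, y, C_grid, seed = derive_seed(seed, k),
                        subject_ids = subject_ids)
    best_C <- gs$best_C
    m <- train_linear_svm(Xk, y, best_C)
    ord <- rank_by_weight(m)
    if (!whole_brain[k]) ord <- keep_top_half(ord, length(current))
    absw <- abs(m$w)[ord]
    current <- current[ord]
    history[k] <- length(current)
  }
  list(selected = current, X = X[, current, drop = FALSE], C = best_C,
       weights = absw, history = history)
}

#' Expected survivor counts of the iterative halving recurrence
#'
#' `s_0 = 0; s_k = ceiling((s_{k-1} + n_k) / 2)` for unflagged groups,
#' `s_k = s_{k-1} + n_k` for whole-brain-flagged ones.
#'
#' @param group_sizes integer vector of group sizes, in merge order.
#' @param whole_brain logical flags per group.
#' @return integer vector `s_1..s_K`.
#' @export
selection_cardinality <- function(group_sizes,
                                  whole_brain = rep(FALSE,
                                                    length(group_sizes))) {
  s <- 0L
  out <- integer(length(group_sizes))
  for (k in seq_along(group_sizes)) {
    s <- if (whole_brain[k]) s + group_sizes[k]
         else as.integer(ceiling((s + group_sizes[k]) / 2))
    out[k] <- s
  }
  out
}

#' Write a selected-feature manifest as TSV
#'
#' @param selection result of [combine_groups()].
#' @param meta per-column metadata for the full matrix (see
#'   [write_feature_table()]); may be NULL.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_manifest <- function(selection, meta = NULL, path) {
  df <- data.frame(column = selection$selected,
                   abs_weight = selection$weights)
  if (!is.null(meta))
    df$feature <- feature_column_names(meta)[selection$selected]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
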