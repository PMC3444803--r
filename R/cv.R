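# Cross-validated evaluation: fold plans, grid-searched C, pooled
# held-out accuracy, and the reference connectivity features.

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# deterministic child seed, kept below 2^31
derive_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed) %% 2147483647
  for (x in k) s <- (s * 48271 + as.double(x) + 1) %% 2147483647
  as.integer(s)
}

#' Build a cross-validation fold plan
#'
#' Subjects are shuffled with the given seed and dealt into `n_folds`
#' folds whose sizes differ by at most one (the first `N %% n_folds`
#' folds get the extra subject).  The shuffle operates on the *sorted*
#' subject ids, so a subject's fold depends only on the id set and the
#' seed, never on the order the subjects are supplied in.  Optionally
#' stratified by class so every fold keeps the overall class balance.
#'
#' @param subject_ids vector of unique subject identifiers.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed; the same seed always yields the same plan.
#' @param stratify_by optional class vector aligned with `subject_ids`.
#' @return An object of class `cv_plan`: list with `assignment`
#'   (data.frame `subject_id`, `fold`, input order), `n_folds`, `seed`.
#' @export
make_cv_plan <- function(subject_ids, n_folds = 10L, seed = 1L,
                         stratify_by = NULL) {
  n <- length(subject_ids)
  n_folds <- as.integer(n_folds)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (n < n_folds)
    stop("need at least n_folds = ", n_folds, " subjects, got ", n)
  fold <- integer(n)
  # canonical (sorted-id) order, then a seeded shuffle of that order
  pos_sorted <- order(subject_ids)[with_seed(seed, sample.int(n))]
  if (is.null(stratify_by)) {
    sizes <- rep(n %/% n_folds, n_folds) +
      (seq_len(n_folds) <= n %% n_folds)
    fold[pos_sorted] <- rep.int(seq_len(n_folds), sizes)
  } else {
    # deal each class round-robin, continuing the fold counter across
    # classes so sizes stay balanced overall
    nxt <- 0L
    for (cl in sort(unique(stratify_by))) {
      members <- pos_sorted[stratify_by[pos_sorted] == cl]
      fold[members] <- (nxt + seq_along(members) - 1L) %% n_folds + 1L
      nxt <- (nxt + length(members)) %% n_folds
    }
  }
  structure(list(assignment = data.frame(subject_id = subject_ids,
                                         fold = fold,
                                         stringsAsFactors = FALSE),
                 n_folds = n_folds, seed = as.integer(seed)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", nrow(x$assignment), " subjects in ", x$n_folds,
      " folds (sizes ", paste(tabulate(x$assignment$fold, x$n_folds),
                              collapse = ", "),
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Default penalty grid: powers of two
#' @param lo,hi exponent range (default -10..10).
#' @return numeric vector `2^(lo:hi)`.
#' @export
default_C_grid <- function(lo = -10L, hi = 10L) 2^(lo:hi)

#' Grid search for the SVM penalty parameter C
#'
#' Evaluates every candidate C by internal cross-validation on the given
#' data (the caller passes the *training* split only) and returns the C
#' with the highest internal accuracy; ties go to the smallest C.
#'
#' @param X,y training features and labels.
#' @param grid candidate C values (non-empty).
#' @param n_folds internal folds (default 10, capped at `nrow(X)`).
#' @param seed seed for the internal fold plan (stratified by class).
#' @param subject_ids optional ids of the rows of `X`; the internal folds
#'   are keyed to them, making the search invariant to row permutation.
#' @return list with `best_C` and `accuracy` (named per grid value).
#' @export
grid_search_C <- function(X, y, grid = default_C_grid(), n_folds = 10L,
                          seed = 1L, subject_ids = NULL) {
  if (length(grid) == 0L) stop("empty C grid")
  grid <- sort(grid)
  if (length(grid) == 1L)
    return(list(best_C = grid, accuracy = stats::setNames(NA_real_,
                                                          as.character(grid))))
  X <- as.matrix(X)
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(X))
  n_folds <- min(as.integer(n_folds), nrow(X))
  plan <- make_cv_plan(subject_ids, n_folds, seed, stratify_by = y)
  fold <- plan$assignment$fold
  acc <- vapply(grid, function(C) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      m <- train_linear_svm(X[tr, , drop = FALSE], y[tr], C)
      correct <- correct +
        sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / nrow(X)
  }, numeric(1))
  best <- grid[which.max(acc)]  # first max = smallest C (grid sorted)
  list(best_C = best, accuracy = stats::setNames(acc, as.character(grid)))
}

#' Cross-validated classifier evaluation
#'
#' Outer k-fold evaluation of a linear SVM (with per-fold grid-searched C)
#' or a 1-NN classifier, pooling held-out predictions into one accuracy
#' and confusion matrix.  Optional iterative SVM-weight feature selection
#' is nested strictly inside each outer training split.
#'
#' @param X subjects x features matrix, or an `lbp_feature_set`.
#' @param y two-class label vector.
#' @param plan a [make_cv_plan()] for the subjects (rows of `X`).
#' @param classifier `"svm"` or `"knn"`.
#' @param C_grid penalty grid for the SVM (ignored for knn).
#' @param select if TRUE, run [combine_groups()] feature selection on each
#'   training split; requires `groups`.
#' @param groups named list of column-index groups (defaults to the
#'   feature set's radius groups when `X` is an `lbp_feature_set`).
#' @param whole_brain logical per group: append without dropping
#'   (see [combine_groups()]).
#' @param inner_seed seed for inner grid-search folds.
#' @return An object of class `eval_result`: `predictions` (per subject,
#'   from its held-out fold), `accuracy`, `confusion` (2x2), `fold_C`,
#'   `n_selected` per fold, `plan`.
#' @export
cross_validate <- function(X, y, plan, classifier = c("svm", "knn"),
                           C_grid = default_C_grid(), select = FALSE,
                           groups = NULL, whole_brain = NULL,
                           inner_seed = NULL) {
  classifier <- match.arg(classifier)
  if (inherits(X, "lbp_feature_set")) {
    if (is.null(groups)) groups <- X$groups
    X <- X$X
  }
  X <- as.matrix(X)
  stopifnot(inherits(plan, "cv_plan"), nrow(X) == nrow(plan$assignment),
            length(y) == nrow(X))
  if (select && is.null(groups))
    stop("feature selection requires `groups`")
  if (is.null(inner_seed)) inner_seed <- derive_seed(plan$seed, 97L)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("y must have exactly two classes")
  fold <- plan$assignment$fold
  preds <- rep(y[1], length(y))
  fold_C <- rep(NA_real_, plan$n_folds)
  n_sel <- rep(NA_integer_, plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("training split for fold ", f, " contains a single class")
    cols <- seq_len(ncol(X))
    ids_tr <- plan$assignment$subject_id[tr]
    if (select) {
      sel <- combine_groups(X[tr, , drop = FALSE], y[tr], groups,
                            whole_brain = whole_brain, C_grid = C_grid,
                            seed = derive_seed(inner_seed, f),
                            subject_ids = ids_tr)
      cols <- sel$selected
    }
    n_sel[f] <- length(cols)
    Xtr <- X[tr, cols, drop = FALSE]
    Xte <- X[!tr, cols, drop = FALSE]
    if (classifier == "svm") {
      gs <- grid_search_C(Xtr, y[tr], C_grid,
                          seed = derive_seed(inner_seed, f, 1L),
                          subject_ids = ids_tr)
      fold_C[f] <- gs$best_C
      m <- train_linear_svm(Xtr, y[tr], gs$best_C)
      preds[!tr] <- predict(m, Xte)
    } else {
      preds[!tr] <- knn_predict(Xtr, y[tr], Xte)
    }
  }
  confusion <- table(factor(y, levels = lev), factor(preds, levels = lev),
                     dnn = c("truth", "predicted"))
  structure(list(predictions = preds, truth = y,
                 subject_id = plan$assignment$subject_id,
                 accuracy = mean(preds == y), confusion = confusion,
                 fold_C = fold_C, n_selected = n_sel, plan = plan,
                 classifier = classifier),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> ", x$classifier, ", ", length(x$predictions),
      " subjects, pooled accuracy ", sprintf("%.4f", x$accuracy), "\n",
      sep = "")
  print(x$confusion)
  if (x$classifier == "svm")
    cat("per-fold C: ", paste(signif(x$fold_C, 3), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Pairwise region-correlation (connectivity) features
#'
#' Pearson correlation for every unordered region pair of a region x time
#' matrix, ordered lexicographically by (i, j) with i < j; the reference
#' feature set against which texture features are compared.  116 regions
#' give choose(116, 2) = 6670 features.
#'
#' @param timecourses numeric matrix, regions in rows, timepoints in
#'   columns (>= 3); every region must have positive variance.
#' @return numeric vector of length `n * (n - 1) / 2`, named `"i_j"`.
#' @export
connectivity_features <- function(timecourses) {
  tc <- as.matrix(timecourses)
  n <- nrow(tc)
  if (n < 2L) stop("need at least 2 regions")
  if (ncol(tc) < 3L) stop("need at least 3 timepoints")
  v <- apply(tc, 1L, stats::var)
  if (any(v <= 0))
    stop("zero-variance region(s): ", paste(which(v <= 0), collapse = ", "))
  cm <- stats::cor(t(tc))
  pairs <- t(utils::combn(n, 2L))       # lexicographic (i, j), i < j
  stats::setNames(cm[pairs], paste0(pairs[, 1], "_", pairs[, 2]))
}
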