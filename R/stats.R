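# Significance testing: permutation p-values for learned structure and
# McNemar's test between paired classifiers.

#' Permutation test of a cross-validated classifier
#'
#' Re-runs the full evaluation pipeline on `k` label-permuted copies of
#' the data and reports
#' `p = (#\{randomized error <= observed error\} + 1) / (k + 1)`,
#' where error = 1 - accuracy and ties count (`<=`).  Randomized labels
#' are full permutations of `y` (class balance preserved).  The same CV
#' plan / pipeline settings are used for the observed and every
#' randomized run; the smallest attainable p is `1 / (k + 1)` (0.0099
#' at the conventional k = 100).
#'
#' @param pipeline function `(X, y) -> accuracy in [0, 1]`, e.g. a wrapper
#'   around [cross_validate()] closing over a fixed [make_cv_plan()].
#' @param X,y data passed to the pipeline.
#' @param k number of randomized datasets (default 100).
#' @param seed seed for the label permutations.
#' @return An object of class `perm_result`: `p_value`, `k`,
#'   `observed_error`, `randomized_errors`.
#' @export
permutation_test <- function(pipeline, X, y, k = 100L, seed = 1L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  observed_error <- 1 - pipeline(X, y)
  perms <- with_seed(seed, replicate(k, sample(y), simplify = FALSE))
  randomized_errors <- vapply(perms, function(yp) 1 - pipeline(X, yp),
                              numeric(1))
  p <- (sum(randomized_errors <= observed_error) + 1) / (k + 1)
  structure(list(p_value = p, k = k, observed_error = observed_error,
                 randomized_errors = randomized_errors),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("<perm_result> observed error ", sprintf("%.4f", x$observed_error),
      "; ", sum(x$randomized_errors <= x$observed_error), " of ", x$k,
      " randomized errors <= observed; p = ", sprintf("%.4g", x$p_value),
      "\n", sep = "")
  invisible(x)
}

#' McNemar's test between two paired classifiers
#'
#' Counts the discordant subjects — `b` (A correct, B wrong) and `c`
#' (A wrong, B correct) — over identical subjects, and tests b = c.
#' For `b + c < 25` the exact two-sided binomial test is used
#' (`p = 2 * P(Bin(b+c, 1/2) <= min(b, c))`, capped at 1); otherwise the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df.
#'
#' @param preds_a,preds_b predicted labels from the two classifiers.
#' @param truth true labels, same length.
#' @param method `"auto"` (exact below b + c = 25, chi-square above),
#'   or force `"exact"` / `"chisq"`.
#' @return list with `p_value`, `b`, `c`, `statistic` (chi-square path
#'   only, else NA), `method`.
#' @export
mcnemar_test <- function(preds_a, preds_b, truth,
                         method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  if (length(preds_a) != length(truth) || length(preds_b) != length(truth))
    stop("prediction vectors and truth must have equal length")
  ok_a <- preds_a == truth
  ok_b <- preds_b == truth
  b <- sum(ok_a & !ok_b)
  c_ <- sum(!ok_a & ok_b)
  n <- b + c_
  if (n == 0L) {
    return(list(p_value = 1, b = b, c = c_, statistic = NA_real_,
                method = "exact binomial"))
  }
  if (method == "exact" || (method == "auto" && n < 25L)) {
    p <- min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
    list(p_value = p, b = b, c = c_, statistic = NA_real_,
         method = "exact binomial")
  } else {
    stat <- (abs(b - c_) - 1)^2 / n
    list(p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         b = b, c = c_, statistic = stat,
         method = "continuity-corrected chi-square")
  }
}
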