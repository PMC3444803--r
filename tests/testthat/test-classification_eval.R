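test_that("cv plans: balanced sizes, determinism, degenerate cases", {
  ids <- sprintf("sub%04d", 1:436)
  p <- make_cv_plan(ids, 10, seed = 3)
  sz <- tabulate(p$assignment$fold, 10)
  expect_identical(sort(unique(sz)), c(43L, 44L))
  expect_identical(sum(sz == 44L), 6L)  # 436 = 6*44 + 4*43
  expect_identical(sum(sz == 43L), 4L)

  p2 <- make_cv_plan(ids, 10, seed = 3)
  expect_identical(p$assignment, p2$assignment)
  expect_false(identical(p$assignment$fold,
                         make_cv_plan(ids, 10, seed = 4)$assignment$fold))

  loo <- make_cv_plan(ids[1:10], 10, seed = 1)
  expect_identical(tabulate(loo$assignment$fold, 10), rep(1L, 10))
  expect_error(make_cv_plan(ids[1:5], 10), "at least")

  # fold of a subject depends only on the id set and seed, not input order
  perm <- sample(436)
  pp <- make_cv_plan(ids[perm], 10, seed = 3)
  m <- match(ids, pp$assignment$subject_id)
  expect_identical(pp$assignment$fold[m], p$assignment$fold)
})

test_that("linear SVM: separable data, hard-margin limit, duplication", {
  X <- matrix(c(-1, 1), ncol = 1)
  y <- c(0, 1)
  for (C in c(1, 10, 1000)) {
    m <- train_linear_svm(X, y, C)
    expect_identical(predict(m, X), y)
  }

  # large C approaches the hard margin: training accuracy 1 on separable
  set.seed(40)
  Xs <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  ys <- rep(c(0, 1), each = 20)
  mh <- train_linear_svm(Xs, ys, 1e6)
  expect_identical(mean(predict(mh, Xs) == ys), 1)

  # duplicating every subject: decision on a probe grid unchanged
  md <- train_linear_svm(Xs, ys, 1)
  md2 <- train_linear_svm(Xs[rep(1:40, 2), ], ys[rep(1:40, 2)], 1)
  probe <- rbind(matrix(rnorm(60, -3), 30, 2), matrix(rnorm(60, 3), 30, 2))
  expect_identical(predict(md, probe), predict(md2, probe))

  expect_error(train_linear_svm(Xs, rep(0, 40)), "two classes")
  Xn <- Xs; Xn[1, 1] <- NA
  expect_error(train_linear_svm(Xn, ys), "non-finite")
})

test_that("grid search: single value, tie rule, chance level on noise", {
  set.seed(41)
  X <- matrix(rnorm(30 * 4), 30)
  y <- rep(0:1, 15)
  one <- grid_search_C(X, y, grid = 7)
  expect_identical(one$best_C, 7)

  # separable data: every C perfect, smallest returned by the tie rule
  Xs <- matrix(c(rnorm(15, -5), rnorm(15, 5)), ncol = 1)
  ys <- rep(0:1, each = 15)
  gs <- grid_search_C(Xs, ys, grid = 2^(-3:3), seed = 2)
  expect_true(all(gs$accuracy == 1))
  expect_identical(gs$best_C, 2^-3)

  # pure noise: internal accuracies near 0.5 for all C
  set.seed(42)
  Xn <- matrix(rnorm(60 * 5), 60)
  yn <- rep(0:1, each = 30)
  gn <- grid_search_C(Xn, yn, grid = c(0.01, 1, 100), seed = 3)
  expect_true(all(abs(gn$accuracy - 0.5) < 3 * sqrt(0.25 / 60)))
})

test_that("1-NN: exact match, tie to lower index, brute-force oracle", {
  trX <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_identical(knn_predict(trX, c("a", "b"), trX), c("a", "b"))
  # midway between two training points: first (lower-index) label wins
  expect_identical(knn_predict(matrix(c(-1, 1), 2, 1), c("a", "b"),
                               matrix(0, 1, 1)), "a")
  set.seed(43)
  tr <- matrix(rnorm(500), 50, 10)
  ty <- sample(0:1, 50, TRUE)
  te <- matrix(rnorm(120), 12, 10)
  want <- apply(te, 1, function(z)
    ty[which.min(colSums((t(tr) - z)^2))])
  expect_identical(knn_predict(tr, ty, te), want)
  expect_error(knn_predict(tr[0, ], ty[0], te), "empty")
})

test_that("cross-validation: perfect signal, chance on shuffled labels,
           pooled-accuracy identity", {
  set.seed(44)
  n <- 60
  x1 <- sample(c(runif(n / 2, -3, -1), runif(n / 2, 1, 3)))
  y <- as.integer(x1 > 0)  # labels equal the feature's sign
  X <- cbind(x1, matrix(rnorm(n * 3), n))
  plan <- make_cv_plan(seq_len(n), 10, seed = 5)
  ev <- cross_validate(X, y, plan, "svm", C_grid = c(0.1, 1, 10))
  expect_identical(ev$accuracy, 1)
  expect_identical(sum(ev$confusion), as.integer(n))
  expect_identical(ev$confusion[1, 1] + ev$confusion[2, 2], sum(diag(ev$confusion)))

  # pooled accuracy equals the fold-size-weighted mean of fold accuracies
  fold <- plan$assignment$fold
  per_fold <- vapply(1:10, function(f)
    mean((ev$predictions == y)[fold == f]), numeric(1))
  wts <- tabulate(fold, 10)
  expect_equal(ev$accuracy, sum(per_fold * wts) / n)

  # shuffled labels: accuracy within 3 binomial SDs of 0.5
  yr <- sample(y)
  evr <- cross_validate(X, yr, plan, "svm", C_grid = c(0.1, 1))
  expect_lt(abs(evr$accuracy - 0.5), 3 * sqrt(0.25 / n))

  # knn route
  evk <- cross_validate(X, y, plan, "knn")
  expect_gt(evk$accuracy, 0.9)

  # single-class training fold is a named error
  y_bad <- c(1L, rep(0L, n - 1))
  expect_error(cross_validate(X, y_bad, plan, "svm", C_grid = 1), "fold")
})

test_that("nested selection keeps shuffled-label accuracy at chance while
           selection outside the folds inflates it", {
  set.seed(45)
  n <- 40; d <- 500
  X <- matrix(rnorm(n * d), n)
  y <- rep(0:1, each = n / 2)  # independent of X by construction
  ends <- seq(50, 500, by = 50)
  groups <- lapply(seq_along(ends), function(k)
    (c(0L, ends)[k] + 1L):ends[k])
  plan <- make_cv_plan(seq_len(n), 10, seed = 6)

  inside <- cross_validate(X, y, plan, "svm", C_grid = 1, select = TRUE,
                           groups = groups)
  expect_lt(abs(inside$accuracy - 0.5), 3 * sqrt(0.25 / n))

  # leakage: select once on the full data, then cross-validate the
  # selected columns as if they were given a priori
  sel <- combine_groups(X, y, groups, C_grid = 1, seed = 6)
  leaked <- cross_validate(X[, sel$selected], y, plan, "svm", C_grid = 1)
  expect_gt(leaked$accuracy, inside$accuracy + 0.15)
})

test_that("connectivity features: counts, ordering, Pearson invariances", {
  tc <- generate_timecourses(116, 40, 0, seed = 7)
  expect_identical(length(connectivity_features(tc)), 6670L)

  tc2 <- generate_timecourses(2, 30, 0, seed = 8)
  expect_identical(length(connectivity_features(tc2)), 1L)

  # duplicated region correlates 1 with its twin; self-pairs excluded
  tc3 <- rbind(tc2, tc2[2, ])
  cf <- connectivity_features(tc3)
  expect_identical(names(cf), c("1_2", "1_3", "2_3"))
  expect_equal(unname(cf["2_3"]), 1)

  # invariant to per-subject affine rescaling of the timecourses
  cf_scaled <- connectivity_features(5 * tc - 2)
  expect_equal(cf_scaled, connectivity_features(tc))

  expect_error(connectivity_features(tc2[, 1:2]), "timepoints")
  tc4 <- tc2; tc4[1, ] <- 3
  expect_error(connectivity_features(tc4), "zero-variance region\\(s\\): 1")
})
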