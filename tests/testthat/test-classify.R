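test_that("stratified splits preserve class proportions deterministically", {
  labels <- rep(c("tumor", "normal"), c(1104, 114))
  sp <- stratified_split(labels, 0.5, seed = 1)
  expect_length(sp$train, 609)
  expect_length(sp$test, 609)
  expect_identical(sum(labels[sp$train] == "tumor"), 552L)
  expect_identical(sum(labels[sp$train] == "normal"), 57L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))

  small <- rep(c("tumor", "normal"), each = 4)
  for (s in 1:5) {
    sps <- stratified_split(small, 0.5, seed = s)
    expect_identical(sum(small[sps$train] == "tumor"), 2L)
    expect_identical(sum(small[sps$train] == "normal"), 2L)
  }
  expect_identical(stratified_split(labels, 0.5, 7)$train,
                   stratified_split(labels, 0.5, 7)$train)
  expect_false(identical(stratified_split(labels, 0.5, 7)$train,
                         stratified_split(labels, 0.5, 8)$train))
  expect_error(stratified_split(c("tumor", "tumor", "normal"), 0.5, 1),
               "fewer than 2")
  expect_error(stratified_split(rep("tumor", 5), 0.5, 1), "both classes")
})

test_that("the 1-D separable fit recovers the analytic max-margin solution", {
  x <- matrix(c(0, 0, 2, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  m <- train_svm(x, y, C = 1e6, standardize = FALSE)
  expect_equal(unname(m$w), 1, tolerance = 1e-4)
  expect_equal(m$b, -1, tolerance = 1e-4)
  expect_equal(m$margin, 2, tolerance = 1e-4)
  expect_equal(m$margin, 2 / sqrt(sum(m$w^2)))
  # hard-margin constraints hold on the training points
  s <- decision_values(m, x)
  expect_true(all(y * s >= 1 - 1e-6))
  # decision values: a point on the hyperplane scores 0 and goes positive
  expect_equal(unname(decision_values(m, matrix(1))), 0, tolerance = 1e-6)
  expect_identical(predict(m, matrix(1)), 1L)
  expect_equal(unname(decision_values(m, matrix(3))), 2, tolerance = 1e-4)
  expect_error(decision_values(m, matrix(1, ncol = 2)), "mismatch")
})

test_that("duplicating training points preserves the optimization objective", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, -1), ncol = 2), matrix(rnorm(40, 1), ncol = 2))
  y <- rep(c(-1, 1), each = 20)
  # duplicating every point doubles the total slack penalty, so the
  # equivalent single-copy problem has twice the per-point C; on separable
  # data at the hard-margin limit duplication changes nothing at all
  m1 <- train_svm(x, y, C = 10, standardize = FALSE)
  m2 <- train_svm(rbind(x, x), c(y, y), C = 5, standardize = FALSE)
  expect_equal(m1$w, m2$w, tolerance = 1e-3)
  expect_equal(m1$b, m2$b, tolerance = 1e-3)

  xs <- rbind(matrix(rnorm(40, -3, 0.5), ncol = 2),
              matrix(rnorm(40, 3, 0.5), ncol = 2))
  mh1 <- train_svm(xs, y, C = 1e6, standardize = FALSE)
  mh2 <- train_svm(rbind(xs, xs), c(y, y), C = 1e6, standardize = FALSE)
  expect_equal(mh1$w, mh2$w, tolerance = 1e-3)
  expect_equal(mh1$b, mh2$b, tolerance = 1e-3)
})

test_that("the solver agrees with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(14)
  x <- rbind(matrix(rnorm(60, -1.2), ncol = 2),
             matrix(rnorm(60, 1.2), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(-1, 1), each = 30)
  for (C in c(0.5, 1, 10)) {
    mine <- train_svm(x, y, C = C, standardize = FALSE)
    ref <- e1071::svm(x, factor(y), kernel = "linear", cost = C,
                      scale = FALSE)
    w_ref <- drop(t(ref$coefs) %*% ref$SV)
    b_ref <- -ref$rho
    # e1071 labels by first factor level; align the sign
    sgn <- sign(sum(w_ref * mine$w))
    expect_equal(unname(mine$w), unname(sgn * w_ref), tolerance = 1e-3)
    expect_equal(mine$b, sgn * b_ref, tolerance = 1e-3)
  }
})

test_that("evaluation metrics satisfy their identities and match oracles", {
  y <- c(1, 1, 1, -1, -1)
  s <- c(2.5, 0.3, -0.2, -1, 0.3)
  rep <- evaluate_scores(y, s)
  expect_identical(sum(rep$confusion[c("TP", "FN")]), 3L)
  expect_identical(sum(rep$confusion[c("TN", "FP")]), 2L)
  expect_equal(rep$accuracy,
               sum(rep$confusion[c("TP", "TN")]) / 5)
  expect_equal(rep$auc, oracle_pairwise_auc(s, y))

  # random scores with ties against the pairwise oracle and pROC
  set.seed(9)
  for (i in 1:20) {
    y2 <- sample(c(-1, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y2)) < 2) next
    s2 <- sample(seq(-1, 1, by = 0.25), 30, replace = TRUE)
    expect_equal(evaluate_scores(y2, s2)$auc, oracle_pairwise_auc(s2, y2))
  }
  skip_if_not_installed("pROC")
  r <- pROC::roc(response = y, predictor = s, quiet = TRUE,
                 direction = "<", levels = c(-1, 1))
  expect_equal(rep$auc, as.numeric(pROC::auc(r)))

  # perfect separation: AUC 1 and a threshold with sens = spec = 1
  perf <- evaluate_scores(c(1, 1, -1, -1), c(3, 2, -1, -2))
  expect_identical(perf$auc, 1)
  expect_true(any(perf$roc$tpr == 1 & perf$roc$fpr == 0))
  expect_error(evaluate_scores(c(1, 1), c(0.5, 0.2)), "positive and one negative")
})

test_that("published confusion-matrix arithmetic is internally consistent", {
  # 552 positives at sensitivity 0.991 -> 547 correct; 57 negatives at
  # specificity 0.93 -> 53 correct; together 600 of 609 (accuracy 98.5%)
  y <- rep(c(1, -1), c(552, 57))
  s <- c(rep(1, 547), rep(-1, 5), rep(-1, 53), rep(1, 4))
  rep <- evaluate_scores(y, s)
  expect_identical(unname(rep$confusion["TP"] + rep$confusion["TN"]), 600L)
  expect_equal(rep$sensitivity, 547 / 552, tolerance = 1e-12)
  expect_equal(round(rep$sensitivity, 3), 0.991)
  expect_equal(round(rep$specificity, 2), 0.93)
  expect_equal(round(100 * rep$accuracy, 1), 98.5)
})

test_that("cross-validation separates well-separated classes and stays null-calibrated", {
  set.seed(100)
  n <- 100
  x <- rbind(matrix(rnorm(n * 3, 0), ncol = 3),
             matrix(rnorm(n * 3, 6), ncol = 3))   # 6-sigma separation
  y <- rep(c(-1, 1), each = n)
  cv <- cross_validate(x, y, k = 10, seed = 1)
  expect_gte(cv$accuracy, 0.99)
  expect_gte(cv$auc, 0.99)
  # every sample lands in exactly one test fold
  expect_identical(sort(unique(cv$folds)), 1:10)
  expect_length(cv$folds, 2 * n)
  expect_true(all(table(cv$folds) == 20))

  # permuted labels: pooled CV AUC hovers at chance
  set.seed(200)
  xn <- matrix(rnorm(200 * 5), ncol = 5)
  yn <- sample(rep(c(-1, 1), each = 100))
  cvn <- cross_validate(xn, yn, k = 10, seed = 2)
  expect_lt(abs(cvn$auc - 0.5), 0.07)

  expect_error(cross_validate(xn, yn, k = 1), "at least 2")
  expect_warning(cross_validate(xn[1:12, ], yn[1:12], k = 10, seed = 1),
                 "reducing k")
})

test_that("fold models standardize with training-fold statistics only", {
  set.seed(77)
  x <- matrix(rnorm(60 * 2, 5, 3), ncol = 2)
  y <- rep(c(-1, 1), 30)
  x[y == 1, ] <- x[y == 1, ] + 1
  m <- train_svm(x[1:40, ], y[1:40], C = 1)
  expect_equal(unname(m$center), colMeans(x[1:40, ]))
  expect_equal(unname(m$scale), apply(x[1:40, ], 2, sd))
  # scores on new data are computed on the training standardization
  xs <- sweep(sweep(x[41:60, ], 2, m$center), 2, m$scale, "/")
  expect_equal(decision_values(m, x[41:60, ]),
               drop(xs %*% m$w) + m$b)
})
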