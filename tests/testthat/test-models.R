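sep_toy <- function(n = 60, seed = 6) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(a = rnorm(n, ifelse(y == 1, 4, -4), 0.5),
             b = rnorm(n))
  list(x = x, y = y)
}

test_that("stratified split preserves class balance within one row", {
  set.seed(1)
  y <- rbinom(1000, 1, 0.4)
  sp <- make_split(matrix(rnorm(2000), 1000), y, "random_stratified",
                   seed = 3)
  tr <- sp$assignment == "train"
  expect_identical(sort(unique(sp$assignment)), c("test", "train"))
  for (cl in 0:1) {
    expect_lte(abs(sum(tr & y == cl) - round(0.8 * sum(y == cl))), 1)
  }
  # overall ratio matches within one row per stratum
  expect_lt(abs(mean(y[tr]) - mean(y)), 2 / sum(tr))

  # a single-class set yields single-class partitions without error
  sp1 <- make_split(matrix(rnorm(40), 20), rep(1L, 20), "random_stratified")
  expect_true(all(table(sp1$assignment) > 0))
})

test_that("K-Means split partitions exhaustively and stratifies per cluster", {
  set.seed(2)
  x <- scale(matrix(rnorm(600), 200))
  y <- rbinom(200, 1, 0.5)
  sp <- make_split(x, y, "kmeans_within_cluster", k = 4, seed = 9)
  expect_identical(length(sp$assignment), 200L)
  expect_false(any(is.na(sp$assignment)))
  expect_identical(length(unique(sp$clusters)), 4L)
  # ~80/20 overall
  expect_lt(abs(mean(sp$assignment == "train") - 0.8), 0.05)

  # tiny cluster warning: engineered via k close to n
  w <- capture_warnings(
    make_split(matrix(rnorm(24), 12), rep(0:1, 6),
               "kmeans_within_cluster", k = 5, seed = 1))
  expect_true(any(grepl("fewer than 5", w)))
})

test_that("splits and stochastic learners are reproducible under a seed", {
  toy <- sep_toy(100)
  s1 <- make_split(toy$x, toy$y, seed = 7)
  s2 <- make_split(toy$x, toy$y, seed = 7)
  expect_identical(s1$assignment, s2$assignment)

  m1 <- train_model("RF", toy$x, toy$y, list(ntree = 100), seed = 5)
  m2 <- train_model("RF", toy$x, toy$y, list(ntree = 100), seed = 5)
  expect_identical(predict(m1, toy$x, type = "prob"),
                   predict(m2, toy$x, type = "prob"))
})

test_that("LDA separates a separable toy and exposes its linear expansion", {
  toy <- sep_toy()
  m <- train_model("LDA", toy$x, toy$y)
  pred <- predict(m, toy$x)
  expect_identical(pred$class, toy$y)

  # the probability is exactly the logistic of the explicit linear score
  cf <- coef(m)
  score <- cf[1] + as.matrix(toy$x) %*% cf[-1]
  expect_equal(pred$probability, as.numeric(plogis(score)),
               tolerance = 1e-10)
})

test_that("closed-form LDA agrees with the reference implementation", {
  set.seed(10)
  n <- 150
  y <- rbinom(n, 1, 0.45)
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  x[y == 1, 1] <- x[y == 1, 1] + 1.2
  x[y == 1, 3] <- x[y == 1, 3] - 0.7

  m <- train_model("LDA", x, y)
  ours <- predict(m, x, type = "prob")
  ref <- MASS::lda(x, grouping = factor(y))
  theirs <- predict(ref, as.data.frame(x))$posterior[, "1"]
  expect_equal(ours, unname(theirs), tolerance = 1e-6)
})

test_that("hand-set LDA coefficients reproduce manual score arithmetic", {
  m <- lda_model_from_coefficients(a0 = 0.5, w = c(f1 = 2, f2 = -1))
  x <- rbind(c(f1 = 1, f2 = 0), c(f1 = 0, f2 = 3), c(f1 = -1, f2 = -1))
  manual <- plogis(c(0.5 + 2 * 1, 0.5 - 3, 0.5 - 2 + 1))
  expect_equal(predict(m, x, type = "prob"), manual, tolerance = 1e-12)
  expect_identical(predict(m, x, type = "class"), as.integer(manual > 0.5))

  # all-zero weights with a positive intercept predict everything active
  m0 <- lda_model_from_coefficients(a0 = 1, w = c(f1 = 0, f2 = 0))
  expect_identical(predict(m0, x, type = "class"), rep(1L, 3))
})

test_that("every model family trains and emits probabilities in [0, 1]", {
  toy <- sep_toy(80)
  for (fam in c("LDA", "RF", "SVM", "DT", "KNN", "GB", "XGB")) {
    m <- train_model(fam, toy$x, toy$y, seed = 3)
    p <- predict(m, toy$x, type = "prob")
    expect_true(all(p >= 0 & p <= 1), info = fam)
    expect_gt(mean(as.integer(p > 0.5) == toy$y), 0.9)
  }
  # the reported tuned XGB configuration trains without error
  m <- train_model("XGB", toy$x, toy$y,
                   list(subsample = 1.0, nrounds = 160L, max_depth = 12L,
                        eta = 0.267), seed = 1)
  expect_s3_class(m, "ifptml_model")

  expect_error(train_model("XGB", toy$x, rep(1L, nrow(toy$x))),
               "single-class")
  expect_error(train_model("nope", toy$x, toy$y), "unknown model family")
  expect_error(train_model("RF", toy$x, toy$y, list(bogus = 1)), "bogus")
})

test_that("prediction refuses mismatched feature registries", {
  toy <- sep_toy()
  m <- train_model("LDA", toy$x, toy$y)
  bad <- toy$x
  colnames(bad) <- c("a", "zzz")
  err <- expect_error(predict(m, bad), "contract error")
  expect_match(conditionMessage(err), "b")
  expect_match(conditionMessage(err), "zzz")
  # same set, different order: normalized silently
  reord <- toy$x[, c("b", "a")]
  expect_equal(predict(m, reord, type = "prob"),
               predict(m, toy$x, type = "prob"), tolerance = 1e-12)
})

test_that("cross-validation is stratified and honest about nulls", {
  toy <- sep_toy(100)
  cv <- cross_validate("LDA", toy$x, toy$y, folds = 5, seed = 2)
  expect_identical(nrow(cv$per_fold), 5L)
  expect_equal(cv$mean_accuracy, 1)

  # label-permuted data: mean AUC compatible with chance
  set.seed(30)
  n <- 600
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(n, 1, 0.5)
  cv0 <- cross_validate("LDA", x, y, folds = 5, seed = 2)
  expect_lt(abs(cv0$mean_auc - 0.5), 0.05)

  expect_error(cross_validate("LDA", toy$x, toy$y, folds = 60),
               "folds exceed")
})

test_that("two-stage tuning logs every evaluation and returns the optimum", {
  toy <- sep_toy(80)
  # degenerate one-point space returns that point
  res1 <- tune_model("KNN", toy$x, toy$y, space = list(k = 3L),
                     random_iters = 2, folds = 3, seed = 4)
  expect_identical(res1$best$k, 3L)

  res <- tune_model("LDA", toy$x, toy$y, random_iters = 15, folds = 3,
                    seed = 4)
  expect_identical(sum(res$log$stage == "random"), 15L)
  expect_true(any(res$log$stage == "grid"))
  expect_equal(res$best_accuracy, max(res$log$accuracy), tolerance = 1e-12)
  expect_true(res$best$solver %in% c("lsqr", "svd", "eigen"))

  expect_error(tune_model("LDA", toy$x, toy$y, space = list()),
               "empty search space")
})

test_that("the acceptability gate requires accuracy and sensitivity above 70%", {
  pass <- classification_metrics(confusion_counts(80, 20, 10, 90))
  fail <- classification_metrics(confusion_counts(95, 5, 40, 60))
  expect_true(acceptability_gate(pass)$pass)
  g <- acceptability_gate(fail)
  expect_false(g$pass)          # sensitivity 60% < 70%
  expect_identical(g$threshold, 70)
})
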