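# ---- data splitting ---------------------------------------------------------

#' Split rows into training and test partitions
#'
#' Two strategies: `"random_stratified"` draws 80/20 within each class so the
#' class balance is preserved to within one row per stratum;
#' `"kmeans_within_cluster"` first clusters the standardized feature space
#' with K-Means (k-means++ seeding, fixed seed) and then performs a
#' label-stratified 80/20 split inside each cluster, so the test set covers
#' every region of feature space.
#'
#' @param fm numeric feature matrix (standardized for the K-Means strategy).
#' @param labels 0/1 vector aligned with `fm` rows.
#' @param strategy `"random_stratified"` or `"kmeans_within_cluster"`.
#' @param train_frac training fraction (0.8).
#' @param k number of K-Means clusters.
#' @param seed RNG seed driving the draw (and the K-Means initialization).
#' @return an object of class `ifptml_split`: list with `assignment`
#'   (character vector `"train"`/`"test"`), `strategy`, `seed`, and for the
#'   K-Means strategy the `clusters` vector.
#' @export
make_split <- function(fm, labels,
                       strategy = c("random_stratified", "kmeans_within_cluster"),
                       train_frac = 0.8, k = 5, seed = 42) {
  strategy <- match.arg(strategy)
  fm <- as.matrix(fm)
  n <- nrow(fm)
  stopifnot(length(labels) == n, all(labels %in% c(0L, 1L)))
  assignment <- rep(NA_character_, n)
  clusters <- NULL

  split_stratified <- function(idx, labs, frac) {
    out <- rep("train", length(idx))
    for (cl in unique(labs)) {
      rows <- which(labs == cl)
      n_tr <- round(frac * length(rows))
      shuffled <- if (length(rows) == 1L) rows else sample(rows)
      out[shuffled[seq_len(length(shuffled)) > n_tr]] <- "test"
    }
    out
  }

  withr_seed(seed, {
    if (strategy == "random_stratified") {
      assignment <- split_stratified(seq_len(n), labels, train_frac)
    } else {
      km <- kmeans_pp(fm, k)
      clusters <- km$cluster
      for (cl in seq_len(k)) {
        rows <- which(clusters == cl)
        if (length(rows) < 5L) {
          warning("cluster ", cl, " has fewer than 5 rows; all sent to train")
          assignment[rows] <- "train"
        } else {
          assignment[rows] <- split_stratified(rows, labels[rows], train_frac)
        }
      }
    }
  })
  structure(list(strategy = strategy, train_frac = train_frac, k = k,
                 seed = seed, assignment = assignment, clusters = clusters),
            class = "ifptml_split")
}

#' @export
print.ifptml_split <- function(x, ...) {
  cat(sprintf("ifptml split (%s, seed %d): %d train / %d test\n",
              x$strategy, x$seed, sum(x$assignment == "train"),
              sum(x$assignment == "test")))
  invisible(x)
}

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# K-Means with k-means++ seeding (stats::kmeans only offers random starts)
kmeans_pp <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (i in seq_len(k)[-1]) {
    probs <- d2 / sum(d2)
    centers[i, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[i, ])^2))
  }
  kmeans(x, centers = centers, iter.max = 100)
}

# ---- linear discriminant scorer --------------------------------------------

# Two-class LDA in closed form: pooled within-class covariance, optional
# diagonal shrinkage gamma: S_g = (1-g) S + g mean(diag(S)) I. The score is
# a0 + x'w with w = S^-1 (mu1 - mu0); the posterior is plogis(score), so the
# model is an explicit linear scoring function over the retained features.
lda_fit <- function(x, y, shrinkage = 0, solver = "lsqr") {
  x <- as.matrix(x)
  i1 <- y == 1L
  n0 <- sum(!i1); n1 <- sum(i1)
  if (n0 < 2L || n1 < 2L)
    stop("fit error: need at least two rows per class", call. = FALSE)
  mu0 <- colMeans(x[!i1, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  S <- ((n0 - 1) * cov(x[!i1, , drop = FALSE]) +
        (n1 - 1) * cov(x[i1, , drop = FALSE])) / (n0 + n1 - 2)
  if (shrinkage > 0) {
    mu_d <- mean(diag(S))
    S <- (1 - shrinkage) * S + shrinkage * mu_d * diag(ncol(x))
  }
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e)
    solve(S + diag(1e-8 * mean(diag(S)), ncol(S)), mu1 - mu0))
  a0 <- log(n1 / n0) - 0.5 * sum((mu0 + mu1) * w)
  list(a0 = as.numeric(a0), w = setNames(as.numeric(w), colnames(x)),
       solver = solver, shrinkage = shrinkage,
       means = rbind(`0` = mu0, `1` = mu1), prior = c(n0, n1) / (n0 + n1))
}

lda_score <- function(fit, x) as.numeric(fit$a0 + as.matrix(x) %*% fit$w)

#' Linear scoring coefficients of a fitted LDA model
#'
#' Returns the intercept and one weight per retained feature column, so the
#' predicted score is the explicit linear expansion
#' `a0 + a1 f_ref + sum b_k D_k + sum b'_k ΔD_k + ...` over the feature
#' matrix; the classification probability is the logistic transform of this
#' score.
#'
#' @param object a trained LDA `ifptml_model`.
#' @param ... ignored.
#' @return named numeric vector, first element `(Intercept)`.
#' @export
coef.ifptml_model <- function(object, ...) {
  if (object$family != "LDA")
    stop("coefficients are only exposed for the LDA family", call. = FALSE)
  c("(Intercept)" = object$fit$a0, object$fit$w)
}

#' Build an LDA model from hand-set coefficients
#'
#' Useful for scoring-function arithmetic checks and toy screening grids.
#'
#' @param a0 intercept.
#' @param w named weight vector (names define the expected feature columns).
#' @return an `ifptml_model` of family LDA.
#' @export
lda_model_from_coefficients <- function(a0, w) {
  structure(list(family = "LDA", hyper = list(),
                 fit = list(a0 = a0, w = w, solver = "manual", shrinkage = 0),
                 registry = names(w), seed = NA_integer_),
            class = "ifptml_model")
}

# ---- model families ---------------------------------------------------------

IFPTML_FAMILIES <- c("LDA", "RF", "SVM", "DT", "KNN", "GB", "XGB")

default_hyper <- function(family, p) {
  switch(family,
    LDA = list(solver = "lsqr", shrinkage = 0),
    RF  = list(ntree = 500, mtry = max(1L, floor(sqrt(p)))),
    SVM = list(cost = 1, gamma = 1 / p),
    DT  = list(cp = 0.01, maxdepth = 30),
    KNN = list(k = 5),
    # classic gradient-boosting defaults vs the tuned XGB configuration
    GB  = list(nrounds = 100, max_depth = 3, eta = 0.1, subsample = 1.0),
    XGB = list(nrounds = 160, max_depth = 12, eta = 0.267, subsample = 1.0))
}

#' Train a classifier on a prepared feature matrix
#'
#' Families: `"LDA"` (explicit linear scoring function, closed form),
#' `"RF"` (random forest), `"SVM"` (RBF kernel), `"DT"` (decision tree),
#' `"KNN"`, `"GB"` (gradient boosting with classic shallow-tree defaults)
#' and `"XGB"` (extreme gradient boosting; defaults are the tuned
#' configuration: subsample 1.0, 160 rounds, depth 12, learning rate 0.267).
#' Unspecified hyperparameters take per-family defaults; the RNG seed flows
#' into every stochastic learner so retraining is reproducible.
#'
#' @param family one of the family codes above (case-insensitive).
#' @param x numeric feature matrix (filtered and standardized).
#' @param y 0/1 labels.
#' @param hyper named list of family hyperparameters.
#' @param seed RNG seed.
#' @return an object of class `ifptml_model` carrying the fitted learner and
#'   a snapshot of the feature-column registry.
#' @export
train_model <- function(family, x, y, hyper = list(), seed = 42) {
  family <- toupper(family)
  if (!family %in% IFPTML_FAMILIES)
    stop("unknown model family '", family, "'", call. = FALSE)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("fit error: training labels are single-class", call. = FALSE)
  hp <- utils::modifyList(default_hyper(family, ncol(x)), hyper)
  bad <- setdiff(names(hyper), names(default_hyper(family, ncol(x))))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "), call. = FALSE)

  fit <- withr_seed(seed, switch(family,
    LDA = lda_fit(x, y, shrinkage = hp$shrinkage %||% 0,
                  solver = hp$solver %||% "lsqr"),
    RF = randomForest::randomForest(x, factor(y, levels = 0:1),
                                    ntree = hp$ntree, mtry = hp$mtry),
    SVM = e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                     cost = hp$cost, gamma = hp$gamma, probability = TRUE),
    DT = {
      df <- data.frame(.y = factor(y, levels = 0:1), x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  maxdepth = hp$maxdepth))
    },
    KNN = list(x = x, y = y, k = hp$k),
    GB = ,
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, eta = hp$eta,
                      subsample = hp$subsample, nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    }))
  structure(list(family = family, hyper = hp, fit = fit,
                 registry = colnames(x), seed = seed),
            class = "ifptml_model")
}

#' @export
print.ifptml_model <- function(x, ...) {
  cat(sprintf("ifptml %s model: %d features, seed %s\n", x$family,
              length(x$registry),
              if (is.na(x$seed)) "-" else as.character(x$seed)))
  hp <- vapply(x$hyper, function(h) paste(format(h), collapse = "/"),
               character(1))
  if (length(hp)) cat("  ", paste(names(hp), hp, sep = "=", collapse = ", "),
                      "\n", sep = "")
  invisible(x)
}

#' Predict activity class and probability
#'
#' Refuses feature matrices whose columns do not match the registry snapshot
#' taken at training time (column order is normalized automatically when the
#' sets agree). Class is probability > 0.5.
#'
#' @param object an `ifptml_model`.
#' @param newdata numeric feature matrix with the training columns.
#' @param type `"both"` (default), `"prob"` or `"class"`.
#' @param ... ignored.
#' @return data.frame with columns `class` and `probability`, or the
#'   requested vector.
#' @export
predict.ifptml_model <- function(object, newdata,
                                 type = c("both", "prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!identical(colnames(x), object$registry)) {
    missing_cols <- setdiff(object$registry, colnames(x))
    extra <- setdiff(colnames(x), object$registry)
    if (length(missing_cols) || length(extra))
      stop("contract error: feature columns mismatch; missing: [",
           paste(missing_cols, collapse = ", "), "]; unexpected: [",
           paste(extra, collapse = ", "), "]", call. = FALSE)
    x <- x[, object$registry, drop = FALSE]
  }
  prob <- switch(object$family,
    LDA = plogis(lda_score(object$fit, x)),
    RF = predict(object$fit, x, type = "prob")[, "1"],
    SVM = {
      pr <- predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    DT = predict(object$fit, data.frame(x, check.names = FALSE),
                 type = "prob")[, "1"],
    KNN = {
      pr <- class::knn(object$fit$x, x, factor(object$fit$y, levels = 0:1),
                       k = object$fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    GB = ,
    XGB = predict(object$fit, xgboost::xgb.DMatrix(x)))
  prob <- as.numeric(prob)
  cls <- as.integer(prob > 0.5)
  switch(type, prob = prob, class = cls,
         both = data.frame(class = cls, probability = prob))
}

# ---- cross-validation and tuning -------------------------------------------

stratified_folds <- function(y, folds, seed) {
  withr_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      rows <- which(y == cl)
      if (folds > length(rows))
        stop("folds exceed the size of class ", cl, call. = FALSE)
      fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    fold
  })
}

#' Stratified k-fold cross-validation
#'
#' @param family model family code.
#' @param x feature matrix.
#' @param y 0/1 labels.
#' @param hyper hyperparameter list.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for fold assignment and fits.
#' @return list with `per_fold` (accuracy/AUC per fold), `mean_accuracy`,
#'   `mean_auc`, `sd_accuracy`, `sd_auc`.
#' @export
cross_validate <- function(family, x, y, hyper = list(), folds = 10,
                           seed = 42) {
  x <- as.matrix(x)
  y <- as.integer(y)
  fold <- stratified_folds(y, folds, seed)
  res <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    m <- train_model(family, x[tr, , drop = FALSE], y[tr], hyper, seed = seed)
    p <- predict(m, x[!tr, , drop = FALSE], type = "prob")
    c(accuracy = mean(as.integer(p > 0.5) == y[!tr]),
      auc = auc_rank(y[!tr], p))
  })
  per_fold <- do.call(rbind, res)
  list(per_fold = as.data.frame(per_fold),
       mean_accuracy = mean(per_fold[, "accuracy"]),
       mean_auc = mean(per_fold[, "auc"]),
       sd_accuracy = sd(per_fold[, "accuracy"]),
       sd_auc = sd(per_fold[, "auc"]))
}

#' Default hyperparameter search spaces
#'
#' Value grids bracketing the per-family defaults; used by [tune_model()].
#'
#' @param family model family code.
#' @return named list of candidate value vectors.
#' @export
default_search_space <- function(family) {
  switch(toupper(family),
    LDA = list(solver = c("lsqr", "svd", "eigen"),
               shrinkage = c(0, 0.01, 0.05, 0.1, 0.3)),
    XGB = list(nrounds = c(80L, 120L, 160L, 170L, 220L),
               max_depth = c(4L, 6L, 8L, 10L, 12L),
               eta = c(0.05, 0.1, 0.267, 0.4),
               subsample = c(0.7, 0.85, 1.0)),
    GB = list(nrounds = c(50L, 100L, 200L),
              max_depth = c(2L, 3L, 5L),
              eta = c(0.05, 0.1, 0.2),
              subsample = c(0.8, 1.0)),
    RF = list(ntree = c(200L, 500L, 800L), mtry = c(2L, 5L, 10L, 20L)),
    SVM = list(cost = c(0.1, 1, 10), gamma = c(0.001, 0.01, 0.1)),
    DT = list(cp = c(0.001, 0.01, 0.05), maxdepth = c(3L, 10L, 30L)),
    KNN = list(k = c(1L, 3L, 5L, 9L, 15L)),
    stop("unknown family", call. = FALSE))
}

#' Two-stage hyperparameter search
#'
#' Stage one samples `random_iters` settings uniformly from the search space
#' (a randomized search; 45 draws for XGB and 15 for LDA by default) and
#' scores each by mean cross-validated accuracy. Stage two refines with a
#' grid over the ±1 value-neighbourhood of the randomized optimum in every
#' dimension. The full evaluation log is returned.
#'
#' @param family model family code.
#' @param x,y training features and 0/1 labels.
#' @param space named list of candidate values; see [default_search_space()].
#' @param random_iters randomized-stage sample count.
#' @param folds CV folds per evaluation.
#' @param seed RNG seed.
#' @return list with `best` (hyperparameter list), `best_accuracy`, and
#'   `log` (data.frame: stage, parameters, mean CV accuracy).
#' @export
tune_model <- function(family, x, y, space = default_search_space(family),
                       random_iters = NULL, folds = 10, seed = 42) {
  family <- toupper(family)
  if (!length(space) || any(!lengths(space)))
    stop("config error: empty search space", call. = FALSE)
  if (is.null(random_iters))
    random_iters <- switch(family, XGB = 45L, LDA = 15L, 20L)

  eval_combo <- function(combo) {
    cv <- cross_validate(family, x, y, hyper = combo, folds = folds,
                         seed = seed)
    cv$mean_accuracy
  }
  combo_row <- function(combo, stage, acc) {
    data.frame(stage = stage,
               lapply(combo, function(v) if (is.null(v)) NA else v),
               accuracy = acc, stringsAsFactors = FALSE)
  }

  # randomized stage: index draws per dimension
  draws <- withr_seed(seed, {
    lapply(seq_len(random_iters), function(i)
      lapply(space, function(vals) vals[[sample.int(length(vals), 1)]]))
  })
  log_rows <- list()
  accs <- vapply(draws, function(cmb) {
    a <- eval_combo(cmb)
    log_rows[[length(log_rows) + 1L]] <<- combo_row(cmb, "random", a)
    a
  }, numeric(1))
  best <- draws[[which.max(accs)]]

  # grid stage: +/- 1 neighbourhood around each optimum dimension
  neigh <- lapply(names(space), function(p) {
    vals <- space[[p]]
    i <- match(best[[p]], vals)
    vals[unique(pmax(1L, pmin(length(vals), i + (-1:1))))]
  })
  names(neigh) <- names(space)
  grid <- expand.grid(lapply(neigh, seq_along), KEEP.OUT.ATTRS = FALSE)
  grid_acc <- apply(grid, 1, function(ii) {
    cmb <- Map(function(vals, i) vals[[i]], neigh, ii)
    a <- eval_combo(cmb)
    log_rows[[length(log_rows) + 1L]] <<- combo_row(cmb, "grid", a)
    a
  })
  gbest <- Map(function(vals, i) vals[[i]], neigh,
               as.integer(grid[which.max(grid_acc), ]))
  if (max(grid_acc) >= max(accs)) best <- gbest

  list(best = best,
       best_accuracy = max(c(accs, grid_acc)),
       log = do.call(rbind, log_rows))
}

#' Model-acceptability gate
#'
#' A fitted classifier is deemed acceptable when both accuracy and
#' sensitivity exceed 70 %, with the class balance reported alongside.
#'
#' @param metrics an `ifptml_metrics` report (see [classification_metrics()]).
#' @param threshold acceptance threshold in percent.
#' @return list with `pass` (logical), `accuracy`, `sensitivity`,
#'   `threshold`.
#' @export
acceptability_gate <- function(metrics, threshold = 70) {
  stopifnot(inherits(metrics, "ifptml_metrics"))
  list(pass = is.finite(metrics$ac) && is.finite(metrics$sn) &&
         metrics$ac > threshold && metrics$sn > threshold,
       accuracy = metrics$ac, sensitivity = metrics$sn,
       threshold = threshold)
}
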