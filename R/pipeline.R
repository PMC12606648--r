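#' Fit the full condition-aware bioactivity classifier
#'
#' One call runs the whole pipeline on an assay dataset: labeling (if
#' needed) with the desirability policy, moving-average and
#' reference-function fitting, perturbation-delta feature assembly,
#' variance and correlation filtering, standardization, train/test
#' splitting, model training and evaluation (with the 70 % accuracy-and-
#' sensitivity acceptability gate).
#'
#' The default `scope = "full"` fits the moving averages, reference function
#' and filters on the complete dataset before splitting — the classic
#' convention for this family of models; `scope = "train_only"` restricts
#' every fitted table to the training rows so the information leakage the
#' full-scope convention induces can be quantified.
#'
#' @param data an `ifptml_dataset` (labeled or not).
#' @param policy optional `ifptml_policy`; defaults to [default_policy()].
#' @param model model family code (see [train_model()]).
#' @param hyper named list of hyperparameter overrides.
#' @param split splitting strategy (see [make_split()]).
#' @param scope `"full"` or `"train_only"`.
#' @param variance_threshold,corr_threshold feature-filter thresholds.
#' @param train_frac,k split parameters.
#' @param seed global seed flowing through split, K-Means, folds and
#'   stochastic learners.
#' @return an object of class `ifptml` with components `model`, `ma`, `ref`,
#'   `policy`, `prep` (retained columns + standardization), `split`,
#'   `metrics` (train/test `ifptml_metrics`), `gate`, `filter_reports`.
#' @examples
#' sim <- generate_synth(synth_config(n_records = 400, n_compounds = 120,
#'                                    n_assays = 12, seed = 7))
#' fit <- ifptml(sim$dataset, model = "LDA", seed = 7)
#' print(fit)
#' @export
ifptml <- function(data, policy = NULL, model = "XGB", hyper = list(),
                   split = c("random_stratified", "kmeans_within_cluster"),
                   scope = c("full", "train_only"),
                   variance_threshold = 0.01, corr_threshold = 0.97,
                   train_frac = 0.8, k = 5, seed = 42) {
  stopifnot(inherits(data, "ifptml_dataset"))
  split <- match.arg(split)
  scope <- match.arg(scope)
  cl <- match.call()

  if (is.null(data$data$label)) {
    policy <- policy %||% default_policy(data)
    data <- label_dataset(data, policy)
  }
  labels <- data$data$label

  build <- function(scp, train_idx = NULL) {
    ma <- fit_moving_averages(data, scope = scp, train_idx = train_idx)
    ref <- fit_reference(data, scope = scp, train_idx = train_idx)
    fm <- assemble_features(data, ma, ref)
    fit_rows <- if (scp == "train_only") train_idx else seq_len(nrow(fm))
    vf <- variance_filter(fm[fit_rows, , drop = FALSE],
                          threshold = variance_threshold)
    cf <- correlation_filter(vf$features, r_max = corr_threshold)
    cols <- colnames(cf$features)
    std <- standardize(fm[fit_rows, cols, drop = FALSE])
    full <- standardize(fm[, cols, drop = FALSE], std$params)$features
    list(ma = ma, ref = ref, features = full,
         prep = list(columns = cols, params = std$params),
         reports = list(variance = vf$report, correlation = cf$report))
  }

  if (scope == "full") {
    parts <- build("full")
    sp <- make_split(parts$features, labels, strategy = split,
                     train_frac = train_frac, k = k, seed = seed)
  } else {
    # the split must exist before any table is fitted; the K-Means variant
    # clusters on features built under full scope, used for splitting only
    if (split == "kmeans_within_cluster") {
      pre <- build("full")
      sp <- make_split(pre$features, labels, strategy = split,
                       train_frac = train_frac, k = k, seed = seed)
    } else {
      sp <- make_split(matrix(0, length(labels), 1), labels,
                       strategy = split, train_frac = train_frac, k = k,
                       seed = seed)
    }
    parts <- build("train_only", which(sp$assignment == "train"))
  }

  tr <- sp$assignment == "train"
  fitted <- train_model(model, parts$features[tr, , drop = FALSE],
                        labels[tr], hyper = hyper, seed = seed)
  eval_part <- function(rows) {
    pr <- predict(fitted, parts$features[rows, , drop = FALSE])
    classification_metrics(confusion(labels[rows], pr$class),
                           scores = pr$probability, y_obs = labels[rows])
  }
  metrics <- list(train = eval_part(which(tr)), test = eval_part(which(!tr)))

  structure(list(
    call = cl, dataset = data, policy = policy, scope = scope,
    ma = parts$ma, ref = parts$ref, prep = parts$prep,
    filter_reports = parts$reports, features = parts$features,
    labels = labels, split = sp, model = fitted,
    metrics = metrics, gate = acceptability_gate(metrics$test), seed = seed
  ), class = "ifptml")
}

#' @export
print.ifptml <- function(x, ...) {
  cat(sprintf("ifptml %s fit (%s split, %s scope, seed %d)\n",
              x$model$family, x$split$strategy, x$scope, x$seed))
  cat(sprintf("  %d records; %d retained feature columns\n",
              length(x$labels), length(x$prep$columns)))
  m <- x$metrics$test
  cat(sprintf("  test: Sp %.2f%%  Sn %.2f%%  Ac %.2f%%  AUC %.3f\n",
              m$sp, m$sn, m$ac, m$auc))
  cat(sprintf("  acceptability gate (>%g%%): %s\n", x$gate$threshold,
              if (x$gate$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
summary.ifptml <- function(object, top_n = 10, ...) {
  cat("== ifptml pipeline summary ==\n")
  print(object)
  cat("\nTraining metrics:\n"); print(object$metrics$train)
  cat("\nTest metrics:\n"); print(object$metrics$test)
  imp <- tryCatch(feature_importance(object$model, top_n = top_n),
                  error = function(e) NULL)
  if (!is.null(imp)) {
    cat(sprintf("\nTop %d features:\n", nrow(imp)))
    print(imp, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.ifptml <- function(object, ...) coef(object$model, ...)

#' Predict on a new assay dataset with a fitted pipeline
#'
#' Reassembles features for the new records against the *stored*
#' moving-average and reference tables (never refitted), reapplies the
#' stored filter columns and standardization, and scores the model.
#'
#' @param object an `ifptml` fit.
#' @param newdata an `ifptml_dataset` sharing the training schema; defaults
#'   to the training dataset (in-sample predictions).
#' @param type `"both"`, `"prob"` or `"class"`.
#' @param ... ignored.
#' @return as [predict.ifptml_model()].
#' @export
predict.ifptml <- function(object, newdata = NULL,
                           type = c("both", "prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    return(predict(object$model, object$features, type = type))
  stopifnot(inherits(newdata, "ifptml_dataset"))
  fm <- assemble_features(newdata, object$ma, object$ref)
  fm <- fm[, object$prep$columns, drop = FALSE]
  fm <- standardize(fm, object$prep$params)$features
  predict(object$model, fm, type = type)
}

#' ROC curve of a fitted pipeline
#'
#' @param x an `ifptml` fit.
#' @param partition `"test"` or `"train"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ifptml <- function(x, partition = c("test", "train"), ...) {
  partition <- match.arg(partition)
  rows <- if (partition == "test") x$split$assignment == "test"
          else x$split$assignment == "train"
  pr <- predict(x$model, x$features[rows, , drop = FALSE], type = "prob")
  roc <- roc_points(x$labels[rows], pr)
  graphics::plot(roc$fpr, roc$tpr, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("%s ROC (%s), AUC = %.3f", x$model$family,
                                partition, attr(roc, "auc")), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(roc)
}

#' Screen query compounds with a fitted pipeline
#'
#' Convenience wrapper: enumerates the condition tuples of the training data
#' passing `filter` (unless `tuples` is given) and scores every
#' (query, tuple) pair with [predict_new()].
#'
#' @param fit an `ifptml` object.
#' @param queries query-compound data.frame (identifier + full drug block).
#' @param filter optional condition filter for tuple enumeration.
#' @param tuples optional pre-built tuple table.
#' @return an `ifptml_grid`.
#' @export
screen_compounds <- function(fit, queries, filter = NULL, tuples = NULL) {
  stopifnot(inherits(fit, "ifptml"))
  if (is.null(tuples))
    tuples <- enumerate_conditions(fit$dataset, filter = filter)
  predict_new(fit$model, fit$ma, fit$ref, fit$prep, queries, tuples,
              fit$dataset$schema)
}
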