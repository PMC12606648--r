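#' Confusion matrix from observed and predicted 0/1 labels
#'
#' @param y_obs,y_pred equal-length vectors with values in 0/1.
#' @return an object of class `ifptml_cm`: named integer vector
#'   `(tn, fp, fn, tp)`.
#' @export
confusion <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred))
    stop("length mismatch between observed and predicted labels",
         call. = FALSE)
  if (!all(y_obs %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  cm <- c(tn = sum(y_obs == 0 & y_pred == 0),
          fp = sum(y_obs == 0 & y_pred == 1),
          fn = sum(y_obs == 1 & y_pred == 0),
          tp = sum(y_obs == 1 & y_pred == 1))
  structure(as.integer(cm), names = names(cm), class = "ifptml_cm")
}

#' Build a confusion matrix from known cell counts
#'
#' @param tn,fp,fn,tp non-negative cell counts.
#' @return an `ifptml_cm`.
#' @export
confusion_counts <- function(tn, fp, fn, tp) {
  cm <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(cm < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.integer(cm), names = names(cm), class = "ifptml_cm")
}

#' @export
print.ifptml_cm <- function(x, ...) {
  m <- matrix(x[c("tn", "fp", "fn", "tp")], 2, 2, byrow = TRUE,
              dimnames = list(observed = c("0", "1"),
                              predicted = c("0", "1")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Specificity, sensitivity and accuracy are reported in percent (two
#' decimals when printed, full precision stored); precision/recall/F1 refer
#' to the positive class, with macro-averaged variants alongside; MCC and
#' unweighted Cohen's kappa complete the set. Metrics with an undefined
#' denominator are set to 0 and flagged. When `scores` (and `y_obs`) are
#' supplied, the rank-statistic AUC is added.
#'
#' @param cm an `ifptml_cm`.
#' @param scores optional continuous scores for AUC.
#' @param y_obs observed labels aligned with `scores`.
#' @return an object of class `ifptml_metrics` (a list).
#' @export
classification_metrics <- function(cm, scores = NULL, y_obs = NULL) {
  stopifnot(inherits(cm, "ifptml_cm"))
  tn <- cm[["tn"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tp <- cm[["tp"]]
  n <- tn + fp + fn + tp
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  flags <- character()
  safe <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); 0 } else num / den
  }
  sp <- 100 * safe(tn, tn + fp, "specificity")
  sn <- 100 * safe(tp, tp + fn, "sensitivity")
  ac <- 100 * (tn + tp) / n
  prec1 <- safe(tp, tp + fp, "precision")
  rec1 <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * prec1 * rec1, prec1 + rec1, "f1")
  prec0 <- safe(tn, tn + fn, "precision0")
  rec0 <- safe(tn, tn + fp, "recall0")
  f0 <- safe(2 * prec0 * rec0, prec0 + rec0, "f0")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { flags <- c(flags, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  po <- (tn + tp) / n
  pe <- ((tn + fp) * (tn + fn) + (fn + tp) * (fp + tp)) / n^2
  kappa <- if (pe == 1) { flags <- c(flags, "kappa"); 0 } else
    (po - pe) / (1 - pe)
  auc <- if (!is.null(scores)) {
    stopifnot(!is.null(y_obs), length(scores) == length(y_obs))
    auc_rank(y_obs, scores)
  } else NA_real_
  structure(list(
    cm = cm, n = n, n0 = tn + fp, n1 = tp + fn,
    sp = sp, sn = sn, ac = ac,
    precision = prec1, recall = rec1, f1 = f1,
    precision_macro = (prec0 + prec1) / 2,
    recall_macro = (rec0 + rec1) / 2,
    f1_macro = (f0 + f1) / 2,
    mcc = mcc, kappa = kappa, auc = auc, flags = flags
  ), class = "ifptml_metrics")
}

#' @export
print.ifptml_metrics <- function(x, ...) {
  cat("ifptml classification metrics\n")
  cat(sprintf("  n = %d (%d inactive / %d active)\n", x$n, x$n0, x$n1))
  cat(sprintf("  Sp %.2f%%  Sn %.2f%%  Ac %.2f%%\n", x$sp, x$sn, x$ac))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  MCC %.3f  kappa %.3f", x$mcc, x$kappa))
  if (is.finite(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n")
  if (length(x$flags))
    cat("  undefined (set to 0):", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param metrics an `ifptml_metrics`.
#' @param path output path.
#' @export
write_metrics <- function(metrics, path) {
  x <- unclass(metrics)
  x$cm <- as.list(setNames(as.integer(metrics$cm), names(metrics$cm)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# AUC as the Mann-Whitney rank statistic (ties at half weight)
auc_rank <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points and area
#'
#' Returns the monotone ROC staircase from (0, 0) to (1, 1), obtained by
#' sweeping the classification threshold over the distinct score values.
#' The trapezoidal area equals the Mann–Whitney rank statistic.
#'
#' @param y_obs 0/1 labels.
#' @param scores continuous scores (higher = more active).
#' @return data.frame with columns `threshold`, `fpr`, `tpr`; attribute
#'   `"auc"` holds the area under the curve.
#' @export
roc_points <- function(y_obs, scores) {
  y <- as.integer(y_obs)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("ROC needs at least one member of each class", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)   # one point per distinct threshold
  tpr <- cumsum(y == 1L)[keep] / n1
  fpr <- cumsum(y == 0L)[keep] / n0
  out <- data.frame(threshold = c(Inf, s[keep]), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(out$fpr) * (head(out$tpr, -1) + out$tpr[-1]) / 2)
  attr(out, "auc") <- auc
  out
}

#' Write ROC points to CSV
#'
#' @param roc output of [roc_points()].
#' @param path file path.
#' @export
write_roc <- function(roc, path) {
  write.csv(roc, path, row.names = FALSE)
  invisible(path)
}

#' Ranked feature importances for a trained model
#'
#' LDA ranks by absolute coefficient on the (standardized) feature columns;
#' the tree families (RF, DT, GB, XGB) rank by split gain / impurity
#' importance. Ties break by registry column order. SVM and KNN expose no
#' intrinsic importances.
#'
#' @param model an `ifptml_model`.
#' @param top_n number of features to return (truncated to the available
#'   count, no padding).
#' @return data.frame with columns `feature`, `weight`, ordered by
#'   decreasing weight.
#' @export
feature_importance <- function(model, top_n = 20) {
  stopifnot(inherits(model, "ifptml_model"))
  w <- switch(model$family,
    LDA = abs(model$fit$w),
    RF = {
      imp <- randomForest::importance(model$fit)
      setNames(imp[, 1], rownames(imp))
    },
    DT = {
      imp <- model$fit$variable.importance
      if (is.null(imp)) setNames(numeric(0), character(0)) else imp
    },
    GB = ,
    XGB = {
      imp <- xgboost::xgb.importance(model = model$fit)
      setNames(imp$Gain, imp$Feature)
    },
    stop("capability error: no intrinsic importances for family ",
         model$family, call. = FALSE))
  full <- setNames(rep(0, length(model$registry)), model$registry)
  full[names(w)] <- w
  # stable sort preserves registry order among ties
  ord <- order(-full)
  out <- data.frame(feature = names(full)[ord], weight = unname(full[ord]),
                    stringsAsFactors = FALSE)
  head(out, top_n)
}
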