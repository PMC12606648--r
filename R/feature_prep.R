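#' Variance-threshold feature filter
#'
#' Drops every column whose sample variance is strictly below `threshold`.
#' No column is special-cased: the reference-function column survives only
#' if its variance clears the threshold.
#'
#' @param fm numeric feature matrix (no non-finite entries).
#' @param threshold minimum sample variance to retain a column.
#' @return list with elements `features` (the filtered matrix) and `report`
#'   (an `ifptml_filter_report`).
#' @export
variance_filter <- function(fm, threshold = 0.01) {
  fm <- as.matrix(fm)
  stopifnot(all(is.finite(fm)))
  v <- apply(fm, 2, var)
  drop <- v < threshold
  if (all(drop)) stop("degenerate matrix: every column dropped", call. = FALSE)
  kept <- fm[, !drop, drop = FALSE]
  report <- structure(list(
    step = "variance",
    threshold = threshold,
    dropped_by_variance = colnames(fm)[drop],
    dropped_by_correlation = data.frame(kept = character(),
                                        dropped = character(), r = numeric()),
    retained = colnames(kept)
  ), class = "ifptml_filter_report")
  list(features = keep_attrs(kept, fm), report = report)
}

#' Correlation-based feature de-duplication
#'
#' Greedy scan in registry (column) order: each column is compared against
#' every earlier *surviving* column and dropped as redundant the first time
#' its absolute Pearson correlation exceeds `r_max`. Deterministic given the
#' column order; run after [variance_filter()] so no constant columns remain.
#'
#' @param fm numeric feature matrix.
#' @param r_max maximum tolerated absolute pairwise Pearson correlation.
#' @return list with `features` and `report` as in [variance_filter()].
#' @export
correlation_filter <- function(fm, r_max = 0.97) {
  fm <- as.matrix(fm)
  stopifnot(all(is.finite(fm)))
  p <- ncol(fm)
  if (p == 0L) stop("degenerate matrix: no columns", call. = FALSE)
  C <- abs(suppressWarnings(cor(fm)))
  keep <- logical(p)
  keep[1] <- TRUE
  pairs <- list()
  for (j in seq_len(p)[-1]) {
    earlier <- which(keep[seq_len(j - 1L)])
    hit <- earlier[C[earlier, j] > r_max]
    if (length(hit)) {
      k <- hit[1]
      pairs[[length(pairs) + 1L]] <-
        data.frame(kept = colnames(fm)[k], dropped = colnames(fm)[j],
                   r = cor(fm[, k], fm[, j]), stringsAsFactors = FALSE)
    } else keep[j] <- TRUE
  }
  kept <- fm[, keep, drop = FALSE]
  report <- structure(list(
    step = "correlation",
    threshold = r_max,
    dropped_by_variance = character(),
    dropped_by_correlation = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(kept = character(), dropped = character(), r = numeric()),
    retained = colnames(kept)
  ), class = "ifptml_filter_report")
  list(features = keep_attrs(kept, fm), report = report)
}

#' Standardize feature columns
#'
#' Fits per-column means and population standard deviations (zero mean,
#' unit variance, `n` denominator — the usual machine-learning scaler
#' convention, so `{1, 2, 3}` maps to `{-1.2247, 0, 1.2247}`) or, when
#' `params` is supplied, reapplies previously fitted parameters verbatim —
#' the transform used for new rows at prediction time.
#'
#' @param fm numeric feature matrix.
#' @param params optional list with `center` and `scale` from a prior fit.
#' @return list with `features` (standardized matrix) and `params`.
#' @export
standardize <- function(fm, params = NULL) {
  fm <- as.matrix(fm)
  if (is.null(params)) {
    center <- colMeans(fm)
    n <- nrow(fm)
    scale <- apply(fm, 2, sd) * sqrt((n - 1) / n)
    if (any(scale == 0))
      stop("zero-scale column '", colnames(fm)[scale == 0][1],
           "'; run the variance filter first", call. = FALSE)
    params <- list(center = center, scale = scale)
  } else {
    if (!identical(names(params$center), colnames(fm)))
      stop("standardization params do not match columns", call. = FALSE)
  }
  out <- sweep(sweep(fm, 2, params$center, "-"), 2, params$scale, "/")
  list(features = keep_attrs(out, fm), params = params)
}

# carry the column registry through filtering steps
keep_attrs <- function(new, old) {
  reg <- attr(old, "registry")
  if (!is.null(reg))
    attr(new, "registry") <- reg[reg$column %in% colnames(new), , drop = FALSE]
  fb <- attr(old, "fallback")
  if (!is.null(fb)) attr(new, "fallback") <- fb
  class(new) <- class(old)
  new
}

#' @export
print.ifptml_filter_report <- function(x, ...) {
  cat(sprintf("ifptml %s filter (threshold %g)\n", x$step, x$threshold))
  cat(sprintf("  retained %d columns; dropped %d by variance, %d by correlation\n",
              length(x$retained), length(x$dropped_by_variance),
              nrow(x$dropped_by_correlation)))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report an `ifptml_filter_report` (or a list of them).
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  if (inherits(report, "ifptml_filter_report")) report <- list(report)
  jsonlite::write_json(lapply(report, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
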