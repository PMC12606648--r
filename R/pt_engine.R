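# ---- condition grouping -----------------------------------------------------

# the two moving-average groupings: assay conditions (c1..c5) and data
# conditions (c6..c10); the reference function conditions on the full c0..c10
group_columns <- function(schema, group = c("assay", "dat", "ref")) {
  group <- match.arg(group)
  cc <- schema$condition_columns
  switch(group, assay = cc[2:6], dat = cc[7:11], ref = cc[1:11])
}

# collapse a tuple of condition values into a single grouping key;
# \x1f (unit separator) cannot occur in CSV-sourced condition text
condition_key <- function(df, cols) {
  if (!nrow(df)) return(character())
  do.call(paste, c(unname(df[cols]), list(sep = "\x1f")))
}

delta_names <- function(cols, group) paste0("d", group, "_", cols)

# ---- moving averages --------------------------------------------------------

#' Fit the moving-average (expected descriptor) tables
#'
#' For each of the two condition groupings — assay conditions
#' `c_assay = (c1..c5)` and data conditions `c_dat = (c6..c10)` — computes
#' the mean of every registered descriptor (drug block, protein block and
#' assay variables) over the records sharing the grouping's full level
#' tuple: the Box–Jenkins moving-average expectation ⟨Dk(cj)⟩. Per-key
#' support counts and scope-wide global means (the fallback for unseen
#' tuples) are stored alongside.
#'
#' @param ds an `ifptml_dataset`.
#' @param scope `"full"` fits on every record (the classic, pre-split
#'   convention); `"train_only"` restricts fitting to `train_idx`.
#' @param train_idx integer/logical row index, required when
#'   `scope = "train_only"`.
#' @return an object of class `ifptml_ma`.
#' @export
fit_moving_averages <- function(ds, scope = c("full", "train_only"),
                                train_idx = NULL) {
  stopifnot(inherits(ds, "ifptml_dataset"))
  scope <- match.arg(scope)
  d <- ds$data
  if (scope == "train_only") {
    if (is.null(train_idx)) stop("train_idx required for train_only scope",
                                 call. = FALSE)
    d <- d[train_idx, , drop = FALSE]
  }
  if (!nrow(d)) stop("fit error: empty dataset", call. = FALSE)
  desc <- numeric_roles(ds$schema)
  X <- as.matrix(d[, desc, drop = FALSE])
  if (any(is.na(X)))
    stop("fit error: missing descriptor values; impute or drop first",
         call. = FALSE)

  fit_group <- function(group) {
    cols <- group_columns(ds$schema, group)
    key <- condition_key(d, cols)
    # deterministic regardless of row order: key-sorted table
    ord <- sort(unique(key))
    n <- as.vector(table(factor(key, levels = ord)))
    sums <- rowsum(X, group = factor(key, levels = ord))
    means <- sums / n
    keys_df <- as.data.frame(do.call(rbind, strsplit(ord, "\x1f", fixed = TRUE)),
                             stringsAsFactors = FALSE)
    names(keys_df) <- cols
    list(columns = cols, key = ord, n = n, means = means, keys = keys_df)
  }

  structure(list(
    assay = fit_group("assay"),
    dat = fit_group("dat"),
    descriptors = desc,
    global = colMeans(X),
    scope = scope
  ), class = "ifptml_ma")
}

#' @export
print.ifptml_ma <- function(x, ...) {
  cat(sprintf("ifptml moving-average table (%s scope)\n", x$scope))
  cat(sprintf("  assay groups (c1..c5): %d tuples\n", length(x$assay$key)))
  cat(sprintf("  data groups  (c6..c10): %d tuples\n", length(x$dat$key)))
  cat(sprintf("  descriptors: %d\n", length(x$descriptors)))
  invisible(x)
}

# look up group means for a set of records; returns matrix rows aligned with d
ma_lookup <- function(ma, tab, d, schema, unseen = c("global", "error")) {
  unseen <- match.arg(unseen)
  key <- condition_key(d, tab$columns)
  pos <- match(key, tab$key)
  out <- matrix(NA_real_, nrow(d), length(ma$descriptors),
                dimnames = list(NULL, ma$descriptors))
  hit <- !is.na(pos)
  if (any(hit)) out[hit, ] <- tab$means[pos[hit], , drop = FALSE]
  if (any(!hit)) {
    if (unseen == "error")
      stop("lookup error: unseen condition tuple '",
           gsub("\x1f", " | ", key[!hit][1], fixed = TRUE), "'", call. = FALSE)
    out[!hit, ] <- matrix(ma$global, sum(!hit), length(ma$global), byrow = TRUE)
  }
  attr(out, "fallback") <- !hit
  out
}

#' Compute the perturbation-theory delta operators
#'
#' For every registered descriptor and each of the two condition groupings,
#' the delta operator is the record's deviation from the group expectation:
#' `ΔDk(cj) = Dk − ⟨Dk(cj)⟩`. Records whose tuple was not seen when the
#' moving averages were fitted fall back to the scope-wide global descriptor
#' mean (or raise, per `unseen`).
#'
#' @param ds an `ifptml_dataset`.
#' @param ma an `ifptml_ma` from [fit_moving_averages()].
#' @param unseen `"global"` (default fallback) or `"error"`.
#' @return a numeric matrix with `2 * p` columns named `dassay_*` / `ddat_*`,
#'   row-aligned with the dataset; attribute `"fallback"` flags rows that
#'   used the global fallback in either grouping.
#' @export
apply_deltas <- function(ds, ma, unseen = c("global", "error")) {
  stopifnot(inherits(ds, "ifptml_dataset"), inherits(ma, "ifptml_ma"))
  unseen <- match.arg(unseen)
  d <- ds$data
  X <- as.matrix(d[, ma$descriptors, drop = FALSE])
  ea <- ma_lookup(ma, ma$assay, d, ds$schema, unseen)
  ed <- ma_lookup(ma, ma$dat, d, ds$schema, unseen)
  da <- X - ea
  dd <- X - ed
  colnames(da) <- delta_names(ma$descriptors, "assay")
  colnames(dd) <- delta_names(ma$descriptors, "dat")
  out <- cbind(da, dd)
  if (any(!is.finite(out))) stop("non-finite delta produced", call. = FALSE)
  attr(out, "fallback") <- attr(ea, "fallback") | attr(ed, "fallback")
  out
}

# ---- reference function -----------------------------------------------------

#' Fit the conditional reference function
#'
#' The reference function f(vij)ref is the empirical probability of activity
#' among records sharing the full boundary-condition tuple (c0..c10):
#' `f_ref(key) = n(label = 1 | key) / n(key)`. Sparse tuples at prediction
#' time resolve through the fallback chain exact tuple → (c0, c10) pair →
#' global prevalence.
#'
#' @param ds a labeled `ifptml_dataset` (see [label_dataset()]).
#' @param scope `"full"` or `"train_only"` (with `train_idx`).
#' @param train_idx rows defining the train-only fit scope.
#' @return an object of class `ifptml_ref` with the tuple table, the
#'   (c0, c10) backoff table and the global prevalence.
#' @export
fit_reference <- function(ds, scope = c("full", "train_only"),
                          train_idx = NULL) {
  stopifnot(inherits(ds, "ifptml_dataset"))
  scope <- match.arg(scope)
  d <- ds$data
  if (is.null(d$label) || any(is.na(d$label)))
    stop("state error: dataset must be fully labeled", call. = FALSE)
  if (scope == "train_only") {
    if (is.null(train_idx)) stop("train_idx required for train_only scope",
                                 call. = FALSE)
    d <- d[train_idx, , drop = FALSE]
  }
  if (!nrow(d)) stop("fit error: empty dataset", call. = FALSE)

  prev_table <- function(cols) {
    key <- condition_key(d, cols)
    ord <- sort(unique(key))
    f <- factor(key, levels = ord)
    n <- as.vector(table(f))
    n1 <- as.vector(rowsum(d$label, f))
    list(columns = cols, key = ord, n = n, n_active = n1, f_ref = n1 / n)
  }
  cc <- ds$schema$condition_columns
  structure(list(
    exact = prev_table(cc),                 # full c0..c10 tuple
    backoff = prev_table(cc[c(1, 11)]),     # (c0, c10) pair
    global = mean(d$label),
    scope = scope
  ), class = "ifptml_ref")
}

#' @export
print.ifptml_ref <- function(x, ...) {
  cat(sprintf("ifptml reference function (%s scope)\n", x$scope))
  cat(sprintf("  %d condition tuples; global prevalence %.3f\n",
              length(x$exact$key), x$global))
  invisible(x)
}

#' Look up reference-function values with the fallback chain
#'
#' @param ref an `ifptml_ref`.
#' @param d data.frame of records carrying the condition columns.
#' @return numeric vector in \[0, 1\]; attribute `"provenance"` says per row
#'   whether the exact tuple, the (c0, c10) backoff or the global prevalence
#'   was used.
#' @export
reference_lookup <- function(ref, d) {
  stopifnot(inherits(ref, "ifptml_ref"))
  key <- condition_key(d, ref$exact$columns)
  pos <- match(key, ref$exact$key)
  out <- ref$exact$f_ref[pos]
  prov <- rep("exact", nrow(d))
  miss <- is.na(pos)
  if (any(miss)) {
    bkey <- condition_key(d[miss, , drop = FALSE], ref$backoff$columns)
    bpos <- match(bkey, ref$backoff$key)
    out[miss] <- ref$backoff$f_ref[bpos]
    prov[miss] <- ifelse(is.na(bpos), "global", "backoff")
    out[miss][is.na(bpos)] <- ref$global
  }
  attr(out, "provenance") <- prov
  out
}

# ---- feature assembly -------------------------------------------------------

#' Assemble the model-ready feature matrix
#'
#' Columns are ordered `[f_ref | raw descriptors | Δ(assay) | Δ(dat)]`, i.e.
#' `1 + p + 2p` columns for `p` registered descriptors, row-aligned with the
#' dataset. A column provenance registry (`"registry"` attribute) records
#' each column's source block.
#'
#' @param ds an `ifptml_dataset`.
#' @param ma an `ifptml_ma`.
#' @param ref an `ifptml_ref`.
#' @param unseen fallback rule for unseen moving-average tuples.
#' @return a numeric matrix of class `ifptml_features` with attributes
#'   `"registry"` (data.frame column/block) and `"fallback"`.
#' @export
assemble_features <- function(ds, ma, ref, unseen = c("global", "error")) {
  stopifnot(inherits(ds, "ifptml_dataset"))
  unseen <- match.arg(unseen)
  d <- ds$data
  f_ref <- reference_lookup(ref, d)
  raw <- as.matrix(d[, ma$descriptors, drop = FALSE])
  deltas <- apply_deltas(ds, ma, unseen)
  fm <- cbind(f_ref = as.numeric(f_ref), raw, deltas)
  if (any(!is.finite(fm)))
    stop("non-finite entry in assembled feature matrix", call. = FALSE)
  registry <- data.frame(
    column = colnames(fm),
    block = c("reference", rep("raw", ncol(raw)),
              rep("delta_assay", length(ma$descriptors)),
              rep("delta_dat", length(ma$descriptors))),
    stringsAsFactors = FALSE)
  structure(fm, registry = registry,
            fallback = attr(deltas, "fallback"),
            ref_provenance = attr(f_ref, "provenance"),
            class = c("ifptml_features", class(fm)))
}
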