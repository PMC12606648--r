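#' Enumerate the distinct assay-condition tuples of a dataset
#'
#' Returns every distinct combination of target, boundary conditions
#' (c0..c10) and protein-domain descriptors present in the data and passing
#' the filter, in a deterministic (sorted) order. The assay variables are
#' attached as their within-tuple means so a screening grid can be scored
#' without per-record concentrations (query compounds may override them).
#'
#' @param ds an `ifptml_dataset`.
#' @param filter optional named list restricting condition columns to given
#'   values, e.g. `list(c10 = "B", c4 = "org_L1")`.
#' @return data.frame of condition tuples with protein descriptors and mean
#'   assay variables; zero rows (with a warning) when nothing matches.
#' @export
enumerate_conditions <- function(ds, filter = NULL) {
  stopifnot(inherits(ds, "ifptml_dataset"))
  sch <- ds$schema
  d <- ds$data
  if (!is.null(filter)) {
    for (col in names(filter)) {
      if (!col %in% names(d))
        stop("unknown filter column '", col, "'", call. = FALSE)
      d <- d[d[[col]] %in% filter[[col]], , drop = FALSE]
    }
  }
  if (!nrow(d)) {
    warning("condition filter matched no records")
    return(d[, c(sch$target_column, sch$condition_columns,
                 sch$protein_descriptor_columns, sch$variable_columns),
             drop = FALSE])
  }
  keycols <- c(sch$target_column, sch$condition_columns,
               sch$protein_descriptor_columns)
  key <- do.call(paste, c(unname(d[keycols]), list(sep = "\x1f")))
  first <- !duplicated(key)
  out <- d[first, keycols, drop = FALSE]
  grp <- factor(key, levels = key[first])
  for (vc in sch$variable_columns)
    out[[vc]] <- as.numeric(tapply(d[[vc]], grp, mean))
  ord <- do.call(order, unname(out[c(sch$target_column,
                                     sch$condition_columns)]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score new compounds across enumerated condition tuples
#'
#' For each (query compound, condition tuple) pair the perturbation-theory
#' deltas are computed against the *stored* moving-average table (the query
#' descriptors minus the fitted group means — the tables are never refitted),
#' the reference function is looked up through its fallback chain, the
#' stored filtering/standardization is reapplied, and the model is scored.
#' Fallback usage is recorded per row.
#'
#' @param model an `ifptml_model`.
#' @param ma fitted `ifptml_ma`.
#' @param ref fitted `ifptml_ref`.
#' @param prep preprocessing snapshot: list with `columns` (retained feature
#'   columns) and `params` (standardization center/scale), as stored by
#'   [ifptml()].
#' @param queries data.frame of query compounds: a compound identifier
#'   column plus the complete drug-descriptor block; optional assay-variable
#'   columns override the tuple means.
#' @param tuples condition tuples from [enumerate_conditions()] (or rows of
#'   the original table carrying the same columns).
#' @param schema the dataset's `ifptml_schema`.
#' @return an `ifptml_grid`: data.frame with identifiers, conditions,
#'   predicted `class` and `probability`, and lookup provenance columns
#'   `ma_fallback` / `ref_source`.
#' @export
predict_new <- function(model, ma, ref, prep, queries, tuples, schema) {
  stopifnot(inherits(model, "ifptml_model"), inherits(ma, "ifptml_ma"),
            inherits(ref, "ifptml_ref"), inherits(schema, "ifptml_schema"))
  dcols <- schema$drug_descriptor_columns
  missing_d <- setdiff(dcols, names(queries))
  if (length(missing_d))
    stop("query descriptor block incomplete; missing: ",
         paste(head(missing_d, 5), collapse = ", "), call. = FALSE)
  idcol <- schema$compound_column
  if (!idcol %in% names(queries))
    stop("queries must carry a '", idcol, "' column", call. = FALSE)
  need_t <- c(schema$target_column, schema$condition_columns,
              schema$protein_descriptor_columns)
  missing_t <- setdiff(need_t, names(tuples))
  if (length(missing_t))
    stop("tuples lack column(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)

  nq <- nrow(queries); nt <- nrow(tuples)
  qi <- rep(seq_len(nq), each = nt)
  ti <- rep(seq_len(nt), times = nq)
  grid <- cbind(queries[qi, c(idcol, dcols), drop = FALSE],
                tuples[ti, , drop = FALSE])
  # assay variables: tuple means unless the query overrides them
  for (vc in schema$variable_columns) {
    if (vc %in% names(queries)) {
      ov <- queries[[vc]][qi]
      grid[[vc]] <- ifelse(is.na(ov), tuples[[vc]][ti], ov)
    } else grid[[vc]] <- tuples[[vc]][ti]
  }
  rownames(grid) <- NULL

  X <- as.matrix(grid[, ma$descriptors, drop = FALSE])
  ea <- ma_lookup(ma, ma$assay, grid, schema, unseen = "global")
  ed <- ma_lookup(ma, ma$dat, grid, schema, unseen = "global")
  da <- X - ea; colnames(da) <- delta_names(ma$descriptors, "assay")
  dd <- X - ed; colnames(dd) <- delta_names(ma$descriptors, "dat")
  f_ref <- reference_lookup(ref, grid)
  fm <- cbind(f_ref = as.numeric(f_ref), X, da, dd)
  fm <- fm[, prep$columns, drop = FALSE]
  fm <- standardize(fm, prep$params)$features
  pred <- predict(model, fm, type = "both")

  out <- cbind(grid[, c(idcol, schema$target_column,
                        schema$condition_columns, schema$variable_columns),
                    drop = FALSE],
               pred,
               ma_fallback = attr(ea, "fallback") | attr(ed, "fallback"),
               ref_source = attr(f_ref, "provenance"))
  structure(out, schema = schema, class = c("ifptml_grid", class(out)))
}

#' Relative predicted outcome against a reference compound
#'
#' For every (target, compound) cell: the mean, over the grid tuples passing
#' the aggregation filter, of the predicted class difference between the
#' compound and the reference compound on the *same* tuple. Values are
#' signed reals bounded by \[-1, 1\]; a compound predicted active wherever
#' the reference is inactive scores +1. Tuples where the reference was not
#' scored are excluded and counted; empty cells are flagged, never imputed.
#'
#' @param grid an `ifptml_grid` from [predict_new()].
#' @param reference_id compound identifier of the reference.
#' @param filter optional named list restricting condition columns (e.g.
#'   binding assays on one organism).
#' @return an `ifptml_relative`: list with `delta` (targets x compounds
#'   matrix), `support` (tuples per cell), `excluded_tuples`, `filter`.
#' @export
relative_outcome <- function(grid, reference_id, filter = NULL) {
  stopifnot(inherits(grid, "ifptml_grid"))
  schema <- attr(grid, "schema")
  idcol <- schema$compound_column
  tcol <- schema$target_column
  d <- as.data.frame(grid)
  if (!is.null(filter))
    for (col in names(filter))
      d <- d[d[[col]] %in% filter[[col]], , drop = FALSE]
  if (!reference_id %in% d[[idcol]])
    stop("reference compound '", reference_id,
         "' absent from the (filtered) grid", call. = FALSE)
  tuple_key <- do.call(paste, c(unname(d[c(tcol, schema$condition_columns)]),
                                list(sep = "\x1f")))
  refrows <- d[[idcol]] == reference_id
  ref_class <- setNames(d$class[refrows], tuple_key[refrows])
  have_ref <- tuple_key %in% names(ref_class)
  excluded <- length(unique(tuple_key[!have_ref]))
  d <- d[have_ref & !refrows, , drop = FALSE]
  tuple_key <- tuple_key[have_ref & !refrows]
  diffs <- d$class - ref_class[tuple_key]

  targets <- sort(unique(as.data.frame(grid)[[tcol]]))
  compounds <- sort(setdiff(unique(as.data.frame(grid)[[idcol]]),
                            reference_id))
  delta <- matrix(NA_real_, length(targets), length(compounds),
                  dimnames = list(targets, compounds))
  support <- matrix(0L, length(targets), length(compounds),
                    dimnames = list(targets, compounds))
  if (nrow(d)) {
    agg <- aggregate(diffs, by = list(target = d[[tcol]],
                                      compound = d[[idcol]]), FUN = mean)
    cnt <- aggregate(diffs, by = list(target = d[[tcol]],
                                      compound = d[[idcol]]), FUN = length)
    idx <- cbind(match(agg$target, targets), match(agg$compound, compounds))
    delta[idx] <- agg$x
    support[idx] <- cnt$x
  }
  structure(list(delta = delta, support = support,
                 excluded_tuples = excluded, reference = reference_id,
                 filter = filter),
            class = "ifptml_relative")
}

#' @export
print.ifptml_relative <- function(x, ...) {
  cat(sprintf("relative outcome vs '%s' (%d targets x %d compounds)\n",
              x$reference, nrow(x$delta), ncol(x$delta)))
  print(round(x$delta, 2))
  if (x$excluded_tuples)
    cat(sprintf("  %d tuple(s) excluded (reference unscored)\n",
                x$excluded_tuples))
  invisible(x)
}

#' Success-probability summaries of a prediction grid
#'
#' Mean predicted probability per compound and per assay type (c10),
#' ordered by decreasing mean and then by identifier.
#'
#' @param grid an `ifptml_grid`.
#' @return list with data.frames `by_compound` and `by_assay_type`.
#' @export
success_summary <- function(grid) {
  stopifnot(inherits(grid, "ifptml_grid"))
  if (!nrow(grid)) stop("empty prediction grid", call. = FALSE)
  schema <- attr(grid, "schema")
  d <- as.data.frame(grid)
  one <- function(by) {
    agg <- aggregate(d$probability, by = list(group = d[[by]]), FUN = mean)
    names(agg) <- c(by, "mean_probability")
    agg$n <- as.vector(table(d[[by]])[agg[[by]]])
    agg[order(-agg$mean_probability, agg[[by]]), , drop = FALSE]
  }
  list(by_compound = one(schema$compound_column),
       by_assay_type = one(schema$condition_columns[11]))
}
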