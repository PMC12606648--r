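#' Assay dataset container
#'
#' Wraps a flat table of (compound, assay) records together with the column
#' registry (schema). Missing boundary-condition cells are represented by the
#' reserved level `"NA"`, which participates in grouping like any other level.
#'
#' @param data a data.frame holding one row per assay record.
#' @param schema an [ifptml_schema()] mapping columns to roles.
#' @return an object of class `ifptml_dataset`: a list with elements `data`
#'   and `schema`.
#' @export
ifptml_dataset <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "ifptml_schema"))
  needed <- c(schema$compound_column, schema$activity_column,
              schema$condition_columns, numeric_roles(schema))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  # normalise conditions: character, missing -> reserved "NA" level
  for (cc in schema$condition_columns) {
    v <- as.character(data[[cc]])
    v[is.na(v) | !nzchar(trimws(v))] <- IFPTML_NA_LEVEL
    data[[cc]] <- v
  }
  c0 <- schema$condition_columns[1]
  if (nrow(data) && any(data[[c0]] == IFPTML_NA_LEVEL))
    stop("c0 (activity-measure class) may not be missing", call. = FALSE)
  c9 <- data[[schema$condition_columns[10]]]
  bad9 <- setdiff(unique(c9), c(IFPTML_RELATIONS, IFPTML_NA_LEVEL))
  if (length(bad9))
    stop("invalid standard-relation level(s): ", paste(bad9, collapse = ", "),
         call. = FALSE)
  c10 <- data[[schema$condition_columns[11]]]
  bad10 <- setdiff(unique(c10), c(IFPTML_ASSAY_TYPES, IFPTML_NA_LEVEL))
  if (length(bad10))
    stop("invalid assay-type level(s): ", paste(bad10, collapse = ", "),
         call. = FALSE)

  # numeric blocks must be finite
  for (col in numeric_roles(schema)) {
    v <- data[[col]]
    if (!is.numeric(v))
      stop("parse error: column '", col, "' is not numeric", call. = FALSE)
    if (col %in% schema$variable_columns) {
      if (any(v[!is.na(v)] < 0))
        stop("assay variable '", col, "' has negative values", call. = FALSE)
      if (any(is.nan(v) | is.infinite(v)))
        stop("non-finite value in column '", col, "'", call. = FALSE)
    } else if (any(!is.finite(v)))
      stop("non-finite value in column '", col, "' (row ",
           which(!is.finite(v))[1], ")", call. = FALSE)
  }
  av <- data[[schema$activity_column]]
  if (!is.numeric(av))
    stop("parse error: activity column is not numeric", call. = FALSE)
  if (any(is.nan(av) | is.infinite(av)))
    stop("activity_value must be finite when present", call. = FALSE)
  if (nrow(data) && any(!nzchar(as.character(data[[schema$compound_column]]))))
    stop("compound_id must be non-empty", call. = FALSE)
  if (!is.null(data$label) && !all(data$label %in% c(0L, 1L, NA)))
    stop("label must be 0/1", call. = FALSE)

  structure(list(data = data, schema = schema), class = "ifptml_dataset")
}

#' Load an assay table from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row) and validates it against the
#' schema. Categorical cells that are empty or literal `NA` are mapped to the
#' reserved `"NA"` level; numeric cells must parse with a locale-independent
#' decimal point (thousands separators are rejected as parse errors).
#'
#' @param path CSV file path.
#' @param schema an [ifptml_schema()], or a path to a YAML/JSON schema file.
#' @return an `ifptml_dataset`.
#' @export
load_dataset <- function(path, schema = default_schema()) {
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "ifptml_schema"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character", na.strings = character()),
    error = function(e) stop("schema error: cannot read '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!nrow(df) && !ncol(df)) stop("schema error: empty file", call. = FALSE)

  needed <- c(schema$compound_column, schema$activity_column,
              schema$condition_columns, numeric_roles(schema))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  for (col in c(schema$activity_column, numeric_roles(schema))) {
    raw <- trimws(df[[col]])
    empty <- !nzchar(raw) | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stop("parse error: non-numeric value '", raw[bad[1]], "' in column '",
           col, "' (row ", bad[1], ")", call. = FALSE)
    num[empty] <- NA_real_
    df[[col]] <- num
  }
  lc <- schema$label_column
  if (!is.null(lc) && lc %in% names(df)) {
    raw <- trimws(df[[lc]])
    df[[lc]] <- suppressWarnings(as.integer(raw))
  }
  ds <- ifptml_dataset(df, schema)
  message(sprintf("loaded %d records, %d distinct compounds",
                  nrow(ds$data),
                  length(unique(ds$data[[schema$compound_column]]))))
  ds
}

#' Write an assay dataset back to CSV
#'
#' The output is re-readable by [load_dataset()] with the same schema; the
#' reserved `"NA"` condition level is written as the literal token `NA`.
#' Column order follows the registry: identifiers, activity, conditions,
#' drug/protein descriptors, variables, then any extra columns.
#'
#' @param ds an `ifptml_dataset`.
#' @param path output path.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "ifptml_dataset"))
  sch <- ds$schema
  ordered <- c(sch$compound_column, sch$target_column, sch$activity_column,
               sch$condition_columns, sch$drug_descriptor_columns,
               sch$protein_descriptor_columns, sch$variable_columns)
  ordered <- intersect(ordered, names(ds$data))
  extra <- setdiff(names(ds$data), ordered)
  write.csv(ds$data[, c(ordered, extra), drop = FALSE], path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' Validation report for an assay dataset
#'
#' Report-only: never raises. Lists per-column missingness, level
#' cardinalities of every boundary-condition field (the reserved `"NA"`
#' counts as a level) and the range of every numeric descriptor.
#'
#' @param ds an `ifptml_dataset`.
#' @return an object of class `ifptml_validation` with elements
#'   `n_records`, `n_compounds`, `missingness`, `cardinality`, `ranges`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "ifptml_dataset"))
  sch <- ds$schema
  d <- ds$data
  card <- vapply(sch$condition_columns,
                 function(cc) length(unique(d[[cc]])), integer(1))
  names(card) <- paste0("c", 0:10)
  miss <- vapply(names(d), function(col) {
    v <- d[[col]]
    if (is.numeric(v)) mean(is.na(v)) else mean(v == IFPTML_NA_LEVEL)
  }, numeric(1))
  nr <- numeric_roles(sch)
  ranges <- if (nrow(d)) {
    t(vapply(nr, function(col) range(d[[col]], na.rm = TRUE), numeric(2)))
  } else matrix(NA_real_, 0, 2)
  structure(list(
    n_records = nrow(d),
    n_compounds = length(unique(d[[sch$compound_column]])),
    missingness = miss,
    cardinality = card,
    ranges = ranges
  ), class = "ifptml_validation")
}

#' @export
print.ifptml_validation <- function(x, ...) {
  cat("ifptml dataset validation\n")
  cat(sprintf("  records: %d   compounds: %d\n", x$n_records, x$n_compounds))
  cat("  condition cardinalities:\n")
  print(x$cardinality)
  high <- sort(x$missingness[x$missingness > 0], decreasing = TRUE)
  if (length(high)) {
    cat("  columns with missingness:\n")
    print(round(head(high, 10), 3))
  }
  invisible(x)
}

#' @export
print.ifptml_dataset <- function(x, ...) {
  cat(sprintf("ifptml_dataset: %d records, %d compounds, %d targets\n",
              nrow(x$data),
              length(unique(x$data[[x$schema$compound_column]])),
              length(unique(x$data[[x$schema$target_column]]))))
  if (!is.null(x$data$label))
    cat(sprintf("  labeled: %d active / %d inactive\n",
                sum(x$data$label == 1L), sum(x$data$label == 0L)))
  invisible(x)
}
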