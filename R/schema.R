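#' Column-role schema for assay tables
#'
#' An assay table is a flat CSV with one row per (compound, assay) pair.
#' The schema maps column names to roles so that the same code reads both
#' the deposited-style headers and synthetic headers: the activity value,
#' the eleven ordered boundary-condition columns c0..c10, the drug
#' descriptor block, the protein-domain descriptor block and the assay
#' variables (concentrations).
#'
#' @param activity_column name of the raw activity value column (v_ij).
#' @param condition_columns character vector of length 11, ordered c0..c10:
#'   activity-measure class, target name, assay cell type, assay tissue,
#'   target organism, assay organism, target type, subcellular fraction,
#'   buffer, standard relation, assay type.
#' @param drug_descriptor_columns compound descriptor columns (continuous).
#' @param protein_descriptor_columns protein-domain descriptor columns.
#' @param variable_columns assay variable columns (substrate / inhibitor
#'   concentration), treated like descriptors for delta computation.
#' @param compound_column,target_column identifier columns.
#' @param label_column optional column holding an already-assigned 0/1 label.
#' @return an object of class `ifptml_schema`.
#' @seealso [load_dataset()], [default_schema()]
#' @export
ifptml_schema <- function(activity_column,
                          condition_columns,
                          drug_descriptor_columns,
                          protein_descriptor_columns,
                          variable_columns = character(),
                          compound_column = "compound_id",
                          target_column = "target_id",
                          label_column = NULL) {
  if (length(condition_columns) != 11L)
    stop("`condition_columns` must name the 11 boundary conditions c0..c10, got ",
         length(condition_columns), call. = FALSE)
  stopifnot(is.character(activity_column), length(activity_column) == 1L)
  sch <- list(
    activity_column = activity_column,
    condition_columns = as.character(condition_columns),
    drug_descriptor_columns = as.character(drug_descriptor_columns),
    protein_descriptor_columns = as.character(protein_descriptor_columns),
    variable_columns = as.character(variable_columns),
    compound_column = compound_column,
    target_column = target_column,
    label_column = label_column
  )
  dup <- duplicated(unlist(sch[c("activity_column", "condition_columns",
                                 "drug_descriptor_columns",
                                 "protein_descriptor_columns",
                                 "variable_columns")]))
  if (any(dup))
    stop("schema assigns the same column to two roles", call. = FALSE)
  structure(sch, class = "ifptml_schema")
}

#' Default schema matching the headers written by the synthetic generator
#'
#' @param n_drug number of generic drug descriptor columns (D001...), on top
#'   of the three named descriptors MW, LRO5 and ALOGP.
#' @param n_protein number of protein-domain descriptor columns (P001...).
#' @return an `ifptml_schema`.
#' @export
default_schema <- function(n_drug = 105L, n_protein = 15L) {
  ifptml_schema(
    activity_column = "activity_value",
    condition_columns = paste0("c", 0:10),
    drug_descriptor_columns = c("MW", "LRO5", "ALOGP",
                                sprintf("D%03d", seq_len(n_drug))),
    protein_descriptor_columns = sprintf("P%03d", seq_len(n_protein)),
    variable_columns = c("V1", "V2")
  )
}

#' Read or write a schema as YAML/JSON
#'
#' The on-disk representation uses the keys `activity_column`,
#' `condition_columns`, `drug_descriptor_columns`,
#' `protein_descriptor_columns`, `variable_columns`, `compound_column`,
#' `target_column`.
#'
#' @param path file path; format chosen by extension (`.json` vs YAML).
#' @return `read_schema()` returns an `ifptml_schema`.
#' @export
read_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  ifptml_schema(
    activity_column = raw$activity_column,
    condition_columns = raw$condition_columns,
    drug_descriptor_columns = raw$drug_descriptor_columns,
    protein_descriptor_columns = raw$protein_descriptor_columns,
    variable_columns = raw$variable_columns %||% character(),
    compound_column = raw$compound_column %||% "compound_id",
    target_column = raw$target_column %||% "target_id",
    label_column = raw$label_column
  )
}

#' @rdname read_schema
#' @param schema an `ifptml_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "ifptml_schema"))
  x <- unclass(schema)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all columns carrying numeric measurements, in registry order
numeric_roles <- function(schema) {
  c(schema$drug_descriptor_columns, schema$protein_descriptor_columns,
    schema$variable_columns)
}

#' @export
print.ifptml_schema <- function(x, ...) {
  cat("ifptml column schema\n")
  cat("  activity:   ", x$activity_column, "\n")
  cat("  conditions: ", paste(x$condition_columns, collapse = ", "), "\n")
  cat("  drug descriptors:    ", length(x$drug_descriptor_columns), "\n")
  cat("  protein descriptors: ", length(x$protein_descriptor_columns), "\n")
  cat("  assay variables:     ", length(x$variable_columns), "\n")
  invisible(x)
}
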