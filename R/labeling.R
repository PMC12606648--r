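#' Desirability rules and labeling policy
#'
#' Every activity-measure class (c0 level) carries a desirability
#' `d` ∈ {+1, −1} saying whether the raw value should be maximized or
#' minimized for a record to count as active, plus a cut-off. Cut-offs are
#' either fixed in the measure's native units or resolved at fit time as the
#' dataset mean of the activity values inside that c0 level.
#'
#' @param measure c0 level the rule applies to.
#' @param d +1 (maximize) or -1 (minimize).
#' @param cutoff_kind "fixed" or "dataset_mean".
#' @param cutoff_value cut-off in the measure's units (NA until resolved for
#'   dataset_mean rules).
#' @return a one-row data.frame.
#' @export
desirability_rule <- function(measure, d, cutoff_kind = "fixed",
                              cutoff_value = NA_real_) {
  if (!d %in% c(-1L, 1L)) stop("d must be +1 or -1", call. = FALSE)
  if (!cutoff_kind %in% c("fixed", "dataset_mean"))
    stop("cutoff_kind must be 'fixed' or 'dataset_mean'", call. = FALSE)
  if (cutoff_kind == "fixed" && !is.finite(cutoff_value))
    stop("fixed cut-off must be finite", call. = FALSE)
  data.frame(measure = measure, d = as.integer(d), cutoff_kind = cutoff_kind,
             cutoff_value = as.numeric(cutoff_value),
             stringsAsFactors = FALSE)
}

# measure-name tokens with standard thresholds
PCT_MEASURES <- c("residual activity", "inhibition", "metabolism", "activity")
CONC_MEASURES <- c("ic50", "ki", "potency", "kd", "km")

#' Default labeling policy for a dataset
#'
#' Standard potency / screening criteria: percentage-type measures (residual
#' activity, inhibition, metabolism, activity, or any measure whose label
#' carries a `%` unit) get `d = +1` with a fixed 70 (%) cut-off;
#' concentration-type measures (IC50, Ki, potency, Kd, Km) get `d = -1` with
#' a fixed 100 (nM) cut-off. Every other c0 level present in the data gets
#' `d = default_d` and a `dataset_mean` cut-off resolved as the mean activity
#' value within that level. Explicit `overrides` rules win over defaults.
#'
#' @param ds an `ifptml_dataset`.
#' @param overrides optional data.frame of [desirability_rule()] rows.
#' @param default_d desirability assigned to measures with no standard rule.
#' @param pct_cutoff,conc_cutoff the fixed thresholds (70 % and 100 nM).
#' @return an object of class `ifptml_policy` (a data.frame of rules).
#' @export
default_policy <- function(ds, overrides = NULL, default_d = 1L,
                           pct_cutoff = 70, conc_cutoff = 100) {
  stopifnot(inherits(ds, "ifptml_dataset"))
  c0 <- ds$schema$condition_columns[1]
  levels_c0 <- sort(unique(ds$data[[c0]]))
  rules <- lapply(levels_c0, function(m) {
    if (!is.null(overrides) && m %in% overrides$measure)
      return(overrides[overrides$measure == m, , drop = FALSE])
    low <- tolower(m)
    base <- sub("\\s*\\(.*\\)\\s*$", "", low)          # strip unit suffix
    if (base %in% PCT_MEASURES || grepl("%", m, fixed = TRUE))
      return(desirability_rule(m, +1L, "fixed", pct_cutoff))
    if (base %in% CONC_MEASURES)
      return(desirability_rule(m, -1L, "fixed", conc_cutoff))
    v <- ds$data[[ds$schema$activity_column]][ds$data[[c0]] == m]
    mu <- mean(v, na.rm = TRUE)
    if (!is.finite(mu))
      stop("policy error: no default rule resolvable for measure '", m, "'",
           call. = FALSE)
    desirability_rule(m, as.integer(default_d), "dataset_mean", mu)
  })
  pol <- do.call(rbind, rules)
  rownames(pol) <- NULL
  structure(pol, class = c("ifptml_policy", "data.frame"))
}

#' Read/write a labeling policy as YAML
#'
#' Serialized as a list of `{measure, d, cutoff_kind, cutoff_value}` entries.
#'
#' @param path YAML file path.
#' @return `read_policy()` returns an `ifptml_policy`.
#' @export
read_policy <- function(path) {
  raw <- yaml::read_yaml(path)
  pol <- do.call(rbind, lapply(raw, function(r)
    desirability_rule(r$measure, r$d, r$cutoff_kind,
                      r$cutoff_value %||% NA_real_)))
  structure(pol, class = c("ifptml_policy", "data.frame"))
}

#' @rdname read_policy
#' @param policy an `ifptml_policy`.
#' @export
write_policy <- function(policy, path) {
  entries <- lapply(seq_len(nrow(policy)), function(i) {
    r <- as.list(policy[i, , drop = FALSE])
    r <- lapply(r, function(x) if (is.na(x)) NULL else x)
    r[!vapply(r, is.null, logical(1))]
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Binarize a raw activity value into the objective function
#'
#' With desirability `d = +1` the record is active (1) iff the value is
#' strictly above the cut-off; with `d = -1` iff strictly below. Exact
#' equality always yields 0. Censored relations (`c9` of `">"` or `"<"`)
#' are handled conservatively: a record is labeled 1 only when the censoring
#' direction guarantees the desirability criterion (e.g. `< 50 nM` with
#' `d = -1` and cut-off 100 certifies activity; `< 80 %` with `d = +1` and
#' cut-off 70 does not); ambiguous censorings yield 0.
#'
#' @param v numeric vector of raw activity values.
#' @param d +1 or -1 (recycled).
#' @param cutoff resolved cut-off in the measure's units (recycled).
#' @param relation standard relation, one of `"="`, `">"`, `"<"` (or the
#'   `"NA"` level, treated as `"="`); recycled.
#' @return integer vector of 0/1 labels.
#' @export
objective_function <- function(v, d, cutoff, relation = "=") {
  n <- max(length(v), length(d), length(cutoff), length(relation))
  v <- rep_len(as.numeric(v), n)
  d <- rep_len(as.integer(d), n)
  cutoff <- rep_len(as.numeric(cutoff), n)
  relation <- rep_len(as.character(relation), n)
  relation[relation == IFPTML_NA_LEVEL] <- "="
  if (any(!is.finite(v))) stop("activity value must be finite", call. = FALSE)
  if (any(!is.finite(cutoff)))
    stop("state error: unresolved cut-off", call. = FALSE)
  if (any(!d %in% c(-1L, 1L))) stop("d must be +1 or -1", call. = FALSE)
  if (any(!relation %in% IFPTML_RELATIONS))
    stop("unknown standard relation", call. = FALSE)

  out <- integer(n)
  eq <- relation == "="
  out[eq] <- as.integer(ifelse(d[eq] > 0, v[eq] > cutoff[eq],
                               v[eq] < cutoff[eq]))
  # "<": true value strictly below v; certifies d=-1 success iff v <= cutoff
  lt <- relation == "<"
  out[lt] <- as.integer(d[lt] < 0 & v[lt] <= cutoff[lt])
  # ">": true value strictly above v; certifies d=+1 success iff v >= cutoff
  gt <- relation == ">"
  out[gt] <- as.integer(d[gt] > 0 & v[gt] >= cutoff[gt])
  out
}

#' Label every record of a dataset
#'
#' Applies the policy's resolved rules to every record, honouring the c9
#' censoring relation, and attaches the 0/1 objective function as a `label`
#' column. A class-balance report (overall and per measure class) is stored
#' in the `"balance"` attribute.
#'
#' @param ds an `ifptml_dataset`.
#' @param policy an `ifptml_policy`; defaults to [default_policy()].
#' @return the labeled `ifptml_dataset`.
#' @export
label_dataset <- function(ds, policy = default_policy(ds)) {
  stopifnot(inherits(ds, "ifptml_dataset"))
  sch <- ds$schema
  c0 <- ds$data[[sch$condition_columns[1]]]
  missing_rules <- setdiff(unique(c0), policy$measure)
  if (length(missing_rules))
    stop("policy error: no rule for measure(s): ",
         paste(missing_rules, collapse = ", "), call. = FALSE)
  if (anyDuplicated(policy$measure))
    stop("policy error: duplicated rules", call. = FALSE)
  idx <- match(c0, policy$measure)
  v <- ds$data[[sch$activity_column]]
  if (any(is.na(v)))
    stop("cannot label records with missing activity (row ",
         which(is.na(v))[1], ")", call. = FALSE)
  rel <- ds$data[[sch$condition_columns[10]]]
  lab <- objective_function(v, policy$d[idx], policy$cutoff_value[idx], rel)
  ds$data$label <- lab
  balance <- list(
    overall = c(`0` = sum(lab == 0L), `1` = sum(lab == 1L)),
    by_measure = table(measure = c0, label = lab)
  )
  attr(ds, "balance") <- balance
  ds
}
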