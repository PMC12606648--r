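# shared fixtures, all generated in code

# a quick small synthetic configuration for unit tests
small_cfg <- function(n_records = 400L, seed = 11L, ...) {
  synth_config(n_records = n_records, n_compounds = 120L, n_targets = 6L,
               n_assays = 12L, seed = seed, ...)
}

small_synth <- function(...) generate_synth(small_cfg(...))

# a hand-built 10-row dataset with a tiny descriptor registry
tiny_schema <- function() {
  ifptml_schema(
    activity_column = "act",
    condition_columns = paste0("c", 0:10),
    drug_descriptor_columns = c("D1", "D2"),
    protein_descriptor_columns = "P1",
    variable_columns = "V1")
}

tiny_dataset <- function(n = 10L) {
  set.seed(99)
  df <- data.frame(
    compound_id = paste0("cpd", seq_len(n)),
    target_id = rep(c("tA", "tB"), length.out = n),
    act = round(runif(n, 10, 500), 2),
    c0 = rep("IC50 (nM)", n),
    c1 = rep(c("tA", "tB"), length.out = n),
    c2 = rep(c("HEK293", "NA"), length.out = n),
    c3 = "NA", c4 = "Homo sapiens", c5 = "Homo sapiens",
    c6 = "SINGLE PROTEIN", c7 = "NA", c8 = "NA",
    c9 = "=",
    c10 = rep(c("B", "B", "F"), length.out = n),
    D1 = rnorm(n), D2 = rnorm(n),
    P1 = rep(c(0.3, -0.8), length.out = n),
    V1 = runif(n, 0, 10),
    stringsAsFactors = FALSE)
  ifptml_dataset(df, tiny_schema())
}

# brute-force group means: nested loops, no shared code with the package
brute_group_means <- function(df, group_cols, desc_cols) {
  keys <- unique(df[, group_cols, drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(df))
    for (g in group_cols) sel <- sel & df[[g]] == keys[i, g]
    mns <- vapply(desc_cols, function(cc) mean(df[[cc]][sel]), numeric(1))
    out[[paste(unlist(keys[i, ]), collapse = "\x1f")]] <-
      list(n = sum(sel), means = mns)
  }
  out
}
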