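test_that("group means reproduce simple hand cases", {
  ds <- tiny_dataset()
  # isolate rows 1-2 in one assay tuple with known D1 values, and give the
  # last row a tuple of its own
  d <- ds$data
  d$D1[1:2] <- c(4, 6)
  d[2, paste0("c", 1:5)] <- d[1, paste0("c", 1:5)]
  d$c2[1:2] <- "isolated-cell-line"
  d$c2[10] <- "solo-cell-line"
  ds <- ifptml_dataset(d, tiny_schema())
  ma <- fit_moving_averages(ds)
  key <- paste(unlist(d[1, paste0("c", 1:5)]), collapse = "\x1f")
  expect_equal(unname(ma$assay$means[match(key, ma$assay$key), "D1"]), 5)

  # a singleton group's mean is its own value, so its delta is 0
  deltas <- apply_deltas(ds, ma)
  singles <- which(ma$assay$n == 1)
  expect_true(length(singles) > 0)
  row <- match(ma$assay$key[singles[1]],
               ifptml:::condition_key(d, paste0("c", 1:5)))
  expect_equal(unname(deltas[row, "dassay_D1"]), 0)
})

test_that("moving averages, deltas and reference match brute-force loops", {
  sim <- small_synth(n_records = 500L, seed = 21L)
  ds <- label_dataset(sim$dataset)
  sch <- ds$schema
  desc <- c(sch$drug_descriptor_columns, sch$protein_descriptor_columns,
            sch$variable_columns)
  ma <- fit_moving_averages(ds)
  ref <- fit_reference(ds)

  for (grp in c("assay", "dat")) {
    cols <- if (grp == "assay") sch$condition_columns[2:6]
            else sch$condition_columns[7:11]
    oracle <- brute_group_means(ds$data, cols, desc)
    tab <- ma[[grp]]
    expect_setequal(tab$key, names(oracle))
    for (k in names(oracle)) {
      i <- match(k, tab$key)
      expect_identical(tab$n[i], oracle[[k]]$n)
      expect_equal(unname(tab$means[i, desc]), unname(oracle[[k]]$means),
                   tolerance = 1e-12)
    }
  }

  # deltas: direct per-row recomputation
  deltas <- apply_deltas(ds, ma)
  set.seed(1)
  for (r in sample(nrow(ds$data), 25)) {
    for (grp in c("assay", "dat")) {
      cols <- if (grp == "assay") sch$condition_columns[2:6]
              else sch$condition_columns[7:11]
      sel <- rep(TRUE, nrow(ds$data))
      for (g in cols) sel <- sel & ds$data[[g]] == ds$data[[g]][r]
      for (cc in desc[c(1, 50, 110)]) {
        expected <- ds$data[[cc]][r] - mean(ds$data[[cc]][sel])
        expect_equal(unname(deltas[r, paste0("d", grp, "_", cc)]), expected,
                     tolerance = 1e-12)
      }
    }
  }

  # reference function: conditional prevalence by nested loops
  cc <- sch$condition_columns
  key <- ifptml:::condition_key(ds$data, cc)
  for (k in sample(unique(key), 10)) {
    sel <- key == k
    i <- match(k, ref$exact$key)
    expect_equal(ref$exact$f_ref[i], mean(ds$data$label[sel]),
                 tolerance = 1e-12)
  }
  expect_equal(ref$global, mean(ds$data$label), tolerance = 1e-12)
})

test_that("delta columns have exactly zero mean within each fitted group", {
  sim <- small_synth(n_records = 400L, seed = 13L)
  ds <- sim$dataset
  ma <- fit_moving_averages(ds, scope = "full")
  deltas <- apply_deltas(ds, ma)
  for (grp in c("assay", "dat")) {
    cols <- ifptml:::group_columns(ds$schema, grp)
    key <- ifptml:::condition_key(ds$data, cols)
    dn <- paste0("d", grp, "_", ma$descriptors)
    for (k in unique(key)) {
      mns <- colMeans(deltas[key == k, dn, drop = FALSE])
      expect_true(all(abs(mns) < 1e-9))
    }
  }
})

test_that("reference values are probabilities and average to the prevalence", {
  sim <- small_synth(n_records = 400L, seed = 17L)
  ds <- label_dataset(sim$dataset)
  ref <- fit_reference(ds)
  expect_true(all(ref$exact$f_ref >= 0 & ref$exact$f_ref <= 1))
  f <- reference_lookup(ref, ds$data)
  expect_equal(mean(f * 0 + f), mean(ds$data$label), tolerance = 1e-12)
  expect_true(all(attr(f, "provenance") == "exact"))
})

test_that("fitted tables are invariant to row order", {
  sim <- small_synth(n_records = 300L, seed = 23L)
  ds <- label_dataset(sim$dataset)
  set.seed(2)
  perm <- sample(nrow(ds$data))
  ds2 <- ifptml_dataset(ds$data[perm, , drop = FALSE], ds$schema)

  ma1 <- fit_moving_averages(ds); ma2 <- fit_moving_averages(ds2)
  expect_identical(ma1$assay$key, ma2$assay$key)
  expect_equal(ma1$assay$means, ma2$assay$means, tolerance = 1e-12)
  expect_equal(ma1$dat$means, ma2$dat$means, tolerance = 1e-12)

  ref1 <- fit_reference(ds); ref2 <- fit_reference(ds2)
  expect_equal(ref1$exact$f_ref, ref2$exact$f_ref, tolerance = 1e-12)

  fm1 <- assemble_features(ds, ma1, ref1)
  fm2 <- assemble_features(ds2, ma2, ref2)
  expect_equal(unclass(fm2)[, ], unclass(fm1)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("unseen tuples follow the configured fallback", {
  sim <- small_synth(n_records = 200L, seed = 29L)
  ds <- label_dataset(sim$dataset)
  ma <- fit_moving_averages(ds)
  ref <- fit_reference(ds)

  d2 <- ds$data[1:3, , drop = FALSE]
  d2$c2 <- "never-seen-cell-line"
  ds2 <- ifptml_dataset(d2, ds$schema)

  expect_error(apply_deltas(ds2, ma, unseen = "error"), "never-seen-cell-line")
  deltas <- apply_deltas(ds2, ma, unseen = "global")
  expect_true(all(attr(deltas, "fallback")))
  expect_equal(unname(deltas[1, "dassay_MW"]),
               d2$MW[1] - ma$global[["MW"]], tolerance = 1e-12)

  # reference fallback chain: exact tuple -> (c0, c10) -> global prevalence
  f <- reference_lookup(ref, d2)
  expect_true(all(attr(f, "provenance") %in% c("backoff", "global")))
  c0c10 <- paste(d2$c0[1], d2$c10[1], sep = "\x1f")
  i <- match(c0c10, ref$backoff$key)
  if (!is.na(i)) expect_equal(f[1], ref$backoff$f_ref[i], tolerance = 1e-12)

  d3 <- d2; d3$c0 <- d3$c0  # unseen (c0, c10) combination forces global
  d3$c10 <- "P"
  ds3 <- ifptml_dataset(d3, ds$schema)
  key3 <- paste(d3$c0, d3$c10, sep = "\x1f")
  f3 <- reference_lookup(ref, d3)
  drop_to_global <- !(key3 %in% ref$backoff$key)
  expect_true(all(f3[drop_to_global] == ref$global))
})

test_that("assembled feature matrix has the documented shape and order", {
  sim <- small_synth(n_records = 150L, seed = 31L)
  ds <- label_dataset(sim$dataset)
  ma <- fit_moving_averages(ds)
  ref <- fit_reference(ds)
  fm <- assemble_features(ds, ma, ref)

  p <- length(ma$descriptors)
  expect_identical(p, 125L)           # 108 drug + 15 protein + 2 variables
  expect_identical(ncol(fm), 1L + p + 2L * p)   # 376 pre-filter columns
  expect_identical(colnames(fm)[1], "f_ref")
  reg <- attr(fm, "registry")
  expect_identical(reg$block,
                   c("reference", rep("raw", p), rep("delta_assay", p),
                     rep("delta_dat", p)))
  expect_identical(nrow(fm), nrow(ds$data))  # row order preserved
  expect_true(all(is.finite(fm)))
})
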