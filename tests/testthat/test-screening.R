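# a small fitted pipeline shared by the screening tests
screen_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_synth(n_records = 500L, seed = 19L)
      fit <- ifptml(sim$dataset, model = "LDA", seed = 19)
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})

test_that("condition enumeration respects filters deterministically", {
  ds <- tiny_dataset()
  tup <- enumerate_conditions(ds, filter = list(c10 = "B"))
  expect_true(all(tup$c10 == "B"))
  oracle <- nrow(unique(ds$data[ds$data$c10 == "B",
                                c("target_id", paste0("c", 0:10), "P1")]))
  expect_identical(nrow(tup), oracle)

  all_tup <- enumerate_conditions(ds)
  expect_identical(nrow(all_tup),
                   nrow(unique(ds$data[, c("target_id", paste0("c", 0:10),
                                           "P1")])))
  expect_identical(all_tup, enumerate_conditions(ds))  # deterministic

  expect_warning(out <- enumerate_conditions(ds, filter = list(c10 = "P")),
                 "matched no records")
  expect_identical(nrow(out), 0L)
  expect_error(enumerate_conditions(ds, filter = list(nope = "x")),
               "unknown filter column")
})

test_that("screening verbatim training rows reproduces in-sample predictions", {
  fx <- screen_fixture()
  fit <- fx$fit
  ds <- fit$dataset
  sch <- ds$schema

  rows <- ds$data[c(3, 40, 101), , drop = FALSE]
  queries <- rows[, c(sch$compound_column, sch$drug_descriptor_columns,
                      sch$variable_columns), drop = FALSE]
  tuples <- rows[, c(sch$target_column, sch$condition_columns,
                     sch$protein_descriptor_columns, sch$variable_columns),
                 drop = FALSE]
  grids <- lapply(seq_len(3), function(i)
    predict_new(fit$model, fit$ma, fit$ref, fit$prep,
                queries[i, , drop = FALSE], tuples[i, , drop = FALSE],
                sch))
  insample <- predict(fit)
  for (i in seq_len(3)) {
    expect_equal(grids[[i]]$probability,
                 insample$probability[c(3, 40, 101)[i]], tolerance = 1e-10)
    expect_false(any(grids[[i]]$ma_fallback))
    expect_identical(grids[[i]]$ref_source, "exact")
  }
})

test_that("a toy grid with hand-set coefficients matches manual arithmetic", {
  ds <- tiny_dataset()
  ds <- label_dataset(ds)
  ma <- fit_moving_averages(ds)
  ref <- fit_reference(ds)
  prep <- list(columns = c("f_ref", "D1", "dassay_D1"),
               params = list(center = c(f_ref = 0, D1 = 0, dassay_D1 = 0),
                             scale = c(f_ref = 1, D1 = 1, dassay_D1 = 1)))
  model <- lda_model_from_coefficients(
    a0 = -0.2, w = c(f_ref = 1.5, D1 = 0.8, dassay_D1 = -0.5))

  tuples <- enumerate_conditions(ds)[1:2, ]
  queries <- data.frame(compound_id = c("q1", "q2"),
                        D1 = c(0.4, -1.1), D2 = c(0, 0),
                        stringsAsFactors = FALSE)
  grid <- predict_new(model, ma, ref, prep, queries, tuples, ds$schema)
  expect_identical(nrow(grid), 4L)

  # manual Eq-style score for the first (query, tuple) pair
  akey <- paste(unlist(tuples[1, paste0("c", 1:5)]), collapse = "\x1f")
  m_d1 <- ma$assay$means[match(akey, ma$assay$key), "D1"]
  rkey <- paste(unlist(tuples[1, paste0("c", 0:10)]), collapse = "\x1f")
  f_ref <- ref$exact$f_ref[match(rkey, ref$exact$key)]
  manual <- plogis(-0.2 + 1.5 * f_ref + 0.8 * 0.4 - 0.5 * (0.4 - m_d1))
  expect_equal(grid$probability[1], unname(manual), tolerance = 1e-10)

  # incomplete descriptor block is refused
  expect_error(predict_new(model, ma, ref, prep,
                           queries[, c("compound_id", "D1")], tuples,
                           ds$schema),
               "incomplete")
})

test_that("relative outcomes are antisymmetric, bounded and zero on self", {
  fx <- screen_fixture()
  fit <- fx$fit
  sch <- fit$dataset$schema
  # three query compounds taken from the training chemical space
  base <- fit$dataset$data[!duplicated(fit$dataset$data$compound_id), ]
  queries <- base[c(1, 1, 2), c(sch$compound_column,
                                sch$drug_descriptor_columns)]
  queries[[sch$compound_column]] <- c("refc", "twin", "qA")
  grid <- screen_compounds(fit, queries)

  rel <- relative_outcome(grid, "refc")
  expect_true(all(abs(rel$delta[rel$support > 0]) <= 1 + 1e-12))
  expect_true(all(rel$support[!is.na(rel$delta)] > 0))

  # a compound identical to the reference scores exactly 0 everywhere
  twin <- rel$delta[, "twin"]
  expect_true(all(twin[rel$support[, "twin"] > 0] == 0))

  # antisymmetry: swapping roles negates every cell
  d1 <- rel$delta["T01", "qA"]
  rel2 <- relative_outcome(grid, "qA")
  d2 <- rel2$delta["T01", "refc"]
  if (!is.na(d1) && !is.na(d2)) expect_equal(d1, -d2, tolerance = 1e-12)

  expect_error(relative_outcome(grid, "missing-compound"), "absent")
})

test_that("relative outcome averages class differences per tuple", {
  # hand-built grid: compound active on 1 of 2 tuples, reference inactive on
  # both -> +0.5; a compound active wherever the reference is not -> +1
  sch <- tiny_schema()
  g <- data.frame(
    compound_id = rep(c("ref", "a", "b"), each = 2),
    target_id = "tA",
    c0 = "IC50 (nM)", c1 = "tA", c2 = "x", c3 = "NA", c4 = "o", c5 = "o",
    c6 = "sp", c7 = "NA", c8 = "NA", c9 = "=",
    c10 = rep(c("B", "F"), 3),
    V1 = 1,
    class = c(0L, 0L, 1L, 0L, 1L, 1L),
    probability = c(0.2, 0.4, 0.8, 0.3, 0.9, 0.7),
    ma_fallback = FALSE, ref_source = "exact",
    stringsAsFactors = FALSE)
  grid <- structure(g, schema = sch, class = c("ifptml_grid", "data.frame"))

  rel <- relative_outcome(grid, "ref")
  expect_equal(rel$delta["tA", "a"], 0.5)
  expect_equal(rel$delta["tA", "b"], 1)
  expect_identical(rel$support["tA", "a"], 2L)

  # aggregation filter restricts the tuple set
  relB <- relative_outcome(grid, "ref", filter = list(c10 = "B"))
  expect_equal(relB$delta["tA", "a"], 1)

  summ <- success_summary(grid)
  expect_equal(summ$by_compound$mean_probability[
    summ$by_compound$compound_id == "a"], 0.55)
  bt <- summ$by_assay_type
  expect_equal(bt$mean_probability[bt$c10 == "B"], mean(c(0.2, 0.8, 0.9)))
  # ordering: by decreasing mean, then identifier
  expect_false(is.unsorted(rev(summ$by_compound$mean_probability)))
})
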