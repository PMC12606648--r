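#' Configuration for the synthetic assay-table generator
#'
#' The generator emulates the composition of a curated multi-condition
#' bioactivity table: ~10^3 compounds assayed against a panel of targets
#' under 13 activity-measure classes (concentration-type, percentage-type
#' and measures without a standard threshold), four assay types, sparse
#' cell-type/tissue/fraction/buffer annotations (with a reserved `"NA"`
#' level), censored standard relations, correlated continuous descriptor
#' blocks with deliberately planted duplicate and near-constant columns, and
#' a latent logistic activity model with known descriptor effects and
#' per-assay condition effects. Condition cardinalities default to roughly a
#' 1/5 scale of a realistic curated panel so desk-scale runs stay fast.
#'
#' @param n_records number of (compound, assay) rows.
#' @param n_compounds,n_targets,n_assays panel sizes; each synthetic assay
#'   carries one fixed boundary-condition tuple, so records sharing an assay
#'   share conditions (as in real assay panels).
#' @param n_drug generic drug-descriptor count (plus MW, LRO5, ALOGP).
#' @param n_protein protein-domain descriptor count per target.
#' @param cardinalities named list of level counts for c2..c8 (the sparse
#'   categorical fields; c2, c3, c7, c8 include the `"NA"` level).
#' @param measure_weights length-3 numeric: sampling weight of
#'   concentration-type, percentage-type and mean-cutoff measure classes.
#' @param censored_fraction fraction of threshold-bearing rows reported with
#'   a censored standard relation (`">"`/`"<"`) instead of `"="`.
#' @param n_informative number of drug descriptors carrying the planted
#'   effect.
#' @param beta_scale standard deviation of the planted descriptor effects.
#' @param beta_protein effect of the first protein descriptor.
#' @param condition_effect_sd standard deviation of the per-assay random
#'   effect on the activity logit.
#' @param prevalence target marginal activity prevalence in (0, 1).
#' @param n_duplicate,n_nearconstant planted redundant / near-constant drug
#'   descriptor columns (placed at the end of the D-block).
#' @param seed RNG seed; every draw is reproducible from it.
#' @return an object of class `ifptml_synth_config`.
#' @export
synth_config <- function(n_records = 3748L,
                         n_compounds = 1000L,
                         n_targets = 20L,
                         n_assays = 60L,
                         n_drug = 105L,
                         n_protein = 15L,
                         cardinalities = list(c2 = 3L, c3 = 2L, c4 = 4L,
                                              c5 = 5L, c6 = 2L, c7 = 2L,
                                              c8 = 2L),
                         measure_weights = c(conc = 0.5, pct = 0.3,
                                             other = 0.2),
                         censored_fraction = 0.08,
                         n_informative = 8L,
                         beta_scale = 0.6,
                         beta_protein = 0.3,
                         condition_effect_sd = 0.6,
                         prevalence = 0.5,
                         n_duplicate = 2L,
                         n_nearconstant = 2L,
                         seed = 42L) {
  cfg <- as.list(environment())
  if (prevalence <= 0 || prevalence >= 1)
    stop("config error: prevalence must lie strictly inside (0, 1)",
         call. = FALSE)
  if (any(unlist(cardinalities) < 1L))
    stop("config error: cardinalities must be >= 1", call. = FALSE)
  if (n_informative + n_duplicate + n_nearconstant > n_drug)
    stop("config error: planted columns exceed descriptor count",
         call. = FALSE)
  if (censored_fraction < 0 || censored_fraction > 1)
    stop("config error: censored_fraction outside [0, 1]", call. = FALSE)
  structure(cfg, class = "ifptml_synth_config")
}

# the 13 measure classes: 5 concentration, 4 percentage, 4 mean-cutoff
synth_measures <- function() {
  list(conc = c("IC50 (nM)", "Ki (nM)", "Kd (nM)", "Km (nM)", "Potency (nM)"),
       pct = c("Inhibition (%)", "Activity (%)", "Residual activity (%)",
               "Metabolism (%)"),
       other = c("Thermal shift (C)", "Fold change", "Response ratio",
                 "Binding score"))
}

#' Generate a synthetic assay dataset with known ground truth
#'
#' Descriptors are drawn from a latent-factor covariance model; condition
#' tuples are attached at the assay level; the latent activity probability
#' is `plogis(b0 + beta . descriptors + assay effect)` with `b0` calibrated
#' so the marginal prevalence matches the configuration; raw activity values
#' are back-mapped into each row's measure scale (log-normal around the
#' 100 nM cut-off for concentration measures, uniform bands around 70 % for
#' percentages, wide symmetric offsets around the class centre for
#' mean-cutoff measures) so that the labeling rules recover the latent
#' class. Censored rows are generated so the conservative censoring rule
#' also recovers it.
#'
#' The configuration seed fixes the *planted structure* (descriptor pools,
#' targets, assay panel with its condition tuples and effects, and the
#' effect vector beta); `record_seed` drives only the record-level sampling
#' (which compound meets which assay, label noise, value back-mapping).
#' Keeping the structure fixed while refreshing `record_seed` draws a new
#' sample from the same population, which is how
#' [expected_separability()] estimates the Bayes ceiling of a
#' configuration.
#'
#' @param cfg an [synth_config()].
#' @param record_seed seed for the record-level draws; defaults to the
#'   configuration seed, so a given config reproduces byte-identically.
#' @return list with `dataset` (an `ifptml_dataset`) and `truth` (list:
#'   per-row `prob` and `label`, the planted `beta`, `duplicate_cols`,
#'   `nearconstant_cols`, `assay_effects`, intercept `b0`).
#' @export
generate_synth <- function(cfg = synth_config(), record_seed = cfg$seed) {
  stopifnot(inherits(cfg, "ifptml_synth_config"))
  structure_part <- withr_seed(cfg$seed, {
    p <- cfg$n_drug
    meas <- synth_measures()

    # ---- compounds: descriptor blocks with latent-factor correlation ----
    n_f <- 5L
    load <- matrix(rnorm(p * n_f, 0, 0.5), p, n_f)
    fac <- matrix(rnorm(cfg$n_compounds * n_f), cfg$n_compounds, n_f)
    D <- fac %*% t(load) + matrix(rnorm(cfg$n_compounds * p), cfg$n_compounds)
    colnames(D) <- sprintf("D%03d", seq_len(p))
    near_idx <- if (cfg$n_nearconstant)
      p - cfg$n_duplicate - seq_len(cfg$n_nearconstant) + 1L else integer()
    dup_idx <- if (cfg$n_duplicate) p - seq_len(cfg$n_duplicate) + 1L
      else integer()
    for (j in near_idx) D[, j] <- 1 + rnorm(cfg$n_compounds, 0, 0.05)
    for (i in seq_along(dup_idx)) D[, dup_idx[i]] <- D[, i]
    MW <- rnorm(cfg$n_compounds, 400, 80)
    LRO5 <- as.numeric(rbinom(cfg$n_compounds, 4, 0.25))
    ALOGP <- rnorm(cfg$n_compounds, 2.5, 1.5)
    compounds <- sprintf("CPD%04d", seq_len(cfg$n_compounds))

    # ---- targets ----
    P <- matrix(rnorm(cfg$n_targets * cfg$n_protein), cfg$n_targets)
    colnames(P) <- sprintf("P%03d", seq_len(cfg$n_protein))
    targets <- sprintf("T%02d", seq_len(cfg$n_targets))

    # ---- assays: one fixed condition tuple each ----
    mk_levels <- function(field, k, with_na) {
      lv <- sprintf("%s_L%d", field, seq_len(k))
      if (with_na && k > 1L) lv[k] <- IFPTML_NA_LEVEL
      lv
    }
    card <- cfg$cardinalities
    pools <- list(
      c2 = mk_levels("cell", card$c2, TRUE),
      c3 = mk_levels("tissue", card$c3, TRUE),
      c4 = mk_levels("org", card$c4, FALSE),
      c5 = mk_levels("aorg", card$c5, FALSE),
      c6 = mk_levels("ttype", card$c6, FALSE),
      c7 = mk_levels("fraction", card$c7, TRUE),
      c8 = mk_levels("buffer", card$c8, TRUE))
    kind_of <- c(rep("conc", length(meas$conc)), rep("pct", length(meas$pct)),
                 rep("other", length(meas$other)))
    all_meas <- unlist(meas, use.names = FALSE)
    w <- cfg$measure_weights
    meas_prob <- c(rep(w[["conc"]] / length(meas$conc), length(meas$conc)),
                   rep(w[["pct"]] / length(meas$pct), length(meas$pct)),
                   rep(w[["other"]] / length(meas$other), length(meas$other)))
    assays <- data.frame(
      assay = seq_len(cfg$n_assays),
      target = sample(seq_len(cfg$n_targets), cfg$n_assays, replace = TRUE),
      c0 = sample(all_meas, cfg$n_assays, replace = TRUE, prob = meas_prob),
      c2 = sample(pools$c2, cfg$n_assays, replace = TRUE),
      c3 = sample(pools$c3, cfg$n_assays, replace = TRUE),
      c4 = sample(pools$c4, cfg$n_assays, replace = TRUE),
      c5 = sample(pools$c5, cfg$n_assays, replace = TRUE),
      c6 = sample(pools$c6, cfg$n_assays, replace = TRUE),
      c7 = sample(pools$c7, cfg$n_assays, replace = TRUE),
      c8 = sample(pools$c8, cfg$n_assays, replace = TRUE),
      c10 = sample(IFPTML_ASSAY_TYPES, cfg$n_assays, replace = TRUE,
                   prob = c(0.45, 0.35, 0.1, 0.1)),
      effect = rnorm(cfg$n_assays, 0, cfg$condition_effect_sd),
      stringsAsFactors = FALSE)

    beta <- setNames(rnorm(cfg$n_informative, 0, cfg$beta_scale),
                     sprintf("D%03d", seq_len(cfg$n_informative)))
    list(p = p, meas = meas, kind_of = kind_of, all_meas = all_meas,
         D = D, MW = MW, LRO5 = LRO5, ALOGP = ALOGP, compounds = compounds,
         P = P, targets = targets, assays = assays, beta = beta,
         near_idx = near_idx, dup_idx = dup_idx)
  })

  st <- structure_part
  withr_seed(record_seed, {
    p <- st$p; D <- st$D; P <- st$P
    assays <- st$assays; beta <- st$beta
    kind_of <- st$kind_of; all_meas <- st$all_meas
    MW <- st$MW; LRO5 <- st$LRO5; ALOGP <- st$ALOGP
    compounds <- st$compounds; targets <- st$targets
    near_idx <- st$near_idx; dup_idx <- st$dup_idx

    # ---- records ----
    n <- cfg$n_records
    a <- sample(cfg$n_assays, n, replace = TRUE)
    ci <- sample(cfg$n_compounds, n, replace = TRUE)
    ti <- assays$target[a]
    V1 <- exp(rnorm(n, log(10), 1))
    V2 <- exp(rnorm(n, log(1), 1))

    eta <- as.numeric(D[ci, seq_len(cfg$n_informative), drop = FALSE] %*%
                        beta) +
      cfg$beta_protein * P[ti, 1] + assays$effect[a]
    b0 <- tryCatch(
      uniroot(function(b) mean(plogis(b + eta)) - cfg$prevalence,
              c(-50, 50), tol = 1e-10)$root,
      error = function(e)
        stop("config error: infeasible prevalence/effect combination",
             call. = FALSE))
    prob <- plogis(b0 + eta)
    y <- rbinom(n, 1, prob)

    # ---- back-map activity values so labeling recovers y ----
    kind <- kind_of[match(assays$c0[a], all_meas)]
    v <- numeric(n)
    rel <- rep("=", n)
    cens <- runif(n) < cfg$censored_fraction & kind != "other"
    ic <- which(kind == "conc")
    m <- 0.1 + abs(rnorm(length(ic), 0, 0.8))
    v[ic] <- 100 * exp(ifelse(y[ic] == 1L, -m, m))
    ip <- which(kind == "pct")
    v[ip] <- ifelse(y[ip] == 1L, runif(length(ip), 70.5, 99.5),
                    runif(length(ip), 2, 69.5))
    io <- which(kind == "other")
    off <- 15 + abs(rnorm(length(io), 0, 2))
    v[io] <- 50 + ifelse(y[io] == 1L, off, -off)
    cc <- which(cens & kind == "conc")
    rel[cc] <- ifelse(y[cc] == 1L, "<", ">")
    v[cc] <- ifelse(y[cc] == 1L, 100 * runif(length(cc), 0.2, 0.95),
                    100 * (1.05 + rexp(length(cc))))
    cp <- which(cens & kind == "pct")
    rel[cp] <- ifelse(y[cp] == 1L, ">", "<")
    v[cp] <- ifelse(y[cp] == 1L, runif(length(cp), 70.5, 95),
                    runif(length(cp), 5, 69.5))

    df <- data.frame(
      compound_id = compounds[ci],
      target_id = targets[ti],
      activity_value = v,
      c0 = assays$c0[a],
      c1 = targets[ti],
      c2 = assays$c2[a], c3 = assays$c3[a], c4 = assays$c4[a],
      c5 = assays$c5[a], c6 = assays$c6[a], c7 = assays$c7[a],
      c8 = assays$c8[a],
      c9 = rel,
      c10 = assays$c10[a],
      MW = MW[ci], LRO5 = LRO5[ci], ALOGP = ALOGP[ci],
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(D[ci, , drop = FALSE]),
                as.data.frame(P[ti, , drop = FALSE]), V1 = V1, V2 = V2)
    rownames(df) <- NULL

    ds <- ifptml_dataset(df, default_schema(n_drug = p,
                                            n_protein = cfg$n_protein))
    truth <- list(
      prob = prob, label = y, beta = beta, b0 = b0,
      duplicate_cols = data.frame(
        copy_of = sprintf("D%03d", seq_along(dup_idx)),
        duplicate = sprintf("D%03d", dup_idx),
        stringsAsFactors = FALSE),
      nearconstant_cols = sprintf("D%03d", near_idx),
      assay_effects = assays$effect)
    list(dataset = ds, truth = truth)
  })
}

#' Monte-Carlo estimate of the Bayes-optimal AUC of a configuration
#'
#' Draws `n_mc` fresh records from the configuration's population (the
#' planted structure — descriptor pools, assay panel, effect vector — stays
#' fixed by the config seed; only the record-level sampling is refreshed)
#' and computes the AUC of the true latent activity probability as a scorer
#' of the realized labels — the ceiling no trained classifier can
#' systematically exceed.
#'
#' @param cfg an [synth_config()].
#' @param n_mc number of Monte-Carlo rows.
#' @return AUC estimate in \[0.5, 1\].
#' @export
expected_separability <- function(cfg = synth_config(), n_mc = 20000L) {
  stopifnot(inherits(cfg, "ifptml_synth_config"))
  cfg2 <- cfg
  cfg2$n_records <- as.integer(n_mc)
  class(cfg2) <- class(cfg)
  truth <- generate_synth(
    cfg2, record_seed = (cfg$seed + 104729L) %% .Machine$integer.max)$truth
  if (length(unique(truth$label)) < 2L) return(0.5)
  if (all(truth$prob == truth$prob[1])) return(0.5)
  auc_rank(truth$label, truth$prob)
}
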