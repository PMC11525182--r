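# Desk-scale validation experiments: end-to-end runs of the full pipeline
# on synthetic cohorts with known truth. Used by the acceptance test suite
# and by scripts/acceptance.R; problem sizes are fixed design choices
# (documented in the methods vignette), only the seed varies.

#' Subset a cohort to a set of individuals
#'
#' Keeps variants, gene models and assignments; restricts genotypes,
#' covariates, phenotypes and the truth impairment matrix to the given
#' individuals.
#'
#' @param cohort an `rvat_cohort`
#' @param individuals individual ids to keep
#' @return an `rvat_cohort`
#' @export
subset_cohort <- function(cohort, individuals) {
  idx <- match(individuals, cohort$genotypes$individual_id)
  if (anyNA(idx)) abort("unknown individual id(s) in subset")
  out <- cohort
  out$genotypes <- sparse_genotypes(
    cohort$genotypes$mat[idx, , drop = FALSE],
    individuals, cohort$genotypes$variant_id, cohort$genotypes$maf)
  out$covariates <- cohort$covariates[idx, , drop = FALSE]
  out$phenotypes <- cohort$phenotypes[idx, , drop = FALSE]
  out$config$n_individuals <- length(individuals)
  if (!is.null(cohort$truth$gene_impairment)) {
    out$truth$gene_impairment <-
      cohort$truth$gene_impairment[idx, , drop = FALSE]
  }
  out
}

#' End-to-end null-calibration experiment
#'
#' One cohort with five pure-null traits and two seeded traits. Seed
#' discovery is run on the null traits (expected: ~none found), the
#' ensemble is trained on the seeded traits, every gene is scored
#' out-of-fold and tested against every null trait.
#'
#' @param seed integer seed
#' @param n cohort size
#' @param n_genes gene count (null tests = n_genes x n_null_traits)
#' @param n_null_traits number of pure-null traits
#' @param K,R folds and restarts for the CV ensemble
#' @param max_epochs training epoch cap
#' @return list: `type1_at_05`, `ks_p`, `lambda`, `n_tests`,
#'   `n_null_seeds`, `power_seeded` (true seeds recovered on one seeded
#'   trait)
#' @export
experiment_null_calibration <- function(seed, n = 5000, n_genes = 400,
                                        n_null_traits = 5, K = 2, R = 2,
                                        max_epochs = 120) {
  nulls <- lapply(seq_len(n_null_traits), function(i) {
    trait_config(paste0("null", i), n_seed_genes = 0)
  })
  sA <- n_genes - 99; sB <- n_genes - 79  # seeded blocks at the gene tail
  seeded <- list(
    trait_config("s1", n_seed_genes = 20, seed_genes = sA:(sA + 19)),
    trait_config("s2", n_seed_genes = 20, seed_genes = sB:(sB + 19)))
  cfg <- sim_config(n_individuals = n, n_genes = n_genes,
                    rng_seed = derive_seed(seed, "nullcal"),
                    traits = c(nulls, seeded))
  co <- simulate_cohort(cfg)

  null_seeds <- unlist(lapply(paste0("null", seq_len(n_null_traits)),
                              function(tr) {
    res <- suppressWarnings(suppressMessages(
      discover_seed_genes(co, tr, maf_cutoff = 0.01, eaf_threshold = 1,
                          genes = sort(unique(co$gene_models$gene_id))[1:50])))
    attr(res, "seed_genes")
  }))

  sg <- co$truth$seed_genes[c("s1", "s2")]
  plan <- make_folds(co$genotypes$individual_id, K = K,
                     seed = derive_seed(seed, "folds"))
  ens <- suppressMessages(train_cv_ensemble(
    co, sg,
    train_config(min_epochs = 50, max_epochs = max_epochs, patience = 10,
                 seed = derive_seed(seed, "train")),
    plan = plan, R = R))
  S <- score_out_of_fold(ens, co, maf_cutoff = 0.01)
  ps <- unlist(lapply(paste0("null", seq_len(n_null_traits)), function(tr) {
    suppressWarnings(association_scan(S, co, tr, maf_cutoff = 0.01))$p
  }))
  ps <- ps[!is.na(ps)]
  a1 <- association_scan(S, co, "s1", maf_cutoff = 0.01)
  truth1 <- co$truth$seed_genes$s1
  list(type1_at_05 = mean(ps < 0.05),
       ks_p = suppressWarnings(ks.test(ps, "punif")$p.value),
       lambda = genomic_inflation(ps)$lambda,
       n_tests = length(ps),
       n_null_seeds = length(null_seeds),
       power_seeded = sum(a1$p_corrected < 0.05 &
                            a1$gene_id %in% truth1, na.rm = TRUE),
       ensemble = ens)
}

#' Leakage demonstration on a pure-null cohort
#'
#' Trains the ensemble on a null trait with deliberately nonassociated
#' "decoy" seed genes for a fixed number of epochs, then tests the decoy
#' genes against the same trait twice: with leakage-free out-of-fold
#' scores, and with deliberately leaky in-fold scores (each individual
#' scored by the models trained on it). The no-leakage audit is also run.
#'
#' @param seed integer seed
#' @param n cohort size
#' @param n_genes genes (half become decoy seed genes)
#' @param epochs fixed training length (no early stopping, so the returned
#'   checkpoint is maximally overfit)
#' @return list: `lambda_oof`, `lambda_leaky`, `audit_passed`
#' @export
experiment_leakage <- function(seed, n = 2000, n_genes = 80, epochs = 120) {
  cfg <- sim_config(n_individuals = n, n_genes = n_genes,
                    rng_seed = derive_seed(seed, "leak"),
                    traits = list(trait_config("t1", n_seed_genes = 0)))
  co <- simulate_cohort(cfg)
  decoys <- sort(unique(co$gene_models$gene_id))[seq_len(n_genes / 2)]
  plan <- make_folds(co$genotypes$individual_id, K = 2,
                     seed = derive_seed(seed, "leakfolds"))
  ens <- suppressMessages(train_cv_ensemble(
    co, list(t1 = decoys),
    train_config(min_epochs = epochs, max_epochs = epochs, patience = 999,
                 seed = derive_seed(seed, "leaktrain")),
    plan = plan, R = 1))
  S_oof <- score_out_of_fold(ens, co, genes = decoys, maf_cutoff = 0.01)
  S_leak <- score_in_fold_leaky(ens, co, genes = decoys, maf_cutoff = 0.01)
  a_oof <- suppressWarnings(
    association_scan(S_oof, co, "t1", maf_cutoff = 0.01))
  a_leak <- suppressWarnings(
    association_scan(S_leak, co, "t1", maf_cutoff = 0.01))
  list(lambda_oof = genomic_inflation(a_oof$p)$lambda,
       lambda_leaky = genomic_inflation(a_leak$p)$lambda,
       audit_passed = attr(audit_no_leakage(ens), "passed"))
}

#' Parameter-recovery experiment
#'
#' Trains a single impairment module on a cohort with known ground truth
#' and measures, on held-out individuals, the Spearman correlation between
#' psi and the true impairment u, against the best single-annotation
#' alternative burden. With `form = "interaction"` a linear-ablation module
#' of the same size is trained on the same data for comparison.
#'
#' @param seed integer seed
#' @param form ground-truth impairment form
#' @param n cohort size
#' @param n_seed_genes causal genes (all genes are scored)
#' @param max_epochs epoch cap
#' @return list: `spearman_psi`, `best_single_annotation`,
#'   `per_annotation` (tibble), and for the interaction form
#'   `spearman_linear_ablation`
#' @export
experiment_parameter_recovery <- function(seed, form = "linear", n = 10000,
                                          n_seed_genes = 20,
                                          max_epochs = 120) {
  cfg <- sim_config(
    n_individuals = n, n_genes = n_seed_genes + 5,
    impairment_form = form,
    impairment_scale = if (form == "interaction") 2 else 1,
    rng_seed = derive_seed(seed, "recov", form),
    traits = list(trait_config("t", n_seed_genes = n_seed_genes,
                               effect_size = if (form == "interaction") 0.6
                                             else 0.4)))
  co <- simulate_cohort(cfg)
  ids <- co$genotypes$individual_id
  withr::with_seed(derive_seed(seed, "recovsplit"), {
    train_ids <- sample(ids, round(0.8 * length(ids)))
  })
  heldout <- setdiff(ids, train_ids)
  sg <- list(t = co$truth$seed_genes$t)
  tc <- train_config(min_epochs = 50, max_epochs = max_epochs,
                     patience = 10, seed = derive_seed(seed, "recovtrain"))
  fit <- suppressMessages(
    train_impairment_module(co, sg, tc, individuals = train_ids))
  U <- co$truth$gene_impairment[heldout, , drop = FALSE]
  carr <- U > 0
  S <- score_matrix(fit$module, co, maf_cutoff = 0.01)[heldout, , drop = FALSE]
  sp_psi <- cor(S[carr], U[carr], method = "spearman")
  anns <- annotation_columns(co)
  per_ann <- purrr::map_dfr(anns, function(a) {
    B <- alternative_burden(co, a, maf_cutoff = 0.01)[heldout, , drop = FALSE]
    tibble::tibble(annotation = a,
                   spearman = abs(cor(B[carr], U[carr],
                                      method = "spearman")))
  })
  out <- list(spearman_psi = sp_psi,
              best_single_annotation = max(per_ann$spearman),
              per_annotation = per_ann)
  if (form == "interaction") {
    tcl <- tc
    tcl$activation <- "linear"
    fitL <- suppressMessages(
      train_impairment_module(co, sg, tcl, individuals = train_ids))
    SL <- score_matrix(fitL$module, co,
                       maf_cutoff = 0.01)[heldout, , drop = FALSE]
    out$spearman_linear_ablation <- cor(SL[carr], U[carr],
                                        method = "spearman")
  }
  out
}

#' Power-ordering experiment on interaction-only truth
#'
#' On a cohort whose impairment is driven purely by an annotation
#' interaction, counts the true seed genes recovered at FWER 0.05 by (a)
#' the learned impairment score with out-of-fold CV scoring and (b) each of
#' the four conventional burden/SKAT (mask x test) arms, Bonferroni-
#' corrected per arm across genes.
#'
#' @param seed integer seed
#' @param n cohort size
#' @param n_genes gene count
#' @param n_seed_genes causal genes
#' @param fwer family-wise error rate
#' @param max_epochs epoch cap
#' @return list: `n_true_learned`, `n_true_best_arm`, `arms` (tibble)
#' @export
experiment_power_ordering <- function(seed, n = 6000, n_genes = 100,
                                      n_seed_genes = 20, fwer = 0.05,
                                      max_epochs = 100) {
  cfg <- sim_config(
    n_individuals = n, n_genes = n_genes, impairment_form = "interaction",
    impairment_scale = 2, rng_seed = derive_seed(seed, "power"),
    traits = list(trait_config("t", n_seed_genes = n_seed_genes,
                               effect_size = 0.6)))
  co <- simulate_cohort(cfg)
  truth <- co$truth$seed_genes$t

  scan <- suppressWarnings(suppressMessages(
    burden_skat_scan(co, "t", maf_cutoff = 0.01, eaf_threshold = 1)))
  arms <- scan |>
    dplyr::filter(!.data$skipped, !is.na(.data$p)) |>
    dplyr::group_by(.data$mask, .data$test) |>
    dplyr::mutate(p_corrected = pmin(1, .data$p * dplyr::n())) |>
    dplyr::summarise(
      n_true = sum(.data$p_corrected < fwer & .data$gene_id %in% truth),
      .groups = "drop")

  plan <- make_folds(co$genotypes$individual_id, K = 2,
                     seed = derive_seed(seed, "powerfolds"))
  ens <- suppressMessages(train_cv_ensemble(
    co, list(t = truth),
    train_config(min_epochs = 50, max_epochs = max_epochs, patience = 10,
                 seed = derive_seed(seed, "powertrain")),
    plan = plan, R = 2))
  S <- score_out_of_fold(ens, co, maf_cutoff = 0.01)
  a <- suppressWarnings(
    association_scan(S, co, "t", maf_cutoff = 0.01, eaf_threshold = 1))
  list(n_true_learned = sum(a$p_corrected < fwer & a$gene_id %in% truth,
                            na.rm = TRUE),
       n_true_best_arm = max(arms$n_true),
       arms = arms)
}

#' Rare-variant-augmented prediction experiment
#'
#' Splits a seeded cohort in half, trains the impairment module and
#' discovers gene sets on the training half only, fits the PRS-only,
#' PRS + impairment and PRS + single-annotation-burden predictors on the
#' training half, and evaluates on the held-out half: Relative delta-R^2
#' and deviation-based extreme-phenotype enrichment.
#'
#' @param seed integer seed
#' @param n cohort size (split in half)
#' @param n_genes genes
#' @param n_seed_genes causal genes
#' @param prs_r2 trait variance explained by the simulated PRS
#' @param max_epochs epoch cap
#' @return list: `r2_prs`, `r2_psi`, `r2_burden`, `rel_dr2_psi`,
#'   `rel_dr2_burden`, `enrichment_area`, `enrichment_p`
#' @export
experiment_prediction <- function(seed, n = 6000, n_genes = 30,
                                  n_seed_genes = 10, prs_r2 = 0.25,
                                  max_epochs = 100) {
  cfg <- sim_config(n_individuals = n, n_genes = n_genes,
                    rng_seed = derive_seed(seed, "pred"),
                    traits = list(trait_config("t",
                                               n_seed_genes = n_seed_genes,
                                               effect_size = 0.8)))
  co <- simulate_cohort(cfg)
  y_all <- quantile_transform(co$phenotypes$t)
  prs_all <- simulate_prs(y_all, prs_r2, seed = derive_seed(seed, "prs"))
  ids <- co$genotypes$individual_id
  withr::with_seed(derive_seed(seed, "predsplit"), {
    train_ids <- sort(sample(ids, n %/% 2))
  })
  eval_ids <- setdiff(ids, train_ids)
  tr_idx <- match(train_ids, ids)
  ev_idx <- match(eval_ids, ids)

  # gene discovery strictly on the training half
  co_tr <- subset_cohort(co, train_ids)
  disc <- suppressWarnings(suppressMessages(
    discover_seed_genes(co_tr, "t", maf_cutoff = 0.01, eaf_threshold = 1)))
  genes_b <- attr(disc, "seed_genes")

  fit <- suppressMessages(train_impairment_module(
    co, list(t = co$truth$seed_genes$t),
    train_config(min_epochs = 50, max_epochs = max_epochs, patience = 10,
                 seed = derive_seed(seed, "predtrain")),
    individuals = train_ids))
  S <- score_matrix(fit$module, co, maf_cutoff = 0.01)
  a_tr <- suppressWarnings(
    association_scan(S[tr_idx, , drop = FALSE], co_tr, "t",
                     maf_cutoff = 0.01, eaf_threshold = 1))
  genes_d <- a_tr$gene_id[which(a_tr$p_corrected < 0.05)]
  if (length(genes_d) == 0) genes_d <- a_tr$gene_id[which.min(a_tr$p)]
  if (length(genes_b) == 0) genes_b <- disc$gene_id[which.min(disc$p_combined)]

  B <- alternative_burden(co, "a1", maf_cutoff = 0.01)
  covs <- c("sex", "age", "age2", "age_sex", paste0("pc", 1:10))
  base_df <- dplyr::bind_cols(
    tibble::tibble(y = y_all, prs = prs_all), co$covariates[, covs])
  df_psi <- dplyr::bind_cols(
    base_df, tibble::as_tibble(S[, genes_d, drop = FALSE]))
  df_b <- dplyr::bind_cols(
    base_df, tibble::as_tibble(B[, genes_b, drop = FALSE]))

  m_prs <- fit_phenotype_predictor(base_df[tr_idx, ], "y", covs, "prs")
  m_psi <- fit_phenotype_predictor(df_psi[tr_idx, ], "y", covs, "prs",
                                   gene_cols = genes_d)
  m_b <- fit_phenotype_predictor(df_b[tr_idx, ], "y", covs, "prs",
                                 gene_cols = genes_b)

  p_prs <- predict(m_prs, base_df[ev_idx, ])
  p_psi <- predict(m_psi, df_psi[ev_idx, ])
  p_b <- predict(m_b, df_b[ev_idx, ])
  y_ev <- y_all[ev_idx]
  r2 <- c(prs = r_squared(y_ev, p_prs), psi = r_squared(y_ev, p_psi),
          burden = r_squared(y_ev, p_b))

  labels <- pmax(extreme_phenotype_labels(y_ev, "top", 1),
                 extreme_phenotype_labels(y_ev, "bottom", 1))
  bt <- enrichment_bootstrap_test(p_prs, p_psi, labels, n_boot = 500,
                                  seed = derive_seed(seed, "boot"))
  list(r2_prs = unname(r2["prs"]), r2_psi = unname(r2["psi"]),
       r2_burden = unname(r2["burden"]),
       rel_dr2_psi = unname(relative_improvement(r2["psi"], r2["prs"])),
       rel_dr2_burden = unname(relative_improvement(r2["burden"], r2["prs"])),
       enrichment_area = bt$area, enrichment_p = bt$p_value,
       n_genes_psi = length(genes_d), n_genes_burden = length(genes_b))
}
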