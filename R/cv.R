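# K-fold, multi-restart training of the impairment module with leakage-free
# out-of-fold scoring: a training-cohort individual is only ever scored by
# the R models of its own held-out fold; external individuals are scored by
# the full K x R ensemble.

#' Random fold assignment
#'
#' Partitions individuals into `K` folds whose sizes differ by at most one.
#'
#' @param individuals character vector of individual ids
#' @param K fold count (>= 2; default 5)
#' @param seed integer seed
#' @return object of class `cv_plan`: tibble `assignment`
#'   (`individual_id`, `fold`) plus `K` and the seed
#' @export
make_folds <- function(individuals, K = 5, seed = 1L) {
  n <- length(individuals)
  if (K < 2) abort("K must be at least 2")
  if (n < K) abort("need at least K individuals")
  withr::local_seed(derive_seed(seed, "folds"))
  fold <- sample(rep_len(seq_len(K), n))
  structure(list(assignment = tibble::tibble(individual_id = individuals,
                                             fold = fold),
                 K = as.integer(K), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Train the cross-validated ensemble
#'
#' For each fold `k`, trains `R` modules (distinct restart seeds, derived
#' deterministically from the base seed, fold and restart) on the other
#' `K - 1` folds. All `K x R` models are retained together with their
#' training-fold membership, so scoring can be audited for leakage.
#'
#' @param cohort an `rvat_cohort`
#' @param seed_genes named list: trait -> seed gene ids (discovered once on
#'   the full cohort before CV, mirroring the standard workflow)
#' @param config a [train_config()]; each model derives its own seed from it
#' @param plan a [make_folds()] plan
#' @param R restarts per fold (default 6)
#' @return object of class `cv_ensemble`
#' @export
train_cv_ensemble <- function(cohort, seed_genes, config = train_config(),
                              plan = NULL, R = 6) {
  plan <- plan %||% make_folds(cohort$genotypes$individual_id, K = 5,
                               seed = config$seed)
  models <- list()
  for (k in seq_len(plan$K)) {
    train_ids <- plan$assignment$individual_id[plan$assignment$fold != k]
    for (r in seq_len(R)) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, "fold", k, "restart", r)
      fit <- tryCatch(
        train_impairment_module(cohort, seed_genes, cfg,
                                individuals = train_ids),
        error = function(e) {
          abort(sprintf("training failed at fold %d restart %d: %s",
                        k, r, conditionMessage(e)))
        })
      models[[length(models) + 1L]] <-
        list(fit = fit, fold = k, restart = r, train_ids = train_ids)
    }
  }
  structure(list(models = models, plan = plan, R = as.integer(R),
                 seed_genes = seed_genes, config = config),
            class = "cv_ensemble")
}

#' @export
print.cv_ensemble <- function(x, ...) {
  cat(sprintf("<cv_ensemble> K=%d folds x R=%d restarts = %d models\n",
              x$plan$K, x$R, length(x$models)))
  invisible(x)
}

ensemble_score <- function(models, cohort, genes, maf_cutoff, cadd_cutoff) {
  mats <- lapply(models, function(m) {
    score_matrix(m$fit$module, cohort, genes = genes,
                 maf_cutoff = maf_cutoff, cadd_cutoff = cadd_cutoff)
  })
  Reduce(`+`, mats) / length(mats)
}

#' Leakage-free impairment scores for training-cohort individuals
#'
#' Each individual is scored by exactly the `R` models of its own held-out
#' fold — never by a model whose training set contained the individual —
#' and the `R` scores are averaged.
#'
#' @param ensemble a [train_cv_ensemble()] result
#' @param cohort the training cohort
#' @param genes genes to score (default: all)
#' @param maf_cutoff,cadd_cutoff qualifying-variant filters for scoring
#'   (defaults: association conventions, MAF < 0.1%, CADD > 5)
#' @return individuals x genes matrix of out-of-fold scores
#' @export
score_out_of_fold <- function(ensemble, cohort, genes = NULL,
                              maf_cutoff = 0.001, cadd_cutoff = 5) {
  genes <- genes %||% sort(unique(cohort$gene_models$gene_id))
  asn <- ensemble$plan$assignment
  ids <- cohort$genotypes$individual_id
  if (!all(ids %in% asn$individual_id)) {
    abort("cohort contains individuals without a fold assignment")
  }
  out <- matrix(NA_real_, length(ids), length(genes),
                dimnames = list(ids, genes))
  for (k in seq_len(ensemble$plan$K)) {
    fold_models <- Filter(function(m) m$fold == k, ensemble$models)
    fold_ids <- intersect(ids, asn$individual_id[asn$fold == k])
    if (length(fold_ids) == 0) next
    S <- ensemble_score(fold_models, cohort, genes, maf_cutoff, cadd_cutoff)
    out[fold_ids, ] <- S[fold_ids, , drop = FALSE]
  }
  out
}

#' Impairment scores for external individuals
#'
#' Individuals outside the training cohort are scored by the mean over all
#' `K x R` models.
#'
#' @inheritParams score_out_of_fold
#' @param cohort a cohort of individuals disjoint from the training cohort
#'   (annotation columns must match the checkpoint schema by name)
#' @export
score_external <- function(ensemble, cohort, genes = NULL,
                           maf_cutoff = 0.001, cadd_cutoff = 5) {
  genes <- genes %||% sort(unique(cohort$gene_models$gene_id))
  ensemble_score(ensemble$models, cohort, genes, maf_cutoff, cadd_cutoff)
}

#' Deliberately leaky in-fold scores (for calibration demonstrations)
#'
#' Scores every training-cohort individual with the models that were
#' trained *on* that individual (the complement of the out-of-fold rule).
#' Exists to demonstrate the inflation that the CV scheme prevents; never
#' use for real association testing.
#'
#' @inheritParams score_out_of_fold
#' @export
score_in_fold_leaky <- function(ensemble, cohort, genes = NULL,
                                maf_cutoff = 0.001, cadd_cutoff = 5) {
  genes <- genes %||% sort(unique(cohort$gene_models$gene_id))
  asn <- ensemble$plan$assignment
  ids <- cohort$genotypes$individual_id
  out <- matrix(NA_real_, length(ids), length(genes),
                dimnames = list(ids, genes))
  for (k in seq_len(ensemble$plan$K)) {
    leaky_models <- Filter(function(m) m$fold != k, ensemble$models)
    fold_ids <- intersect(ids, asn$individual_id[asn$fold == k])
    if (length(fold_ids) == 0) next
    S <- ensemble_score(leaky_models, cohort, genes, maf_cutoff, cadd_cutoff)
    out[fold_ids, ] <- S[fold_ids, , drop = FALSE]
  }
  out
}

#' Machine-check the no-leakage invariant
#'
#' For every training-cohort individual, verifies that the set of models
#' used for out-of-fold scoring is disjoint from the set of models trained
#' on that individual.
#'
#' @param ensemble a `cv_ensemble`
#' @return tibble (`individual_id`, `n_models_used`, `n_overlap`) with
#'   attribute `passed`; `n_overlap` must be 0 everywhere
#' @export
audit_no_leakage <- function(ensemble) {
  asn <- ensemble$plan$assignment
  model_tab <- tibble::tibble(
    model = seq_along(ensemble$models),
    fold = vapply(ensemble$models, `[[`, 0L, "fold"))
  res <- asn |>
    dplyr::mutate(
      n_models_used = vapply(.data$fold, function(k) sum(model_tab$fold == k), 0L),
      n_overlap = vapply(seq_len(nrow(asn)), function(ii) {
        used <- model_tab$model[model_tab$fold == asn$fold[ii]]
        trained_on <- which(vapply(
          ensemble$models,
          function(m) asn$individual_id[ii] %in% m$train_ids, TRUE))
        length(intersect(used, trained_on))
      }, 0L))
  attr(res, "passed") <- all(res$n_overlap == 0)
  res
}

# ---- checkpoint serialization -------------------------------------------

module_to_list <- function(module) {
  list(version = 1L,
       annotation_cols = module$annotation_cols,
       activation = module$activation,
       center = module$center, scale = module$scale,
       maf_cutoff_train = module$maf_cutoff_train,
       shapes = lapply(module$params, function(p) dim(p) %||% length(p)),
       params = lapply(module$params, function(p) as.vector(p)))
}

module_from_list <- function(x) {
  mod <- new_impairment_module(unlist(x$annotation_cols),
                               activation = x$activation)
  for (nm in names(mod$params)) {
    v <- unlist(x$params[[nm]])
    dm <- unlist(x$shapes[[nm]])
    mod$params[[nm]] <- if (length(dm) == 2) matrix(v, dm[1], dm[2]) else v
  }
  mod$center <- unlist(x$center)
  mod$scale <- unlist(x$scale)
  mod$maf_cutoff_train <- x$maf_cutoff_train
  mod
}

#' Write a CV ensemble to a checkpoint directory
#'
#' One JSON checkpoint per (fold, restart) — explicit versioned schema:
#' layer shapes, annotation column order, standardization, training MAF
#' cutoff — plus a manifest with the fold plan and seeds. Lossless round
#' trip with [read_ensemble()] (doubles serialized in full precision).
#'
#' @param ensemble a `cv_ensemble`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    K = ensemble$plan$K, R = ensemble$R, seed = ensemble$plan$seed,
    assignment = as.list(ensemble$plan$assignment),
    seed_genes = ensemble$seed_genes,
    models = lapply(ensemble$models, function(m) {
      list(fold = m$fold, restart = m$restart,
           file = sprintf("model_f%d_r%d.json", m$fold, m$restart))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (m in ensemble$models) {
    ck <- module_to_list(m$fit$module)
    ck$fold <- m$fold
    ck$restart <- m$restart
    ck$heads <- lapply(m$fit$heads, function(h) lapply(h, as.vector))
    ck$cov_center <- m$fit$cov_center
    ck$cov_scale <- m$fit$cov_scale
    ck$train_ids <- m$train_ids
    jsonlite::write_json(ck,
                         file.path(dir, sprintf("model_f%d_r%d.json",
                                                m$fold, m$restart)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a CV ensemble checkpoint directory
#' @param dir directory written by [write_ensemble()]
#' @return a `cv_ensemble` (fit objects carry the module, heads and
#'   training ids; training logs are not persisted)
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  assignment <- tibble::tibble(
    individual_id = unlist(manifest$assignment$individual_id),
    fold = unlist(manifest$assignment$fold))
  plan <- structure(list(assignment = assignment, K = manifest$K,
                         seed = manifest$seed), class = "cv_plan")
  models <- lapply(manifest$models, function(mm) {
    ck <- jsonlite::read_json(file.path(dir, mm$file))
    mod <- module_from_list(ck)
    heads <- lapply(ck$heads, function(h) lapply(h, unlist))
    fit <- structure(list(module = mod, heads = heads,
                          seed_genes = lapply(manifest$seed_genes, unlist),
                          traits = names(heads),
                          cov_center = unlist(ck$cov_center),
                          cov_scale = unlist(ck$cov_scale),
                          individuals = unlist(ck$train_ids),
                          config = NULL, log = NULL,
                          best_epoch = NA_integer_),
                     class = "impairment_fit")
    list(fit = fit, fold = mm$fold, restart = mm$restart,
         train_ids = unlist(ck$train_ids))
  })
  structure(list(models = models, plan = plan, R = manifest$R,
                 seed_genes = lapply(manifest$seed_genes, unlist),
                 config = NULL),
            class = "cv_ensemble")
}
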