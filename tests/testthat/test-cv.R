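test_that("fold assignment partitions individuals into near-equal folds,
           reproducibly", {
  ids <- sprintf("i%03d", 1:100)
  plan <- make_folds(ids, K = 5, seed = 4)
  sizes <- table(plan$assignment$fold)
  expect_equal(as.vector(sizes), rep(20, 5))
  expect_setequal(plan$assignment$individual_id, ids)

  plan101 <- make_folds(sprintf("i%03d", 1:101), K = 5, seed = 4)
  expect_setequal(as.vector(table(plan101$assignment$fold)),
                  c(21, 20, 20, 20, 20))

  plan2 <- make_folds(ids, K = 5, seed = 4)
  expect_identical(plan$assignment, plan2$assignment)
  expect_error(make_folds(ids, K = 1), "at least 2")
  expect_error(make_folds(ids[1:3], K = 5), "at least K")
})

test_that("the CV ensemble trains K x R models with the right training
           sets", {
  co <- small_cohort()
  sg <- list(q1 = co$truth$seed_genes$q1)
  plan <- make_folds(co$genotypes$individual_id, K = 2, seed = 5)
  ens <- suppressMessages(
    train_cv_ensemble(co, sg, tiny_train_config(seed = 1), plan = plan,
                      R = 1))
  expect_length(ens$models, 2)
  expect_length(intersect(ens$models[[1]]$train_ids,
                          ens$models[[2]]$train_ids), 0)

  ens2 <- suppressMessages(
    train_cv_ensemble(co, sg, tiny_train_config(seed = 1), plan = plan,
                      R = 2))
  expect_length(ens2$models, 4)
  # every model's training set excludes exactly its own fold
  for (m in ens2$models) {
    fold_ids <- plan$assignment$individual_id[plan$assignment$fold == m$fold]
    expect_length(intersect(m$train_ids, fold_ids), 0)
    expect_setequal(m$train_ids,
                    setdiff(co$genotypes$individual_id, fold_ids))
  }
})

test_that("out-of-fold scoring uses only held-out models and the audit is
           machine-checked", {
  co <- small_cohort()
  sg <- list(q1 = co$truth$seed_genes$q1)
  plan <- make_folds(co$genotypes$individual_id, K = 2, seed = 6)
  ens <- suppressMessages(
    train_cv_ensemble(co, sg, tiny_train_config(seed = 2), plan = plan,
                      R = 1))
  genes <- sg$q1
  S_oof <- score_out_of_fold(ens, co, genes = genes, maf_cutoff = 0.01)

  # with R = 1 the out-of-fold score equals the single held-out model's psi
  for (k in 1:2) {
    fold_ids <- plan$assignment$individual_id[plan$assignment$fold == k]
    mk <- Filter(function(m) m$fold == k, ens$models)[[1]]
    Sk <- score_matrix(mk$fit$module, co, genes = genes, maf_cutoff = 0.01)
    expect_equal(S_oof[fold_ids, ], Sk[fold_ids, ])
  }

  audit <- audit_no_leakage(ens)
  expect_true(attr(audit, "passed"))
  expect_true(all(audit$n_overlap == 0))
  expect_true(all(audit$n_models_used == 1))
})

test_that("external scoring averages all models: bounds, constant-ensemble
           identity, order invariance", {
  co <- small_cohort()
  sg <- list(q1 = co$truth$seed_genes$q1)
  plan <- make_folds(co$genotypes$individual_id, K = 2, seed = 7)
  ens <- suppressMessages(
    train_cv_ensemble(co, sg, tiny_train_config(seed = 3), plan = plan,
                      R = 1))
  genes <- sg$q1
  # a second cohort from a different seed plays the external dataset
  cfg2 <- co$config; cfg2$rng_seed <- 999L
  ext <- simulate_cohort(cfg2)
  S_ext <- score_external(ens, ext, genes = genes, maf_cutoff = 0.01)
  mats <- lapply(ens$models, function(m) {
    score_matrix(m$fit$module, ext, genes = genes, maf_cutoff = 0.01)
  })
  expect_true(all(S_ext >= pmin(mats[[1]], mats[[2]]) - 1e-12))
  expect_true(all(S_ext <= pmax(mats[[1]], mats[[2]]) + 1e-12))
  expect_equal(S_ext, (mats[[1]] + mats[[2]]) / 2)

  # permuting the model list leaves the score unchanged
  ens_perm <- ens
  ens_perm$models <- rev(ens$models)
  expect_equal(score_external(ens_perm, ext, genes = genes,
                              maf_cutoff = 0.01), S_ext)

  # identical models: mean equals the single-model score
  ens_const <- ens
  ens_const$models[[2]]$fit <- ens_const$models[[1]]$fit
  expect_equal(score_external(ens_const, ext, genes = genes,
                              maf_cutoff = 0.01),
               mats[[1]])
})

test_that("checkpoint round trip preserves scores, fold bookkeeping and the
           schema", {
  co <- small_cohort()
  sg <- list(q1 = co$truth$seed_genes$q1)
  plan <- make_folds(co$genotypes$individual_id, K = 2, seed = 8)
  ens <- suppressMessages(
    train_cv_ensemble(co, sg, tiny_train_config(seed = 4), plan = plan,
                      R = 1))
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  back <- read_ensemble(dir)
  expect_equal(back$plan$assignment, ens$plan$assignment)
  genes <- sg$q1
  expect_equal(score_out_of_fold(back, co, genes = genes, maf_cutoff = 0.01),
               score_out_of_fold(ens, co, genes = genes, maf_cutoff = 0.01))
  expect_identical(back$models[[1]]$fit$module$annotation_cols,
                   ens$models[[1]]$fit$module$annotation_cols)
  # schema mismatch on scoring is refused with the offending columns named
  co_bad <- co
  co_bad$variants <- dplyr::rename(co$variants, zz = "a1")
  expect_error(score_external(back, co_bad, genes = genes),
               "schema mismatch.*a1")
})

test_that("restart seeds are derived deterministically from one integer", {
  s1 <- derive_seed(42, "fold", 1, "restart", 1)
  s2 <- derive_seed(42, "fold", 1, "restart", 2)
  s3 <- derive_seed(42, "fold", 2, "restart", 1)
  expect_false(s1 == s2 || s1 == s3)
  expect_identical(s1, derive_seed(42, "fold", 1, "restart", 1))
  expect_true(s1 > 0 && s1 < 2^31)
})
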