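test_that("psi is permutation- and duplication-invariant and lies in (0,1)
           for nonempty sets", {
  for (rep in 1:50) {
    mod <- new_impairment_module(paste0("x", 1:6), seed = rep)
    V <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(NULL, paste0("x", 1:6)))
    s <- score_gene(mod, V)
    expect_identical(s, score_gene(mod, V[sample(5), , drop = FALSE]))
    expect_identical(s, score_gene(mod, V[c(1, 1, 2, 3, 4, 5, 3), ,
                                          drop = FALSE]))
    expect_gt(s, 0)
    expect_lt(s, 1)
  }
})

test_that("the empty set scores exactly 0 and schema mismatches error", {
  mod <- new_impairment_module(paste0("x", 1:4))
  expect_identical(score_gene(mod, NULL), 0)
  expect_identical(score_gene(mod, matrix(0, 0, 4)), 0)
  V_bad <- matrix(1, 2, 3, dimnames = list(NULL, c("x1", "x2", "nope")))
  expect_error(score_gene(mod, V_bad), "schema mismatch")
})

test_that("a variant dominated element-wise in the pooled embedding never
           changes the score", {
  mod <- identity_phi_module(3)
  V <- matrix(c(1, 2, 3,
                0.5, 1.9, 2.0), 2, 3, byrow = TRUE,
              dimnames = list(NULL, paste0("x", 1:3)))
  dominated <- matrix(c(0.9, 1.5, 2.5), 1, 3,
                      dimnames = list(NULL, paste0("x", 1:3)))
  expect_equal(score_gene(mod, V), score_gene(mod, rbind(V, dominated)))
})

test_that("scores do not depend on batch composition", {
  co <- small_cohort()
  mod <- new_impairment_module(annotation_columns(co), seed = 3)
  genes <- sort(unique(co$gene_models$gene_id))
  S_all <- score_matrix(mod, co, maf_cutoff = 0.01)
  S_sub <- score_matrix(mod, co, genes = genes[c(2, 5)], maf_cutoff = 0.01)
  expect_equal(S_all[, genes[c(2, 5)]], S_sub)
  # and per-set scoring agrees with the batched matrix
  qual <- suppressMessages(filter_qualifying_variants(co$variants, 0.01))
  mod$center <- rep(0, length(mod$annotation_cols))
  mod$scale <- rep(1, length(mod$annotation_cols))
  S0 <- score_matrix(mod, co, maf_cutoff = 0.01)
  vs <- build_variant_sets(co$genotypes, co$assignments, qual$variant_id)
  one <- vs[vs$individual_id == vs$individual_id[1] &
              vs$gene_id == vs$gene_id[1], ]
  V <- as.matrix(qual[match(one$variant_id, qual$variant_id),
                      mod$annotation_cols])
  expect_equal(score_gene(mod, V), S0[one$individual_id[1], one$gene_id[1]])
})

test_that("multitask loss averages per-trait mean squared errors", {
  expect_equal(multitask_loss(c(1, 2, 3), c(1, 2, 3), c("a", "a", "b")), 0)
  # single trait: plain MSE
  expect_equal(multitask_loss(c(1, 0), c(0, 0), c("a", "a")), 0.5)
  # two traits with per-trait MSEs 0.2 and 0.4 -> 0.3
  pred <- c(sqrt(0.2), 0, sqrt(0.4), 0)
  targ <- c(0, sqrt(0.2), 0, sqrt(0.4))
  expect_equal(multitask_loss(pred, targ, c("a", "a", "b", "b")), 0.3)
  # missing targets are excluded
  expect_equal(multitask_loss(c(1, 5), c(1, NA), c("a", "a")), 0)
  expect_error(multitask_loss(1, NA, "a"), "no valid")
})

test_that("forward prediction is linear in gene weights and ignores genes
           outside the seed set", {
  co <- small_cohort()
  fit <- suppressMessages(train_impairment_module(
    co, list(q1 = co$truth$seed_genes$q1), tiny_train_config(seed = 2)))
  ids <- co$genotypes$individual_id[1:50]
  yhat <- forward_predict(fit, co, "q1", ids)

  # zero gene weights -> covariate-only predictor
  fit0 <- fit
  fit0$heads$q1$w[] <- 0
  Xraw <- as.matrix(co$covariates[1:50, -1])
  Xs <- cbind(1, sweep(sweep(Xraw, 2, fit$cov_center), 2, fit$cov_scale, `/`))
  expect_equal(unname(forward_predict(fit0, co, "q1", ids)),
               as.vector(Xs %*% fit$heads$q1$alpha))

  # doubling one weight shifts predictions by w_j * psi_ij exactly
  fit2 <- fit
  fit2$heads$q1$w[1] <- 2 * fit$heads$q1$w[1]
  S <- score_matrix(fit$module, co, genes = fit$seed_genes$q1[1],
                    maf_cutoff = fit$config$maf_cutoff_train)
  expect_equal(unname(forward_predict(fit2, co, "q1", ids) - yhat),
               unname(fit$heads$q1$w[1] * S[ids, 1]))
})

test_that("training reduces the loss below initialization and is
           seed-reproducible", {
  co <- small_cohort()
  sg <- list(q1 = co$truth$seed_genes$q1)
  fit <- suppressMessages(
    train_impairment_module(co, sg, tiny_train_config(seed = 7)))
  # training loss at the selected checkpoint does not exceed the first
  # epoch's loss
  expect_lte(fit$log$train_loss[fit$best_epoch], fit$log$train_loss[1])
  expect_true(all(is.finite(fit$log$train_loss)))

  fit2 <- suppressMessages(
    train_impairment_module(co, sg, tiny_train_config(seed = 7)))
  expect_identical(fit$module$params, fit2$module$params)
  expect_identical(fit$heads, fit2$heads)

  fit3 <- suppressMessages(
    train_impairment_module(co, sg, tiny_train_config(seed = 8)))
  expect_false(identical(fit$module$params, fit3$module$params))

  expect_error(train_impairment_module(co, list(q1 = character())),
               "no trait has any seed genes")
})

test_that("training respects the epoch bounds and holdout fraction", {
  co <- small_cohort()
  sg <- list(q1 = co$truth$seed_genes$q1)
  cfg <- train_config(min_epochs = 4, max_epochs = 6, patience = 1,
                      val_fraction = 0.25, batch_size = 256, seed = 1)
  fit <- suppressMessages(train_impairment_module(co, sg, cfg))
  expect_gte(max(fit$log$epoch), 4)
  expect_lte(max(fit$log$epoch), 6)
  expect_gte(fit$best_epoch, 4)
})
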