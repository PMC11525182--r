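# End-to-end training of the impairment module: multitask linear phenotype
# heads on top of the shared set network, mini-batch AdamW, per-trait
# validation holdout, early stopping on validation loss.

#' Training configuration
#'
#' Defaults follow the architecture's standard recipe: AdamW (decoupled
#' weight decay 0.01) at learning rate 0.001, batch size 1,024
#' individual-phenotype pairs, between 50 and 1,000 epochs with early
#' stopping (patience 10) on the validation loss over a 20% per-trait
#' holdout, and a training qualifying-variant MAF cutoff of 1%.
#'
#' @param lr learning rate
#' @param batch_size individual-phenotype pairs per batch
#' @param min_epochs,max_epochs epoch bounds
#' @param patience epochs without validation improvement before stopping
#'   (applies after `min_epochs`)
#' @param val_fraction per-trait fraction of individuals held out for
#'   validation, in (0, 1)
#' @param weight_decay decoupled weight-decay coefficient
#' @param maf_cutoff_train qualifying-variant MAF cutoff during training
#' @param cadd_cutoff qualifying-variant CADD cutoff
#' @param activation set-network activation (`"leaky_relu"` or the
#'   `"linear"` ablation)
#' @param seed integer seed (initialisation, shuffling, validation split)
#' @param verbose print a line every 25 epochs
#' @return list of class `train_config`
#' @export
train_config <- function(lr = 1e-3, batch_size = 1024L, min_epochs = 50L,
                         max_epochs = 1000L, patience = 10L,
                         val_fraction = 0.2, weight_decay = 0.01,
                         maf_cutoff_train = 0.01, cadd_cutoff = 5,
                         activation = "leaky_relu", seed = 1L,
                         verbose = FALSE) {
  assert_that(val_fraction > 0 && val_fraction < 1,
              "`val_fraction` must lie in (0, 1)")
  assert_that(min_epochs <= max_epochs, "min_epochs must be <= max_epochs")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, weight_decay = weight_decay,
                 maf_cutoff_train = maf_cutoff_train,
                 cadd_cutoff = cadd_cutoff, activation = activation,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

adamw_new <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adamw_step <- function(params, grads, state, t, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           wd * params[[nm]])
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train the gene impairment module end to end
#'
#' Optimizes the shared set network together with per-trait linear heads
#' (covariate effects plus one weight per seed gene) by mini-batch AdamW
#' on the per-trait mean squared error, averaged over traits. Phenotypes
#' are quantile-transformed and covariates standardized internally; a 20%
#' per-trait validation holdout drives early stopping, and the checkpoint
#' with the lowest validation loss (reached after at least `min_epochs`)
#' is returned.
#'
#' @param cohort an `rvat_cohort`
#' @param seed_genes named list: trait name -> character vector of seed
#'   gene ids (traits with empty sets are dropped; at least one trait must
#'   keep seeds)
#' @param config a [train_config()]
#' @param individuals optional subset of individual ids to train on (used
#'   by the cross-validation scheme); default: all
#' @return object of class `impairment_fit`: `module`, `heads`,
#'   `log` (epoch, train_loss, val_loss), `best_epoch`, covariate
#'   transform, seed-gene bookkeeping
#' @export
train_impairment_module <- function(cohort, seed_genes,
                                    config = train_config(),
                                    individuals = NULL) {
  seed_genes <- seed_genes[lengths(seed_genes) > 0]
  if (length(seed_genes) == 0) abort("no trait has any seed genes")
  traits <- names(seed_genes)
  assert_that(all(traits %in% trait_names(cohort) |
                    traits %in% names(cohort$phenotypes)),
              "seed-gene list names must be phenotype columns")
  all_ind <- cohort$genotypes$individual_id
  individuals <- individuals %||% all_ind
  ind_idx <- match(individuals, all_ind)
  n <- length(individuals)

  sg_all <- sort(unique(unlist(seed_genes)))
  n_sg <- length(sg_all)

  # qualifying variants at the training cutoff; annotation standardization
  # is fit on this variant pool and stored with the module
  qual <- suppressMessages(filter_qualifying_variants(
    cohort$variants, config$maf_cutoff_train, config$cadd_cutoff))
  module <- new_impairment_module(annotation_columns(cohort),
                                  seed = config$seed,
                                  activation = config$activation)
  A_all <- as.matrix(qual[, module$annotation_cols, drop = FALSE])
  module$center <- colMeans(A_all)
  module$scale <- pmax(apply(A_all, 2, sd), 1e-8)
  module$maf_cutoff_train <- config$maf_cutoff_train

  carry_raw <- build_variant_sets(cohort$genotypes, cohort$assignments,
                                  qual$variant_id, genes = sg_all)
  carry_raw <- dplyr::filter(carry_raw, .data$individual_id %in% individuals)
  vkey <- unique(carry_raw$variant_id)
  A_std <- standardize_annotations(
    module, as.matrix(qual[match(vkey, qual$variant_id),
                           module$annotation_cols, drop = FALSE]))
  carry <- data.table::data.table(
    i = match(carry_raw$individual_id, individuals),
    j = match(carry_raw$gene_id, sg_all),
    var_row = match(carry_raw$variant_id, vkey))
  data.table::setkey(carry, i)

  # covariates (standardized) and quantile-transformed targets
  Xraw <- as.matrix(cohort$covariates[ind_idx,
                                      setdiff(names(cohort$covariates),
                                              "individual_id")])
  cov_center <- colMeans(Xraw)
  cov_scale <- pmax(apply(Xraw, 2, sd), 1e-8)
  Xs <- cbind(intercept = 1, sweep(sweep(Xraw, 2, cov_center), 2, cov_scale, `/`))
  q_cov <- ncol(Xs)

  withr::local_seed(derive_seed(config$seed, "train"))
  y_list <- list(); train_rows <- list(); val_rows <- list()
  for (p in traits) {
    yp <- cohort$phenotypes[[p]][ind_idx]
    okp <- which(!is.na(yp))
    yq <- rep(NA_real_, n)
    yq[okp] <- quantile_transform(yp[okp])
    y_list[[p]] <- yq
    n_val <- max(1L, round(config$val_fraction * length(okp)))
    val <- sample(okp, n_val)
    val_rows[[p]] <- val
    train_rows[[p]] <- setdiff(okp, val)
  }

  heads <- lapply(traits, function(p) {
    list(alpha = rep(0, q_cov), w = rep(0, length(seed_genes[[p]])))
  })
  names(heads) <- traits
  sg_local <- lapply(seed_genes, function(g) match(g, sg_all))

  opt_net <- adamw_new(module$params)
  opt_heads <- lapply(heads, adamw_new)

  # flat table of all training (individual, trait) pairs
  pair_tab <- dplyr::bind_rows(lapply(traits, function(p) {
    tibble::tibble(trait = p, i = train_rows[[p]])
  }))
  n_pairs_total <- nrow(pair_tab)

  psi_dense <- function(rows) {
    # dense (length(rows) x n_sg) psi matrix for a set of individual rows
    sub <- carry[J(rows), nomatch = NULL]
    P <- matrix(0, length(rows), n_sg)
    if (nrow(sub) == 0) return(list(P = P, sub = sub, fw = NULL, upair = NULL))
    li <- match(sub$i, rows)
    key <- (li - 1L) * n_sg + sub$j
    upair <- match(key, unique(key))
    fw <- set_forward(module, A_std,
                      data.frame(pair_id = upair, var_row = sub$var_row),
                      max(upair))
    first <- !duplicated(upair)
    P[cbind(li[first], sub$j[first])] <- fw$psi
    list(P = P, sub = sub, fw = fw, upair = upair, li = li, first = first)
  }

  eval_loss <- function(rows_list) {
    rows_all <- sort(unique(unlist(rows_list)))
    ps <- psi_dense(rows_all)
    per_trait <- vapply(traits, function(p) {
      rws <- rows_list[[p]]
      ri <- match(rws, rows_all)
      yhat <- as.vector(Xs[rws, , drop = FALSE] %*% heads[[p]]$alpha) +
        as.vector(ps$P[ri, sg_local[[p]], drop = FALSE] %*% heads[[p]]$w)
      mean((yhat - y_list[[p]][rws])^2)
    }, 0)
    mean(per_trait)
  }

  best <- list(loss = Inf, module = module, heads = heads, epoch = 0L)
  log <- list()
  t_step <- 0L
  epochs_since_best <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n_pairs_total)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    epoch_loss <- 0
    for (bt in batches) {
      bp <- pair_tab[bt, ]
      bi <- sort(unique(bp$i))
      ps <- psi_dense(bi)
      traits_b <- unique(bp$trait)
      dPsi <- matrix(0, length(bi), n_sg)
      grads_heads <- list()
      bloss <- 0
      for (p in traits_b) {
        rws <- bp$i[bp$trait == p]
        ri <- match(rws, bi)
        hp <- heads[[p]]
        Pp <- ps$P[ri, sg_local[[p]], drop = FALSE]
        yhat <- as.vector(Xs[rws, , drop = FALSE] %*% hp$alpha) +
          as.vector(Pp %*% hp$w)
        resid_p <- yhat - y_list[[p]][rws]
        bloss <- bloss + mean(resid_p^2)
        dyhat <- 2 * resid_p / (length(traits_b) * length(rws))
        grads_heads[[p]] <- list(
          alpha = as.vector(crossprod(Xs[rws, , drop = FALSE], dyhat)),
          w = as.vector(crossprod(Pp, dyhat)))
        idx <- cbind(rep(ri, length(sg_local[[p]])),
                     rep(sg_local[[p]], each = length(ri)))
        dPsi[idx] <- dPsi[idx] + outer(dyhat, hp$w)
      }
      bloss <- bloss / length(traits_b)
      epoch_loss <- epoch_loss + bloss * length(bt)

      if (!is.finite(bloss)) abort("training diverged (non-finite loss)")

      if (nrow(ps$sub) > 0) {
        dpsi_pair <- rep(0, max(ps$upair))
        fi <- which(ps$first)
        dpsi_pair[ps$upair[fi]] <- dPsi[cbind(ps$li[fi], ps$sub$j[fi])]
        grads_net <- set_backward(module, A_std, ps$fw, dpsi_pair)
        t_step <- t_step + 1L
        up <- adamw_step(module$params, grads_net, opt_net, t_step,
                         config$lr, config$weight_decay)
        module$params <- up$params
        opt_net <- up$state
      }
      for (p in traits_b) {
        uph <- adamw_step(heads[[p]], grads_heads[[p]], opt_heads[[p]],
                          max(t_step, 1L), config$lr, config$weight_decay)
        heads[[p]] <- uph$params
        opt_heads[[p]] <- uph$state
      }
    }
    train_loss <- epoch_loss / n_pairs_total
    val_loss <- eval_loss(val_rows)
    log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss)
    if (config$verbose && epoch %% 25 == 0) {
      inform(sprintf("epoch %d: train %.4f val %.4f", epoch, train_loss,
                     val_loss))
    }
    # the checkpoint is only eligible once the minimum epoch count is reached
    if (epoch >= config$min_epochs && val_loss < best$loss) {
      best <- list(loss = val_loss, module = module, heads = heads,
                   epoch = epoch)
      epochs_since_best <- 0L
    } else {
      epochs_since_best <- epochs_since_best + 1L
    }
    if (epoch >= config$min_epochs && epochs_since_best >= config$patience) {
      break
    }
  }

  structure(
    list(module = best$module, heads = best$heads,
         log = dplyr::bind_rows(log), best_epoch = best$epoch,
         best_val_loss = best$loss,
         seed_genes = seed_genes, traits = traits,
         cov_center = cov_center, cov_scale = cov_scale,
         individuals = individuals, config = config),
    class = "impairment_fit")
}

#' @export
print.impairment_fit <- function(x, ...) {
  cat(sprintf("<impairment_fit> %d trait(s), %d seed gene(s), best epoch %d (val loss %.4f)\n",
              length(x$traits), length(unique(unlist(x$seed_genes))),
              x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict a phenotype from covariates and gene impairment scores
#'
#' The phenotype head's linear predictor: standardized covariates times
#' their coefficients plus the seed-gene impairment scores times the
#' learned gene weights. Genes outside the trait's seed set contribute
#' nothing; empty variant sets score 0.
#'
#' @param fit an `impairment_fit`
#' @param cohort an `rvat_cohort`
#' @param trait trait name
#' @param individuals individual ids (default: the fit's training
#'   individuals)
#' @return named numeric vector of predictions
#' @export
forward_predict <- function(fit, cohort, trait, individuals = NULL) {
  assert_that(trait %in% fit$traits, "trait was not part of this fit")
  individuals <- individuals %||% fit$individuals
  idx <- match(individuals, cohort$genotypes$individual_id)
  if (anyNA(idx)) abort("unknown individual id(s)")
  Xraw <- as.matrix(cohort$covariates[idx, setdiff(names(cohort$covariates),
                                                   "individual_id")])
  Xs <- cbind(1, sweep(sweep(Xraw, 2, fit$cov_center), 2, fit$cov_scale, `/`))
  hp <- fit$heads[[trait]]
  S <- score_matrix(fit$module, cohort, genes = fit$seed_genes[[trait]],
                    maf_cutoff = fit$config$maf_cutoff_train,
                    cadd_cutoff = fit$config$cadd_cutoff)
  yhat <- as.vector(Xs %*% hp$alpha) +
    as.vector(S[idx, , drop = FALSE] %*% hp$w)
  setNames(yhat, individuals)
}
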