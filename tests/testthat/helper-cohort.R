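# Shared small fixtures, built in code and memoised per test run.

# internal helpers exercised directly by the suite
pvalue_chisq_mixture <- rvatnet:::pvalue_chisq_mixture
derive_seed <- rvatnet:::derive_seed

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_individuals = 800, n_genes = 12, variants_per_gene = 25,
        rng_seed = 101,
        traits = list(
          trait_config("q1", n_seed_genes = 3, effect_size = 0.8),
          trait_config("qnull", n_seed_genes = 0),
          trait_config("b1", type = "binary", n_seed_genes = 2,
                       effect_size = 0.8, prevalence = 0.2)))
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

tiny_train_config <- function(seed = 1, ...) {
  train_config(min_epochs = 3, max_epochs = 3, patience = 99,
               batch_size = 256, seed = seed, ...)
}

# deterministic toy module whose phi embedding is (a monotone transform of)
# the annotation vector itself, padded to the embedding width; element-wise
# domination between variants is preserved end to end
identity_phi_module <- function(d) {
  mod <- new_impairment_module(paste0("x", seq_len(d)), seed = 1)
  W1 <- matrix(0, d, 20); diag(W1[, seq_len(d)]) <- 1
  mod$params$W1 <- W1
  mod$params$b1 <- rep(0, 20)
  mod$params$W2 <- diag(20)
  mod$params$b2 <- rep(0, 20)
  mod
}
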