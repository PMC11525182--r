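test_that("annotation generator honours the configured causal/decoy
           correlation", {
  cfg0 <- sim_config(n_genes = 334, variants_per_gene = 30,  # ~10k variants
                     annotation_correlation = 0, rng_seed = 5)
  va <- simulate_variants_and_annotations(cfg0)
  # decoy a5 is generated from causal a1's noise stream at rho = 0
  expect_lt(abs(cor(va$variants$a5, va$variants$a2)), 0.05)
  expect_lt(abs(cor(va$variants$a6, va$variants$a3)), 0.05)
  cfg7 <- sim_config(n_genes = 334, annotation_correlation = 0.7, rng_seed = 5)
  va7 <- simulate_variants_and_annotations(cfg7)
  expect_gt(cor(va7$variants$a5, va7$variants$a1), 0.6)
})

test_that("zero impairment slope collapses every variant impact to the
           baseline", {
  cfg <- sim_config(n_genes = 10, impairment_scale = 0, rng_seed = 2)
  va <- simulate_variants_and_annotations(cfg)
  expect_true(all(va$truth$variant_u$u == va$truth$variant_u$u[1]))
})

test_that("identical config and seed give bit-identical cohorts; different
           seeds differ", {
  cfg <- sim_config(n_individuals = 300, n_genes = 8, rng_seed = 33)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$variants, c2$variants)
  expect_identical(as.matrix(c1$genotypes$mat), as.matrix(c2$genotypes$mat))
  expect_identical(c1$phenotypes, c2$phenotypes)
  cfg2 <- sim_config(n_individuals = 300, n_genes = 8, rng_seed = 34)
  c3 <- simulate_cohort(cfg2)
  expect_false(identical(as.matrix(c1$genotypes$mat),
                         as.matrix(c3$genotypes$mat)))
  expect_identical(dim(c1$genotypes$mat), dim(c3$genotypes$mat))
})

test_that("genotypes follow Binomial(2, MAF): empirical frequency, carrier
           counts, and domain errors", {
  v <- tibble::tibble(variant_id = "v1", maf = 0.001)
  g <- simulate_genotypes(v, 100000, seed = 6)
  af <- sum(g$mat) / (2 * 100000)
  expect_gte(af, 0.0007)  # 3 binomial SDs
  expect_lte(af, 0.0013)

  # carrier count for MAF = 5e-4, n = 10,000 is approximately Poisson(10)
  v2 <- tibble::tibble(variant_id = sprintf("v%d", 1:200), maf = 0.0005)
  g2 <- simulate_genotypes(v2, 10000, seed = 7)
  carriers <- Matrix::colSums(g2$mat > 0)
  expect_equal(mean(carriers), 10, tolerance = 0.15)
  expect_equal(var(carriers), 10, tolerance = 0.35)

  expect_error(simulate_genotypes(tibble::tibble(variant_id = "x", maf = 0),
                                  100), "MAFs must lie")
})

test_that("ground-truth impairment is a max over member impacts, zero on the
           empty set, permutation-invariant", {
  expect_equal(true_impairment(c(0.2, 0.9, 0.1)), 0.9)
  expect_equal(true_impairment(numeric()), 0)
  u <- runif(7)
  expect_equal(true_impairment(u), true_impairment(rev(u)))
  expect_equal(true_impairment(sample(u)), max(u))
  co <- small_cohort()
  U <- co$truth$gene_impairment
  carriers <- rowSums(co$genotypes$mat) > 0
  expect_true(all(U[!carriers, ] == 0))
})

test_that("phenotypes: nulls are pure noise, binary case counts are binomial,
           prevalence is validated", {
  co <- small_cohort()
  U <- co$truth$gene_impairment
  # pure-noise trait via zero covariate effects and no seed genes
  ph <- simulate_phenotypes(U, co$covariates,
                            list(trait_config("null", n_seed_genes = 0)),
                            colnames(U), seed = 8,
                            covariate_effects = rep(0, 14))
  y <- ph$phenotypes$null
  expect_lt(abs(mean(y)), 3 / sqrt(length(y)))
  expect_equal(sd(y), 1, tolerance = 0.1)

  phb <- simulate_phenotypes(U, co$covariates,
                             list(trait_config("b", type = "binary",
                                               prevalence = 0.1)),
                             colnames(U), seed = 9)
  cases <- sum(phb$phenotypes$b)
  expect_lt(abs(cases - 80), 3 * sqrt(800 * 0.1 * 0.9) + 1)
  expect_error(trait_config("bad", type = "binary", prevalence = 1.2),
               "prevalence")
})

test_that("realized variance decomposition matches the configured components", {
  cfg <- sim_config(n_individuals = 20000, n_genes = 30, rng_seed = 55,
                    traits = list(trait_config("q", n_seed_genes = 10,
                                               effect_size = 0.8)))
  co <- simulate_cohort(cfg)
  U <- co$truth$gene_impairment
  sg <- co$truth$seed_genes$q
  w <- attr(sg, "effects")
  genetic <- as.vector(U[, sg] %*% w)
  y <- co$phenotypes$q
  frac_emp <- var(genetic) / var(y)
  # components: genetic + covariate base + unit noise (cross terms ~ 0)
  Xs <- scale(as.matrix(co$covariates[, -1]))
  base <- as.vector(Xs %*% c(0.1, 0.2, 0.05, 0.05, rep(0.02, 10)))
  frac_conf <- var(genetic) / (var(genetic) + var(base) + 1)
  expect_equal(frac_emp, frac_conf, tolerance = 0.2)
})

test_that("cohorts with zero seed genes give a null association scan", {
  cfg <- sim_config(n_individuals = 600, n_genes = 10, rng_seed = 77,
                    traits = list(trait_config("z", n_seed_genes = 0)))
  co <- simulate_cohort(cfg)
  expect_length(co$truth$seed_genes$z, 0)
  # oracle scores (true impairment) against a null trait: no signal
  a <- suppressWarnings(
    association_scan(co$truth$gene_impairment, co, "z", maf_cutoff = 0.01,
                     eaf_threshold = 1))
  expect_gt(min(a$p, na.rm = TRUE), 0.05 / (2 * nrow(a)))
})

test_that("variant placement exercises both sides of the assignment window", {
  co <- small_cohort()
  tv <- co$truth$variant_u
  asn_ids <- unique(co$assignments$variant_id)
  expect_true(all(tv$variant_id[tv$placement != "out"] %in% asn_ids))
  expect_false(any(tv$variant_id[tv$placement == "out"] %in% asn_ids))
})
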