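#' Configuration for a synthetic rare-variant cohort
#'
#' Defines the generative model used throughout the test-bench: rare
#' genotypes without linkage disequilibrium, multi-dimensional variant
#' annotations of which a subset drive a known nonlinear impairment
#' function, trait-specific seed genes with additive gene-level effects,
#' and the usual covariate set (sex, age, age^2, age x sex, PC-like noise
#' columns).
#'
#' @param n_individuals cohort size
#' @param n_genes number of genes laid out on one synthetic chromosome
#' @param variants_per_gene variants generated per gene (single count)
#' @param maf_range minor-allele-frequency range; MAFs are drawn
#'   log-uniformly on this interval. Default `c(1e-4, 1e-2)` spans both the
#'   training (< 1%) and association (< 0.1%) rarity regimes.
#' @param n_annotations number of annotation columns `a1..ad`
#' @param n_causal_annotations how many of them (the leading ones) drive the
#'   true impairment
#' @param annotation_correlation correlation in `[-1, 1]` between each decoy
#'   annotation and a causal one
#' @param impairment_form ground-truth variant impact function:
#'   `"linear"` (logistic of a weighted sum of causal annotations),
#'   `"threshold"` (step function of the same weighted sum), or
#'   `"interaction"` (logistic of the product `a1 * a2`, with no additive
#'   term, so that no single annotation is marginally sufficient)
#' @param impairment_scale slope `b` inside the impact function; `b = 0`
#'   collapses every variant to the same baseline impact
#' @param traits list of trait configurations from [trait_config()]
#' @param n_pcs number of principal-component-like covariate columns
#' @param rng_seed integer seed; the whole cohort is reproducible from it
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_individuals = 2000,
                       n_genes = 100,
                       variants_per_gene = 30,
                       maf_range = c(1e-4, 1e-2),
                       n_annotations = 8,
                       n_causal_annotations = 4,
                       annotation_correlation = 0.3,
                       impairment_form = c("linear", "threshold", "interaction"),
                       impairment_scale = 1,
                       traits = list(trait_config("trait1")),
                       n_pcs = 10,
                       rng_seed = 1L) {
  impairment_form <- match.arg(impairment_form)
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 &&
                maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "`maf_range` must satisfy 0 < min <= max <= 0.5")
  if (n_causal_annotations > n_annotations) {
    abort("`n_causal_annotations` cannot exceed `n_annotations`")
  }
  assert_that(n_causal_annotations >= 1, "need at least one causal annotation")
  if (impairment_form == "interaction" && n_causal_annotations < 2) {
    abort("interaction-form impairment needs >= 2 causal annotations")
  }
  assert_that(abs(annotation_correlation) <= 1,
              "`annotation_correlation` must lie in [-1, 1]")
  for (tr in traits) {
    assert_that(inherits(tr, "trait_config"), "traits must come from trait_config()")
    if (!is.null(tr$seed_genes)) {
      assert_that(all(tr$seed_genes >= 1 & tr$seed_genes <= n_genes),
                  "every seed gene index must be < n_genes")
    }
    assert_that(tr$noise_sd > 0, "noise variance must be > 0")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_genes = as.integer(n_genes),
         variants_per_gene = as.integer(variants_per_gene),
         maf_range = maf_range,
         n_annotations = as.integer(n_annotations),
         n_causal_annotations = as.integer(n_causal_annotations),
         annotation_correlation = annotation_correlation,
         impairment_form = impairment_form,
         impairment_scale = impairment_scale,
         traits = traits,
         n_pcs = as.integer(n_pcs),
         rng_seed = as.integer(rng_seed)),
    class = "sim_config")
}

#' Configuration for one synthetic trait
#'
#' @param name trait name (column in the phenotype table)
#' @param type `"quantitative"` or `"binary"` (liability-threshold)
#' @param n_seed_genes number of causal genes; 0 gives a pure-null trait
#' @param seed_genes optional explicit gene indices (1-based); otherwise
#'   blocks of genes are allocated per trait without overlap
#' @param effect_size gene-level effect `w_j` applied to the true impairment
#'   `u_ij` (recycled across the trait's seed genes)
#' @param noise_sd residual standard deviation of the latent quantitative
#'   trait
#' @param prevalence case fraction for binary traits, in (0, 1)
#' @export
trait_config <- function(name, type = c("quantitative", "binary"),
                         n_seed_genes = 0, seed_genes = NULL,
                         effect_size = 0.4, noise_sd = 1,
                         prevalence = NULL) {
  type <- match.arg(type)
  if (type == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1) {
      abort("binary traits need a prevalence strictly inside (0, 1)")
    }
  }
  structure(list(name = name, type = type,
                 n_seed_genes = as.integer(n_seed_genes),
                 seed_genes = seed_genes,
                 effect_size = effect_size, noise_sd = noise_sd,
                 prevalence = prevalence),
            class = "trait_config")
}

# Lay out n_genes on one synthetic chromosome, three exons each.
make_gene_models <- function(n_genes, spacing = 50000L) {
  exon_len <- 300L
  intron <- 700L
  starts <- (seq_len(n_genes) - 1L) * spacing + 10000L
  purrr::map_dfr(seq_len(n_genes), function(j) {
    es <- starts[j] + (0:2) * (exon_len + intron)
    tibble::tibble(gene_id = sprintf("gene%03d", j), chrom = "chr1",
                   exon_start = es, exon_end = es + exon_len - 1L,
                   strand = "+")
  })
}

# True per-variant impact u_k in [0, 1] from the causal annotations.
variant_impact <- function(A_causal, form, b) {
  s <- switch(form,
    linear = as.vector(A_causal %*% rep(1, ncol(A_causal))) / sqrt(ncol(A_causal)),
    threshold = as.vector(A_causal %*% rep(1, ncol(A_causal))) / sqrt(ncol(A_causal)),
    interaction = A_causal[, 1] * A_causal[, 2]
  )
  # interaction form carries a negative offset so that variants are
  # damaging only when both causal annotations align (no single annotation
  # is marginally informative, and most variants sit near the baseline)
  switch(form,
    linear = stats::plogis(b * s),
    threshold = ifelse(b * s > 1, 0.95, 0.02),
    interaction = stats::plogis(b * s - 2)
  )
}

#' Simulate annotated variants with known ground-truth impact
#'
#' Places `variants_per_gene` variants per gene: most inside exons, some
#' within the 300 bp assignment window, and a few just outside it so the
#' assignment rule is exercised. Draws MAFs log-uniformly, annotations with
#' the configured causal/decoy correlation structure, variant-class flags
#' (pLOF, missense, synonymous, disruptive missense) that shift the first
#' causal annotation (damaging classes look damaging), and a CADD-like
#' PHRED score correlated with that annotation.
#'
#' @param config a [sim_config()]
#' @return list with `variants` (annotated variant tibble including the
#'   transformed-MAF column `maf_trans`), `gene_models`, and `truth`
#'   (per-variant true impact `u`, intended gene, causal annotation indices)
#' @export
simulate_variants_and_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(derive_seed(config$rng_seed, "variants"))
  gm <- make_gene_models(config$n_genes)
  d <- config$n_annotations
  nc <- config$n_causal_annotations
  m_per <- config$variants_per_gene
  m <- config$n_genes * m_per

  gene_of <- rep(sprintf("gene%03d", seq_len(config$n_genes)), each = m_per)
  # placement: ~85% exonic, ~10% near (<=300 bp), ~5% outside (301..1000 bp)
  placement <- sample(c("exon", "near", "out"), m, replace = TRUE,
                      prob = c(0.85, 0.10, 0.05))
  exons <- dplyr::group_by(gm, .data$gene_id) |>
    dplyr::summarise(starts = list(.data$exon_start), ends = list(.data$exon_end))
  exof <- match(gene_of, exons$gene_id)
  pos <- integer(m)
  for (k in seq_len(m)) {
    ss <- exons$starts[[exof[k]]]
    ee <- exons$ends[[exof[k]]]
    e <- sample(length(ss), 1)
    pos[k] <- switch(placement[k],
      exon = sample(ss[e]:ee[e], 1),
      near = ee[e] + sample(1:300, 1),
      out = ee[3] + sample(301:1000, 1))
  }

  maf <- exp(runif(m, log(config$maf_range[1]), log(config$maf_range[2])))

  # variant classes: mutually exclusive primary class, disruptive subset of
  # missense
  cls <- sample(c("plof", "missense", "synonymous", "other"), m,
                replace = TRUE, prob = c(0.1, 0.45, 0.25, 0.2))
  is_plof <- cls == "plof"
  is_missense <- cls == "missense"
  is_synonymous <- cls == "synonymous"
  is_disruptive <- is_missense & (runif(m) < 0.3)

  A <- matrix(rnorm(m * d), m, d)
  # damaging variant classes shift the first causal annotation upward
  A[, 1] <- A[, 1] + 1.5 * is_plof + 0.8 * is_disruptive - 0.5 * is_synonymous
  rho <- config$annotation_correlation
  if (nc < d) {
    for (l in (nc + 1):d) {
      src <- ((l - nc - 1) %% nc) + 1
      A[, l] <- rho * A[, src] + sqrt(1 - rho^2) * A[, l]
    }
  }
  cadd <- pmax(0, 12 + 3 * A[, 1] + rnorm(m, 0, 4))

  u <- variant_impact(A[, seq_len(nc), drop = FALSE],
                      config$impairment_form, config$impairment_scale)

  variants <- tibble::tibble(
    variant_id = sprintf("chr1:%d:A:G:%04d", pos, seq_len(m)),
    chrom = "chr1", pos = pos, ref = "A", alt = "G",
    maf = maf, cadd_phred = cadd,
    is_plof = is_plof, is_missense = is_missense,
    is_disruptive_missense = is_disruptive, is_synonymous = is_synonymous
  )
  colnames(A) <- paste0("a", seq_len(d))
  variants <- dplyr::bind_cols(variants, tibble::as_tibble(A))
  variants$maf_trans <- transform_maf(maf)

  truth_variants <- tibble::tibble(variant_id = variants$variant_id,
                                   intended_gene = gene_of, u = u,
                                   placement = placement)
  list(variants = variants, gene_models = gm,
       truth = list(variant_u = truth_variants,
                    causal_annotations = seq_len(nc)))
}

#' Sparse genotype container
#'
#' Individuals x variants allele counts stored sparsely (only counts 1 and
#' 2), with per-variant MAF metadata.
#'
#' @param mat a `Matrix::dgCMatrix` (individuals x variants) of allele counts
#' @param individual_id,variant_id row/column keys
#' @param maf per-variant minor allele frequencies
#' @return an object of class `sparse_genotypes`
#' @export
sparse_genotypes <- function(mat, individual_id, variant_id, maf) {
  assert_that(nrow(mat) == length(individual_id), "row key length mismatch")
  assert_that(ncol(mat) == length(variant_id), "column key length mismatch")
  assert_that(ncol(mat) == length(maf), "maf length mismatch")
  mat <- methods::as(methods::as(mat, "CsparseMatrix"), "generalMatrix")
  x <- mat@x
  assert_that(all(x %in% c(1, 2)), "allele counts must be 1 or 2 where stored")
  structure(list(mat = mat, individual_id = individual_id,
                 variant_id = variant_id, maf = maf),
            class = "sparse_genotypes")
}

#' @export
print.sparse_genotypes <- function(x, ...) {
  cat(sprintf("<sparse_genotypes> %d individuals x %d variants, %d nonzero\n",
              nrow(x$mat), ncol(x$mat), length(x$mat@x)))
  invisible(x)
}

#' Simulate rare genotypes
#'
#' Allele counts are drawn independently per individual and variant as
#' Binomial(2, MAF); no linkage disequilibrium. Rare variants make the
#' matrix very sparse, so carriers are sampled directly from the binomial
#' tail instead of materialising the dense matrix.
#'
#' @param variants variant tibble with `variant_id` and `maf`
#' @param n_individuals cohort size
#' @param seed integer seed
#' @return a [sparse_genotypes] object
#' @export
simulate_genotypes <- function(variants, n_individuals, seed = 1L) {
  maf <- variants$maf
  if (any(maf <= 0) || any(maf > 0.5)) {
    abort("MAFs must lie in (0, 0.5] to simulate genotypes")
  }
  withr::local_seed(derive_seed(seed, "genotypes"))
  m <- length(maf)
  ii <- vector("list", m)
  xx <- vector("list", m)
  for (k in seq_len(m)) {
    p <- maf[k]
    n_carrier <- rbinom(1, n_individuals, 2 * p * (1 - p) + p^2)
    if (n_carrier == 0) next
    idx <- sample.int(n_individuals, n_carrier)
    # among carriers, hom-alt with conditional probability p^2 / P(carrier)
    p_hom <- p^2 / (2 * p * (1 - p) + p^2)
    ii[[k]] <- idx
    xx[[k]] <- ifelse(runif(n_carrier) < p_hom, 2, 1)
  }
  lens <- lengths(ii)
  mat <- Matrix::sparseMatrix(
    i = unlist(ii) %||% integer(),
    j = rep.int(seq_len(m), lens),
    x = as.numeric(unlist(xx) %||% numeric()),
    dims = c(n_individuals, m))
  sparse_genotypes(mat, sprintf("ind%06d", seq_len(n_individuals)),
                   variants$variant_id, maf)
}

#' Ground-truth gene impairment of a variant-impact set
#'
#' Aggregates the true per-variant impacts carried by one individual in one
#' gene. The default aggregation is the maximum, matching the scoring
#' model's inductive bias; the empty set maps to 0 (no qualifying rare
#' variants, no measured impairment). Permutation-invariant by
#' construction.
#'
#' @param u numeric vector of member-variant impacts in `[0, 1]` (possibly
#'   empty)
#' @param aggregation `"max"`, `"sum"` (clipped at 1), or `"mean"`
#' @return scalar impairment in `[0, 1]`
#' @export
true_impairment <- function(u, aggregation = c("max", "sum", "mean")) {
  aggregation <- match.arg(aggregation)
  if (length(u) == 0) return(0)
  switch(aggregation,
         max = max(u),
         sum = min(1, sum(u)),
         mean = mean(u))
}

# individuals x genes matrix of true impairment (max-aggregated), using the
# same carry structure the model sees
true_impairment_matrix <- function(genotypes, assignments, truth_u, genes) {
  carry <- build_variant_sets(genotypes, assignments,
                              qualifying_ids = truth_u$variant_id,
                              genes = genes)
  n <- length(genotypes$individual_id)
  U <- matrix(0, n, length(genes), dimnames = list(genotypes$individual_id, genes))
  if (nrow(carry) == 0) return(U)
  dt <- data.table::data.table(
    i = match(carry$individual_id, genotypes$individual_id),
    j = match(carry$gene_id, genes),
    u = truth_u$u[match(carry$variant_id, truth_u$variant_id)])
  agg <- dt[, .(u = max(u)), by = .(i, j)]
  U[cbind(agg$i, agg$j)] <- agg$u
  U
}

#' Simulate covariates
#'
#' Binary sex, Normal age, derived age^2 and age x sex, and `n_pcs`
#' standard-Normal principal-component-like columns.
#'
#' @param n_individuals cohort size
#' @param n_pcs number of PC-like columns
#' @param seed integer seed
#' @return tibble keyed by `individual_id`
#' @export
simulate_covariates <- function(n_individuals, n_pcs = 10, seed = 1L) {
  withr::local_seed(derive_seed(seed, "covariates"))
  sex <- rbinom(n_individuals, 1, 0.5)
  age <- rnorm(n_individuals, 55, 8)
  pcs <- matrix(rnorm(n_individuals * n_pcs), n_individuals, n_pcs)
  colnames(pcs) <- paste0("pc", seq_len(n_pcs))
  dplyr::bind_cols(
    tibble::tibble(individual_id = sprintf("ind%06d", seq_len(n_individuals)),
                   sex = sex, age = age, age2 = age^2, age_sex = age * sex),
    tibble::as_tibble(pcs))
}

#' Simulate phenotypes from genotypes and ground-truth impairment
#'
#' Quantitative traits follow `y_i = x_i' alpha + sum_j w_j u_ij + eps`,
#' with `eps ~ Normal(0, noise_sd^2)` and small fixed covariate effects on
#' standardized covariate columns. Binary traits threshold the standardized
#' latent value at the configured prevalence. Traits with no seed genes are
#' pure nulls.
#'
#' @param U individuals x genes matrix of true impairment `u_ij`
#' @param covariates covariate tibble from [simulate_covariates()]
#' @param traits list of [trait_config()]s
#' @param gene_ids column order of `U`
#' @param seed integer seed
#' @param covariate_effects optional vector of effects on the standardized
#'   covariate columns (default: small fixed effects; pass zeros for a
#'   covariate-free null)
#' @return list with `phenotypes` (tibble, one column per trait) and
#'   `seed_genes` (named list of gene-id vectors with attribute `effects`)
#' @export
simulate_phenotypes <- function(U, covariates, traits, gene_ids, seed = 1L,
                                covariate_effects = NULL) {
  withr::local_seed(derive_seed(seed, "phenotypes"))
  n <- nrow(U)
  Xs <- scale(as.matrix(covariates[, setdiff(names(covariates), "individual_id")]))
  alpha <- covariate_effects %||%
    c(0.1, 0.2, 0.05, 0.05, rep(0.02, ncol(Xs) - 4))
  assert_that(length(alpha) == ncol(Xs), "covariate effect length mismatch")
  base <- as.vector(Xs %*% alpha)

  next_gene <- 1L
  seed_sets <- list()
  phen <- tibble::tibble(individual_id = covariates$individual_id)
  for (tr in traits) {
    if (!is.null(tr$seed_genes)) {
      sg <- tr$seed_genes
    } else if (tr$n_seed_genes > 0) {
      sg <- seq.int(next_gene, length.out = tr$n_seed_genes)
      next_gene <- next_gene + tr$n_seed_genes
      if (max(sg) > length(gene_ids)) abort("not enough genes for seed-gene blocks")
    } else {
      sg <- integer()
    }
    w <- rep_len(tr$effect_size, length(sg))
    genetic <- if (length(sg) > 0) as.vector(U[, sg, drop = FALSE] %*% w) else 0
    y <- base + genetic + rnorm(n, 0, tr$noise_sd)
    if (tr$type == "binary") {
      z <- (y - mean(y)) / sd(y)
      y <- as.numeric(z > qnorm(1 - tr$prevalence))
    }
    phen[[tr$name]] <- y
    ss <- gene_ids[sg]
    attr(ss, "effects") <- w
    seed_sets[[tr$name]] <- ss
  }
  list(phenotypes = phen, seed_genes = seed_sets)
}

#' Simulate a complete cohort with known ground truth
#'
#' Composes variant, genotype, covariate and phenotype simulation into a
#' dataset with the exact shapes consumed by every downstream module, plus
#' a `truth` element holding the per-variant impacts, the per-gene
#' per-individual impairment `u_ij`, the causal-annotation index set and
#' the trait-wise seed genes with their effects.
#'
#' @param config a [sim_config()]
#' @return an object of class `rvat_cohort`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  va <- simulate_variants_and_annotations(config)
  geno <- simulate_genotypes(va$variants, config$n_individuals,
                             seed = derive_seed(config$rng_seed, "geno"))
  cov <- simulate_covariates(config$n_individuals, config$n_pcs,
                             seed = derive_seed(config$rng_seed, "cov"))
  assignments <- assign_variants_to_genes(va$variants, va$gene_models)
  gene_ids <- sort(unique(va$gene_models$gene_id))
  U <- true_impairment_matrix(geno, assignments, va$truth$variant_u, gene_ids)
  ph <- simulate_phenotypes(U, cov, config$traits, gene_ids,
                            seed = derive_seed(config$rng_seed, "phen"))
  structure(
    list(config = config,
         variants = va$variants,
         gene_models = va$gene_models,
         genotypes = geno,
         assignments = assignments,
         covariates = cov,
         phenotypes = ph$phenotypes,
         truth = list(variant_u = va$truth$variant_u,
                      gene_impairment = U,
                      causal_annotations = va$truth$causal_annotations,
                      seed_genes = ph$seed_genes)),
    class = "rvat_cohort")
}

#' @export
print.rvat_cohort <- function(x, ...) {
  cat(sprintf(paste0("<rvat_cohort> %d individuals, %d genes, %d variants, ",
                     "%d trait(s)\n"),
              x$config$n_individuals, x$config$n_genes, nrow(x$variants),
              length(x$config$traits)))
  cat("  traits:", paste(vapply(x$config$traits, `[[`, "", "name"),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Trait names of a cohort
#' @param cohort an `rvat_cohort`
#' @return character vector
#' @export
trait_names <- function(cohort) {
  vapply(cohort$config$traits, `[[`, "", "name")
}

#' Default annotation columns used by the impairment model
#' @param cohort an `rvat_cohort`
#' @return character vector of annotation column names (includes the
#'   transformed-MAF column)
#' @export
annotation_columns <- function(cohort) {
  c(paste0("a", seq_len(cohort$config$n_annotations)), "maf_trans")
}
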