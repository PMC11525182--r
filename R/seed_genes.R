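# Gene-based burden and SKAT score tests used for seed-gene discovery and
# as the conventional-RVAT comparator arm. The linear-model score test and
# the chi-square-mixture tail are implemented exactly as documented here
# and validated against permutation oracles in the test suite.

#' Beta(1, 25) variant weight
#'
#' The Beta density evaluated at the minor allele frequency, the standard
#' up-weighting of rarer variants in burden/SKAT tests. For the default
#' shape (1, 25) this is `25 * (1 - p)^24`.
#'
#' @param p allele frequency in `[0, 1)`
#' @param a,b Beta shape parameters (default 1, 25)
#' @return density values
#' @export
beta_weight <- function(p, a = 1, b = 25) {
  dbeta(p, a, b)
}

#' Collapse ultra-rare variants into a pseudo-marker
#'
#' Variants with minor allele count at most `mac_threshold` are replaced by
#' a single pseudo-marker whose per-individual value is the maximum allele
#' count carried across the collapsed variants; more common variants pass
#' through unchanged. Applied before SKAT testing.
#'
#' @param G individuals x variants allele-count matrix (dense or sparse)
#' @param mac_threshold collapse variants with MAC <= this value (default
#'   10)
#' @return matrix with collapsed columns; attribute `collapsed` gives the
#'   number of columns that were merged
#' @export
collapse_ultra_rare <- function(G, mac_threshold = 10) {
  G <- as.matrix(G)
  if (ncol(G) == 0) return(G)
  mac <- colSums(G)
  rare <- mac <= mac_threshold
  if (!any(rare)) {
    attr(G, "collapsed") <- 0L
    return(G)
  }
  pseudo <- apply(G[, rare, drop = FALSE], 1, max)
  out <- cbind(G[, !rare, drop = FALSE], pseudo = pseudo)
  attr(out, "collapsed") <- sum(rare)
  out
}

# Null-model pieces shared across genes for one trait. For quantitative
# traits: OLS residuals and sigma^2. For binary traits: logistic working
# residuals and the expected-information weight vector.
null_model <- function(y, X, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("covariate matrix is rank deficient")
  if (trait_type == "quantitative") {
    r <- qr.resid(qrX, y)
    sigma2 <- sum(r^2) / (length(y) - qrX$rank)
    list(type = "quantitative", qrX = qrX, X = X, r = r, sigma2 = sigma2)
  } else {
    fit <- glm.fit(X, y, family = binomial())
    mu <- fit$fitted.values
    d <- mu * (1 - mu)
    list(type = "binary", qrX = qrX, X = X, r = y - mu, d = d)
  }
}

# residualize columns of g on the null model's covariates, under the
# null model's metric (identity for linear, diag(d) for logistic)
residualize <- function(nm, g) {
  g <- as.matrix(g)
  if (nm$type == "quantitative") {
    qr.resid(nm$qrX, g)
  } else {
    Xd <- nm$X * nm$d
    g - nm$X %*% solve(crossprod(nm$X, Xd), crossprod(Xd, g))
  }
}

#' Burden score test
#'
#' Score test of a single per-individual burden against a trait under a
#' linear (quantitative) or logistic (binary) null model containing the
#' covariates. For the linear model the statistic is
#' `T = (g~' r)^2 / (sigma^2 * g~' g~)` with `g~` the burden residualized
#' on the covariates and `r` the null residuals; `T` is compared against
#' chi-square with 1 degree of freedom.
#'
#' @param g per-individual burden vector
#' @param y trait values
#' @param X covariate matrix including an intercept column
#' @param trait_type `"quantitative"` or `"binary"`
#' @param nm optional precomputed null model (for scans over many genes)
#' @return one-row tibble: `statistic`, `p`, `beta` (score-based effect
#'   direction/size), `n_markers`, `skipped`
#' @export
burden_score_test <- function(g, y, X, trait_type = "quantitative", nm = NULL) {
  nm <- nm %||% null_model(y, X, trait_type)
  gt <- residualize(nm, g)
  if (nm$type == "quantitative") {
    denom <- nm$sigma2 * sum(gt^2)
    num <- sum(gt * nm$r)
  } else {
    denom <- sum(gt^2 * nm$d)
    num <- sum(g * nm$r)
  }
  if (denom < .Machine$double.eps * length(g)) {
    warn("burden is (numerically) collinear with covariates; p set to 1")
    return(tibble::tibble(statistic = 0, p = 1, beta = NA_real_,
                          n_markers = 1L, skipped = FALSE))
  }
  stat <- num^2 / denom
  beta <- num / if (nm$type == "quantitative") sum(gt^2) else denom
  tibble::tibble(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
                 beta = beta, n_markers = 1L, skipped = FALSE)
}

# Tail probability of sum_i lambda_i * chisq_1 at q: four-moment matching
# (Liu-type) with an Imhof-type numerical-integration refinement for small
# matched p values.
#' @keywords internal
pvalue_chisq_mixture <- function(q, lambda, refine_below = 1e-4) {
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  if (length(lambda) == 0) return(1)
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- if (c3 > 0) c2^3 / c3^2 else 1 / s2
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  p <- pchisq(tstar * sqrt(2 * (l + 2 * delta)) + l + delta, df = l,
              ncp = delta, lower.tail = FALSE)
  if (is.finite(p) && p < refine_below) {
    p_imhof <- tryCatch(imhof_tail(q, lambda), error = function(e) NA_real_)
    if (is.finite(p_imhof)) p <- min(max(p_imhof, 0), 1)
  }
  p
}

# Imhof (1961) inversion integral for P(sum lambda_i chisq_1 > q)
imhof_tail <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- integrate(integrand, lower = 0, upper = Inf, rel.tol = 1e-9,
                   subdivisions = 2000L)$value
  0.5 + val / pi
}

#' SKAT variance-component score test
#'
#' Computes `Q = r' G W^2 G' r` with `W = diag(w)` and compares it against
#' its null distribution, a weighted sum of 1-df chi-squares whose weights
#' are the eigenvalues of the projected weighted kernel. Genes with more
#' than `max_markers` markers are skipped.
#'
#' @param G individuals x markers allele-count matrix (MAC collapsing, if
#'   desired, is applied by the caller)
#' @param weights per-marker weights (e.g. [beta_weight()] of the MAFs)
#' @param y trait values
#' @param X covariate matrix including intercept
#' @param trait_type `"quantitative"` or `"binary"`
#' @param max_markers skip genes wider than this (default 5000)
#' @param nm optional precomputed null model
#' @return one-row tibble: `statistic`, `p`, `n_markers`, `skipped`
#' @export
skat_test <- function(G, weights, y, X, trait_type = "quantitative",
                      max_markers = 5000, nm = NULL) {
  G <- as.matrix(G)
  m <- ncol(G)
  if (m > max_markers) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_,
                          beta = NA_real_, n_markers = m, skipped = TRUE))
  }
  nm <- nm %||% null_model(y, X, trait_type)
  if (m == 0 || all(G == 0)) {
    warn("no nonzero markers; SKAT p set to 1")
    return(tibble::tibble(statistic = 0, p = 1, beta = NA_real_,
                          n_markers = m, skipped = FALSE))
  }
  GW <- sweep(G, 2, weights, `*`)
  Q <- sum(as.vector(crossprod(GW, nm$r))^2)
  B <- residualize(nm, GW)
  if (nm$type == "quantitative") {
    K <- nm$sigma2 * crossprod(B)
  } else {
    K <- crossprod(B * sqrt(nm$d))
  }
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  tibble::tibble(statistic = Q,
                 p = pvalue_chisq_mixture(Q, lambda),
                 beta = NA_real_, n_markers = m, skipped = FALSE)
}

#' Bonferroni combination of a gene's test p values
#'
#' `min(1, m * min(p))`, with `m` the number of tests that were actually
#' attempted (skipped tests contribute no p value and do not count).
#'
#' @param p vector of p values (NAs from skipped tests are dropped)
#' @param m multiplier; defaults to the number of non-missing p values
#' @return combined p value, or `NA` if no test produced a p value
#' @export
combine_gene_pvalues <- function(p, m = NULL) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  m <- m %||% length(p)
  assert_that(m >= 1, "`m` must be at least 1")
  min(1, m * min(p))
}

# the four (mask, test) combinations of the combined burden/SKAT method
mask_test_grid <- function() {
  tidyr::expand_grid(mask = c("plof", "missense"), test = c("burden", "skat"))
}

#' Gene-based burden/SKAT scan for one trait
#'
#' Runs all four (mask, test) combinations — burden and SKAT restricted to
#' pLOF or missense qualifying variants with Beta(1, 25) MAF weights — for
#' every gene passing the EAF filter, and combines the per-gene p values by
#' the Bonferroni rule.
#'
#' @param cohort an `rvat_cohort`
#' @param trait trait name (column of the phenotype table)
#' @param maf_cutoff qualifying-variant MAF cutoff (default 0.001, the
#'   association-testing convention)
#' @param cadd_cutoff qualifying-variant CADD cutoff (default 5)
#' @param eaf_threshold testability gate on expected allele frequency
#'   (default 50)
#' @param mac_threshold SKAT ultra-rare collapsing threshold (default 10)
#' @param genes optional subset of genes
#' @return tibble with one row per gene x mask x test plus combined rows
#' @export
burden_skat_scan <- function(cohort, trait, maf_cutoff = 0.001,
                             cadd_cutoff = 5, eaf_threshold = 50,
                             mac_threshold = 10, genes = NULL) {
  tr_cfg <- cohort$config$traits[[match(trait, trait_names(cohort))]]
  trait_type <- if (!is.null(tr_cfg) && tr_cfg$type == "binary") "binary"
                else "quantitative"
  qual <- suppressMessages(
    filter_qualifying_variants(cohort$variants, maf_cutoff, cadd_cutoff))
  genes <- genes %||% sort(unique(cohort$gene_models$gene_id))

  y_raw <- cohort$phenotypes[[trait]]
  ok <- !is.na(y_raw)
  y <- if (trait_type == "quantitative") quantile_transform(y_raw[ok])
       else y_raw[ok]
  X <- covariate_matrix(cohort$covariates)[ok, , drop = FALSE]
  nm <- null_model(y, X, trait_type)
  n_eff <- if (trait_type == "binary") sum(y == 1) else length(y)

  asn <- dplyr::filter(cohort$assignments, .data$variant_id %in% qual$variant_id)
  asn_split <- split(asn$variant_id, asn$gene_id)

  rows <- purrr::map_dfr(genes, function(g) {
    vids <- asn_split[[g]] %||% character()
    info <- qual[match(vids, qual$variant_id), , drop = FALSE]
    eaf <- compute_eaf(info$maf, n_eff, eaf_threshold)
    grid <- mask_test_grid()
    if (!eaf$passes) {
      return(dplyr::mutate(grid, gene_id = g, trait = trait, statistic = NA_real_,
                           p = NA_real_, n_markers = 0L, skipped = TRUE,
                           eaf = eaf$eaf, eaf_pass = FALSE))
    }
    vidx <- match(vids, cohort$genotypes$variant_id)
    Gfull <- as.matrix(cohort$genotypes$mat[ok, vidx, drop = FALSE])
    purrr::pmap_dfr(grid, function(mask, test) {
      in_mask <- if (mask == "plof") info$is_plof else info$is_missense
      res <- if (!any(in_mask)) {
        tibble::tibble(statistic = NA_real_, p = NA_real_, beta = NA_real_,
                       n_markers = 0L, skipped = TRUE)
      } else if (test == "burden") {
        Gm <- Gfull[, in_mask, drop = FALSE]
        w <- beta_weight(info$maf[in_mask])
        burden_score_test(as.vector(Gm %*% w), y, X, trait_type, nm = nm)
      } else {
        Gm <- collapse_ultra_rare(Gfull[, in_mask, drop = FALSE], mac_threshold)
        emp_maf <- pmin(colSums(Gm) / (2 * nrow(Gm)), 0.5)
        emp_maf <- pmax(emp_maf, 1 / (2 * nrow(Gm)))
        skat_test(Gm, beta_weight(emp_maf), y, X, trait_type, nm = nm)
      }
      dplyr::mutate(res, gene_id = g, trait = trait, mask = mask, test = test,
                    eaf = eaf$eaf, eaf_pass = TRUE)
    })
  })
  dplyr::select(rows, dplyr::any_of(c("gene_id", "trait", "mask", "test",
                                      "statistic", "p", "beta", "n_markers",
                                      "skipped", "eaf", "eaf_pass")))
}

#' Discover trait-specific seed genes
#'
#' Combines the four burden/SKAT p values per gene (Bonferroni over
#' attempted tests), applies Bonferroni correction across tested genes,
#' and returns genes significant at the requested family-wise error rate.
#'
#' @inheritParams burden_skat_scan
#' @param fwer family-wise error rate for seed selection (default 0.05)
#' @return tibble with one row per tested gene: combined and corrected p,
#'   `seed` flag; attribute `seed_genes` carries the significant gene ids
#' @export
discover_seed_genes <- function(cohort, trait, fwer = 0.05,
                                maf_cutoff = 0.001, cadd_cutoff = 5,
                                eaf_threshold = 50, genes = NULL) {
  scan <- burden_skat_scan(cohort, trait, maf_cutoff = maf_cutoff,
                           cadd_cutoff = cadd_cutoff,
                           eaf_threshold = eaf_threshold, genes = genes)
  per_gene <- scan |>
    dplyr::group_by(.data$gene_id, .data$trait) |>
    dplyr::summarise(p_combined = combine_gene_pvalues(.data$p),
                     eaf_pass = any(.data$eaf_pass), .groups = "drop") |>
    dplyr::filter(.data$eaf_pass, !is.na(.data$p_combined))
  m <- nrow(per_gene)
  out <- per_gene |>
    dplyr::mutate(p_corrected = pmin(1, .data$p_combined * m),
                  seed = .data$p_corrected < fwer) |>
    dplyr::arrange(.data$p_combined)
  if (m == 0) warn(sprintf("no genes passed the EAF filter for trait %s", trait))
  attr(out, "seed_genes") <- out$gene_id[out$seed]
  attr(out, "scan") <- scan
  out
}

#' Covariate model matrix (intercept + all covariate columns)
#' @param covariates covariate tibble with `individual_id`
#' @return numeric matrix
#' @export
covariate_matrix <- function(covariates) {
  cols <- setdiff(names(covariates), "individual_id")
  cbind(intercept = 1, as.matrix(covariates[, cols]))
}
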