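test_that("Beta(1,25) weights match the closed form", {
  expect_equal(beta_weight(0), 25)
  expect_equal(beta_weight(0.01), 25 * 0.99^24, tolerance = 1e-12)
  expect_equal(beta_weight(0.5), 25 * 0.5^24, tolerance = 1e-12)
  expect_equal(beta_weight(c(0, 0.01)), c(25, 25 * 0.99^24))
})

test_that("ultra-rare collapsing takes the per-individual maximum across
           collapsed variants", {
  # all MAC > threshold: identity
  G <- matrix(rbinom(60, 2, 0.5), 20, 3)
  expect_equal(collapse_ultra_rare(G, mac_threshold = 1), G,
               ignore_attr = TRUE)
  # two singletons carried by disjoint individuals -> one pseudo-marker
  # with both carriers
  G2 <- matrix(0, 10, 2)
  G2[1, 1] <- 1; G2[5, 2] <- 1
  out <- collapse_ultra_rare(G2, 10)
  expect_equal(ncol(out), 1)
  expect_equal(sum(out > 0), 2)
  # carrier of two collapsed variants with counts 1 and 2 -> value 2
  G3 <- matrix(0, 10, 2)
  G3[1, 1] <- 1; G3[1, 2] <- 2
  expect_equal(as.vector(collapse_ultra_rare(G3, 10))[1], 2)
  expect_equal(ncol(collapse_ultra_rare(matrix(0, 5, 0))), 0)
})

test_that("burden score test matches the hand-evaluated formula on a fixed
           n=6 instance", {
  y <- c(0.3, -1.2, 0.7, 2.1, -0.4, 0.05)
  g <- c(0, 1, 0, 2, 0, 1)
  X <- cbind(1, c(0.5, -0.2, 1.1, 0.3, -0.7, 0.9))
  # independent brute-force evaluation of the documented formula
  H <- X %*% solve(crossprod(X)) %*% t(X)
  r <- y - H %*% y
  s2 <- sum(r^2) / (6 - 2)
  gt <- g - H %*% g
  T_manual <- sum(gt * r)^2 / (s2 * sum(gt^2))
  res <- burden_score_test(g, y, X)
  expect_equal(res$statistic, as.vector(T_manual), tolerance = 1e-10)
  expect_equal(res$p, pchisq(T_manual, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("burden orthogonal to the residuals gives T = 0, p = 1; collinear
           burden is caught", {
  n <- 50
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  r <- qr.resid(qr(X), y)
  g_orth <- qr.resid(qr(cbind(X, r)), rnorm(n))  # orthogonal to r and X
  res <- burden_score_test(g_orth, y, X)
  expect_equal(res$statistic, 0, tolerance = 1e-16)
  expect_equal(res$p, 1)
  expect_warning(res2 <- burden_score_test(X[, 2] * 2, y, X), "collinear")
  expect_equal(res2$p, 1)
})

test_that("score statistic is invariant under affine rescaling of
           covariates", {
  set.seed(11)
  n <- 120
  X <- cbind(1, rnorm(n, 50, 8), rbinom(n, 1, 0.5))
  g <- rbinom(n, 2, 0.05)
  y <- 0.3 * g + rnorm(n)
  X2 <- cbind(1, 3 * X[, 2] - 100, 5 * X[, 3] + 2)
  expect_equal(burden_score_test(g, y, X)$statistic,
               burden_score_test(g, y, X2)$statistic, tolerance = 1e-10)
})

test_that("burden p value agrees with a permutation oracle", {
  set.seed(21)
  n <- 200
  X <- cbind(1, rnorm(n))
  g <- rbinom(n, 2, 0.08)
  y <- 0.25 * g + 0.3 * X[, 2] + rnorm(n)
  p_score <- burden_score_test(g, y, X)$p
  # permutation of the null residuals against the residualized burden
  qrX <- qr(X)
  r <- qr.resid(qrX, y)
  gt <- qr.resid(qrX, g)
  n_perm <- 20000
  obs <- abs(sum(gt * r))
  perm <- replicate(n_perm, abs(sum(gt * sample(r))))
  p_perm <- (1 + sum(perm >= obs)) / (n_perm + 1)
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_score - p_perm), 3 * se + 1e-12)
})

test_that("SKAT on a single marker equals the burden test; wide genes are
           skipped; Q is order-invariant", {
  set.seed(31)
  n <- 150
  X <- cbind(1, rnorm(n))
  g <- rbinom(n, 2, 0.1)
  y <- 0.3 * g + rnorm(n)
  w <- beta_weight(0.1)
  p_skat <- skat_test(matrix(g, ncol = 1), w, y, X)$p
  p_burden <- burden_score_test(g * w, y, X)$p
  expect_equal(p_skat, p_burden, tolerance = 1e-6)

  wide <- matrix(0, 4, 5001)
  res <- skat_test(wide, rep(1, 5001), rnorm(4), matrix(1, 4, 1))
  expect_true(res$skipped)
  expect_true(is.na(res$p))

  G <- matrix(rbinom(n * 5, 2, 0.05), n, 5)
  w5 <- beta_weight(rep(0.05, 5))
  perm_cols <- c(3, 1, 5, 2, 4)
  expect_equal(skat_test(G, w5, y, X)$statistic,
               skat_test(G[, perm_cols], w5[perm_cols], y, X)$statistic)
})

test_that("SKAT p value agrees with a permutation oracle", {
  set.seed(41)
  n <- 200
  X <- cbind(1, rnorm(n))
  G <- matrix(rbinom(n * 5, 2, 0.07), n, 5)
  w <- beta_weight(colSums(G) / (2 * n))
  y <- 0.2 * G[, 1] - 0.25 * G[, 3] + rnorm(n)
  p_skat <- skat_test(G, w, y, X)$p
  qrX <- qr(X)
  r0 <- qr.resid(qrX, y)
  GW <- sweep(G, 2, w, `*`)
  qstat <- function(rr) sum(as.vector(crossprod(GW, rr))^2)
  obs <- qstat(r0)
  n_perm <- 5000
  perm <- replicate(n_perm, qstat(sample(r0)))
  p_perm <- (1 + sum(perm >= obs)) / (n_perm + 1)
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_skat - p_perm), 3 * se + 1e-12)
})

test_that("chi-square mixture tail is exact for a single component and sane
           for several", {
  q <- 7.3
  expect_equal(pvalue_chisq_mixture(q, 1), pchisq(q, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(pvalue_chisq_mixture(3 * q, 3),
               pchisq(q, 1, lower.tail = FALSE), tolerance = 1e-6)
  # equal weights: sum of m chi-squares
  expect_equal(pvalue_chisq_mixture(12, rep(1, 5)),
               pchisq(12, 5, lower.tail = FALSE), tolerance = 1e-4)
  # Monte-Carlo check for unequal weights
  lam <- c(3, 1.2, 0.4, 0.1)
  set.seed(51)
  draws <- colSums(lam * matrix(rchisq(4 * 200000, 1), 4))
  q2 <- quantile(draws, 0.99, names = FALSE)
  expect_equal(pvalue_chisq_mixture(q2, lam), 0.01, tolerance = 0.15)
})

test_that("per-gene Bonferroni combination takes min(1, m * min p) over
           attempted tests", {
  expect_equal(combine_gene_pvalues(c(0.01, 0.02, 0.03, 0.04)), 0.04)
  expect_equal(combine_gene_pvalues(c(0.5, 0.6, 0.9, 0.95)), 1)
  expect_equal(combine_gene_pvalues(0.2), 0.2)
  # skipped tests (NA) do not inflate the multiplier
  expect_equal(combine_gene_pvalues(c(0.01, NA, NA, 0.02)), 0.02)
  expect_true(is.na(combine_gene_pvalues(c(NA_real_, NA_real_))))
})

test_that("burden and SKAT p values are uniform under the null", {
  set.seed(61)
  n <- 300
  X <- cbind(1, rnorm(n))
  nm <- NULL
  y <- rnorm(n)
  p_b <- p_s <- numeric(400)
  for (i in 1:400) {
    G <- matrix(rbinom(n * 4, 2, runif(4, 0.02, 0.1)), n, 4)
    w <- beta_weight(colSums(G) / (2 * n))
    p_b[i] <- burden_score_test(as.vector(G %*% w), y, X)$p
    p_s[i] <- skat_test(G, w, y, X)$p
  }
  expect_gt(suppressWarnings(ks.test(p_b, "punif")$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(p_s, "punif")$p.value), 0.01)
})

test_that("seed-gene discovery recovers strong genes and respects mask
           structure", {
  co <- small_cohort()
  res <- suppressWarnings(suppressMessages(
    discover_seed_genes(co, "q1", maf_cutoff = 0.01, eaf_threshold = 1)))
  truth <- co$truth$seed_genes$q1
  # the strongest signals should be the true seed genes
  top3 <- res$gene_id[1:3]
  expect_gte(length(intersect(top3, truth)), 2)
  scan <- attr(res, "scan")
  expect_setequal(unique(paste(scan$mask, scan$test)),
                  c("plof burden", "plof skat", "missense burden",
                    "missense skat"))
})

test_that("logistic burden score test is calibrated under the null", {
  set.seed(71)
  n <- 500
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, 0.3)
  p <- replicate(300, {
    g <- rbinom(n, 2, 0.05)
    burden_score_test(g, y, X, trait_type = "binary")$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})
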