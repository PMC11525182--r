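# Rare-variant-augmented phenotype prediction: PRS-only baseline,
# PRS + impairment-score and PRS + single-annotation-burden models, with
# relative-improvement and extreme-phenotype enrichment metrics.

#' Simulate a common-variant polygenic score
#'
#' A stand-in for an external PRS catalogue: a score correlated with the
#' trait at a configured R^2 (plus independent noise), used to study how
#' much rare-variant gene scores add on top of common-variant prediction.
#'
#' @param y trait values
#' @param r2 squared correlation between PRS and trait, in `[0, 1)`
#' @param seed integer seed
#' @return numeric PRS vector
#' @export
simulate_prs <- function(y, r2, seed = 1L) {
  assert_that(r2 >= 0 && r2 < 1, "`r2` must lie in [0, 1)")
  withr::local_seed(derive_seed(seed, "prs"))
  z <- as.vector(scale(y))
  sqrt(r2) * z + sqrt(1 - r2) * rnorm(length(y))
}

#' Per-gene single-annotation burden scores
#'
#' The comparator to learned impairment scores: for each gene, the maximum
#' of one annotation over the individual's qualifying variants (or the
#' minimum, for annotations where lower means more damaging). Non-carriers
#' get 0.
#'
#' @param cohort an `rvat_cohort`
#' @param annotation annotation column name
#' @param genes genes to score (default: all)
#' @param maf_cutoff,cadd_cutoff qualifying-variant filters
#' @param worst `"max"` (default) or `"min"`
#' @return individuals x genes matrix
#' @export
alternative_burden <- function(cohort, annotation, genes = NULL,
                               maf_cutoff = 0.001, cadd_cutoff = 5,
                               worst = c("max", "min")) {
  worst <- match.arg(worst)
  genes <- genes %||% sort(unique(cohort$gene_models$gene_id))
  assert_that(annotation %in% names(cohort$variants),
              "unknown annotation column")
  qual <- suppressMessages(
    filter_qualifying_variants(cohort$variants, maf_cutoff, cadd_cutoff))
  carry <- build_variant_sets(cohort$genotypes, cohort$assignments,
                              qual$variant_id, genes = genes)
  ids <- cohort$genotypes$individual_id
  out <- matrix(0, length(ids), length(genes), dimnames = list(ids, genes))
  if (nrow(carry) == 0) return(out)
  dt <- data.table::data.table(
    i = match(carry$individual_id, ids),
    j = match(carry$gene_id, genes),
    a = qual[[annotation]][match(carry$variant_id, qual$variant_id)])
  agg <- if (worst == "max") dt[, .(a = max(a)), by = .(i, j)]
         else dt[, .(a = min(a)), by = .(i, j)]
  out[cbind(agg$i, agg$j)] <- agg$a
  out
}

#' Fit a phenotype predictor
#'
#' Ordinary least squares (quantitative targets) or maximum-likelihood
#' logistic regression (binary extreme-percentile targets) of the target
#' on covariates, the common-variant PRS, and optionally per-gene rare
#' variant scores. An empty gene set reduces the model exactly to the
#' PRS-only baseline.
#'
#' @param data data frame holding the response, covariates, PRS and gene
#'   feature columns (training individuals only; gene sets must have been
#'   discovered on training individuals)
#' @param response response column name
#' @param covariate_cols covariate column names
#' @param prs_col PRS column name (NULL for a covariate-only model)
#' @param gene_cols gene feature column names (may be empty)
#' @param kind `"linear"` or `"logistic"`
#' @return object of class `phenotype_predictor`
#' @export
fit_phenotype_predictor <- function(data, response, covariate_cols,
                                    prs_col = NULL, gene_cols = character(),
                                    kind = c("linear", "logistic")) {
  kind <- match.arg(kind)
  feats <- c(covariate_cols, prs_col, gene_cols)
  fml <- stats::reformulate(sprintf("`%s`", feats), response = sprintf("`%s`", response))
  separation <- FALSE
  if (kind == "linear") {
    model <- lm(fml, data = data)
  } else {
    model <- withCallingHandlers(
      glm(fml, data = data, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (separation) warn("possible perfect separation in logistic fit; model flagged")
  }
  structure(list(model = model, kind = kind, response = response,
                 covariate_cols = covariate_cols, prs_col = prs_col,
                 gene_cols = gene_cols, separation_flag = separation),
            class = "phenotype_predictor")
}

#' @export
print.phenotype_predictor <- function(x, ...) {
  cat(sprintf("<phenotype_predictor> %s: %s ~ %d covariates%s + %d gene(s)%s\n",
              x$kind, x$response, length(x$covariate_cols),
              if (!is.null(x$prs_col)) " + PRS" else "",
              length(x$gene_cols),
              if (x$separation_flag) " [separation flagged]" else ""))
  invisible(x)
}

#' Predict from a phenotype predictor
#' @param object a `phenotype_predictor`
#' @param newdata data frame with the model's feature columns
#' @param ... unused
#' @return numeric predictions (response scale for logistic)
#' @export
predict.phenotype_predictor <- function(object, newdata, ...) {
  as.vector(stats::predict(object$model, newdata = newdata,
                           type = "response"))
}

#' Coefficient of determination on held-out data
#' @param obs observed values
#' @param pred predictions
#' @return `1 - SSE / SST`
#' @export
r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Area under the precision-recall curve
#'
#' Step interpolation (precision as a step function of recall, i.e.
#' average precision): the mean over positives, ranked by decreasing
#' score, of the precision at each positive's rank.
#'
#' @param labels binary labels (0/1)
#' @param scores ranking scores (higher = more positive)
#' @return AUPRC in `[0, 1]`
#' @export
auprc <- function(labels, scores) {
  assert_that(length(labels) == length(scores), "length mismatch")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  n_pos <- sum(lab)
  if (n_pos == 0) return(NA_real_)
  prec_at <- cumsum(lab) / seq_along(lab)
  sum(prec_at[lab == 1]) / n_pos
}

#' Relative improvement of a rare-variant-augmented model
#'
#' `(M_rare - M_prs_only) / M_prs_only`, where `M` is R^2 for linear
#' models or AUPRC for logistic extreme-value models. Negative values pass
#' through unclipped.
#'
#' @param m_rare metric of the rare-augmented model
#' @param m_prs_only metric of the PRS-only baseline (nonzero)
#' @return relative improvement (NA with a warning when the baseline
#'   metric is 0)
#' @export
relative_improvement <- function(m_rare, m_prs_only) {
  if (m_prs_only == 0) {
    warn("baseline metric is 0; relative improvement undefined")
    return(NA_real_)
  }
  (m_rare - m_prs_only) / m_prs_only
}

#' Binary labels for phenotypic extremes
#'
#' Marks the individuals in the top or bottom `percentile` of the
#' empirical phenotype distribution (rank-based, ties broken by first
#' occurrence, so any monotone transform of `y` gives identical labels).
#'
#' @param y phenotype values (non-constant)
#' @param tail `"top"` or `"bottom"`
#' @param percentile tail size in percent, in (0, 50)
#' @return integer vector of 0/1 labels
#' @export
extreme_phenotype_labels <- function(y, tail = c("top", "bottom"),
                                     percentile = 1) {
  tail <- match.arg(tail)
  if (percentile <= 0 || percentile >= 50) {
    abort("`percentile` must lie strictly between 0 and 50")
  }
  if (length(unique(y)) < 2) abort("constant phenotype has no extremes")
  n <- length(y)
  k <- max(1L, round(n * percentile / 100))
  r <- if (tail == "bottom") rank(y, ties.method = "first")
       else rank(-y, ties.method = "first")
  as.integer(r <= k)
}

#' Extreme-phenotype enrichment by prediction deviation
#'
#' Ranks held-out individuals by the absolute difference between the
#' rare-augmented and PRS-only predictions (descending) and accumulates
#' the count of extreme-phenotype individuals along the ranking, against
#' the random baseline (prevalence x rank) and the perfect-ranking
#' diagonal.
#'
#' @param pred_prs,pred_rare predictions of the two models on the same
#'   held-out individuals
#' @param labels extreme-phenotype labels from
#'   [extreme_phenotype_labels()]
#' @return tibble of class `enrichment_curve`: `rank`, `cumulative`,
#'   `baseline`, `perfect`
#' @export
enrichment_by_deviation <- function(pred_prs, pred_rare, labels) {
  if (length(pred_prs) != length(pred_rare) ||
      length(pred_prs) != length(labels)) {
    abort("predictions and labels must have equal length")
  }
  dev <- abs(pred_rare - pred_prs)
  ord <- order(dev, decreasing = TRUE)
  lab <- labels[ord]
  n <- length(lab)
  n_pos <- sum(lab)
  out <- tibble::tibble(
    rank = seq_len(n),
    cumulative = cumsum(lab),
    baseline = seq_len(n) * n_pos / n,
    perfect = pmin(seq_len(n), n_pos))
  class(out) <- c("enrichment_curve", class(out))
  attr(out, "area_above_baseline") <-
    mean(out$cumulative - out$baseline) / max(n_pos, 1)
  out
}

#' Bootstrap test that a deviation-enrichment curve beats random ranking
#'
#' Resamples individuals with replacement and recomputes the normalized
#' area between the cumulative-enrichment curve and the random baseline;
#' the p value is the bootstrap fraction of areas at or below 0.
#'
#' @inheritParams enrichment_by_deviation
#' @param n_boot bootstrap replicates (default 500)
#' @param seed integer seed
#' @return list: `area`, `p_value`
#' @export
enrichment_bootstrap_test <- function(pred_prs, pred_rare, labels,
                                      n_boot = 500, seed = 1L) {
  withr::local_seed(derive_seed(seed, "enrichboot"))
  n <- length(labels)
  base_area <- attr(enrichment_by_deviation(pred_prs, pred_rare, labels),
                    "area_above_baseline")
  areas <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    attr(enrichment_by_deviation(pred_prs[idx], pred_rare[idx], labels[idx]),
         "area_above_baseline")
  }, 0)
  list(area = base_area, p_value = mean(areas <= 0))
}

#' Enrichment of extreme predictions among phenotypic outliers
#'
#' For each phenotype z-score cutoff: among individuals with `y >= z`, the
#' proportion whose prediction exceeds the prediction's own 99% quantile,
#' scaled by the same proportion in the whole population (the `z = 0`
#' stratum includes everyone at or above the mean). At `z = 0` of a
#' symmetric phenotype this is close to 1 by construction of the scaling.
#'
#' @param pred predictions on held-out individuals
#' @param y phenotype (quantile-transformed / z-scaled)
#' @param z_cutoffs vector of cutoffs (0 is always included as the
#'   reference)
#' @param pred_quantile prediction quantile defining "extreme prediction"
#'   (default 0.99)
#' @return tibble: `z`, `n_stratum`, `proportion`, `enrichment`
#' @export
zscore_enrichment <- function(pred, y, z_cutoffs = c(0, 0.5, 1, 1.5, 2),
                              pred_quantile = 0.99) {
  z_cutoffs <- sort(unique(c(0, z_cutoffs)))
  thr <- quantile(pred, pred_quantile, names = FALSE)
  ref <- mean(pred[y >= 0] > thr)
  purrr::map_dfr(z_cutoffs, function(z) {
    idx <- y >= z
    if (!any(idx)) {
      return(tibble::tibble(z = z, n_stratum = 0L, proportion = NA_real_,
                            enrichment = NA_real_))
    }
    pr <- mean(pred[idx] > thr)
    tibble::tibble(z = z, n_stratum = sum(idx), proportion = pr,
                   enrichment = if (ref > 0) pr / ref else NA_real_)
  })
}
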