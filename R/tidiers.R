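# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @export
tidy.rvat_assoc <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.rvat_assoc <- function(x, fwer = 0.05, ...) {
  p <- x$p[!is.na(x$p)]
  tibble::tibble(
    n_genes = nrow(x),
    n_tested = attr(x, "m_tested") %||% length(p),
    n_significant = sum(x$p_corrected < fwer, na.rm = TRUE),
    lambda = if (length(p) >= 2) genomic_inflation(p)$lambda else NA_real_)
}

#' @export
tidy.impairment_fit <- function(x, ...) {
  purrr::map_dfr(x$traits, function(p) {
    hp <- x$heads[[p]]
    dplyr::bind_rows(
      tibble::tibble(trait = p, term = paste0("covariate_",
                                              seq_along(hp$alpha) - 1L),
                     estimate = hp$alpha, type = "covariate"),
      tibble::tibble(trait = p, term = x$seed_genes[[p]],
                     estimate = hp$w, type = "seed_gene"))
  })
}

#' @export
glance.impairment_fit <- function(x, ...) {
  tibble::tibble(
    n_traits = length(x$traits),
    n_seed_genes = length(unique(unlist(x$seed_genes))),
    epochs_run = if (is.null(x$log)) NA_integer_ else max(x$log$epoch),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss %||% NA_real_)
}

#' @export
tidy.phenotype_predictor <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.phenotype_predictor <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = length(resid(x$model)),
                 n_genes = length(x$gene_cols),
                 separation_flag = x$separation_flag,
                 r_squared = if (x$kind == "linear")
                   summary(x$model)$r.squared else NA_real_)
}

#' Q-Q plot of association p values
#' @param object an `rvat_assoc` table or `rvat_qq` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.rvat_assoc <- function(object, ...) {
  qq <- genomic_inflation(object$p[!is.na(object$p)])$qq
  autoplot.rvat_qq(qq, ...)
}

#' @rdname autoplot.rvat_assoc
#' @export
autoplot.rvat_qq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Training/validation loss trajectory
#' @param object an `impairment_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.impairment_fit <- function(object, ...) {
  if (is.null(object$log)) abort("this fit carries no training log")
  long <- tidyr::pivot_longer(object$log, -"epoch", names_to = "set",
                              values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "epoch", y = "multitask MSE") +
    ggplot2::theme_minimal()
}

#' Cumulative extreme-phenotype enrichment curve
#' @param object an `enrichment_curve`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.enrichment_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$perfect), linetype = 3,
                       colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), linetype = 2,
                       colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "#2166ac") +
    ggplot2::labs(x = "individuals ranked by |prediction deviation|",
                  y = "cumulative extreme-phenotype count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
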