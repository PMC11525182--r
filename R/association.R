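# Gene-trait association testing on impairment scores, Bonferroni
# correction, conditional analysis, pseudodosage export and calibration
# diagnostics.

#' Score test of a gene's impairment score against a trait
#'
#' The per-individual impairment score is treated as the gene's burden and
#' tested with the covariate-adjusted score test (linear null for
#' quantitative traits, logistic null for binary traits — the latter is
#' flagged because naive score tests are poorly calibrated for imbalanced
#' binary traits; prefer pseudodosage export to a Firth-penalized external
#' tester there).
#'
#' @param psi per-individual impairment scores for one gene
#' @param y trait values (quantile-transformed if quantitative)
#' @param X covariate matrix including intercept
#' @param trait_type `"quantitative"` or `"binary"`
#' @param nm optional precomputed null model
#' @return one-row tibble (`statistic`, `p`, `beta`, ...)
#' @export
impairment_association_test <- function(psi, y, X,
                                        trait_type = "quantitative",
                                        nm = NULL) {
  if (trait_type == "binary") {
    warn(paste0("logistic score test on binary traits can be poorly ",
                "calibrated for rare outcomes; consider pseudodosage ",
                "export to a Firth-based tester"),
         .frequency = "once", .frequency_id = "rvatnet_binary_assoc")
  }
  if (sd(psi) == 0) {
    warn("impairment score is constant across individuals; p set to 1")
    return(tibble::tibble(statistic = 0, p = 1, beta = NA_real_,
                          n_markers = 1L, skipped = FALSE))
  }
  burden_score_test(psi, y, X, trait_type, nm = nm)
}

#' Bonferroni correction across tested genes
#'
#' @param results tibble with a `p` column
#' @param m number of tested genes (default: number of non-missing p
#'   values)
#' @return `results` with a `p_corrected = min(1, m * p)` column
#' @export
bonferroni_correct <- function(results, m = NULL) {
  m <- m %||% sum(!is.na(results$p))
  assert_that(m >= 1, "`m` must be at least 1")
  dplyr::mutate(results, p_corrected = pmin(1, .data$p * m))
}

#' Gene-trait association scan over an impairment score matrix
#'
#' Applies the EAF testability gate per gene (cohort size for quantitative
#' traits, case count for binary), runs the score test for each passing
#' gene, and Bonferroni-corrects across the genes actually tested for this
#' trait.
#'
#' @param scores individuals x genes impairment score matrix (out-of-fold
#'   or external-ensemble scores)
#' @param cohort an `rvat_cohort`
#' @param trait trait name
#' @param maf_cutoff,cadd_cutoff qualifying-variant filters defining the
#'   EAF gate (association conventions by default)
#' @param eaf_threshold EAF testability threshold (default 50)
#' @return tibble of class `rvat_assoc`, one row per gene
#' @export
association_scan <- function(scores, cohort, trait, maf_cutoff = 0.001,
                             cadd_cutoff = 5, eaf_threshold = 50) {
  tr_cfg <- cohort$config$traits[[match(trait, trait_names(cohort))]]
  trait_type <- if (!is.null(tr_cfg) && tr_cfg$type == "binary") "binary"
                else "quantitative"
  y_raw <- cohort$phenotypes[[trait]]
  ok <- which(!is.na(y_raw))
  y <- if (trait_type == "quantitative") quantile_transform(y_raw[ok])
       else y_raw[ok]
  X <- covariate_matrix(cohort$covariates)[ok, , drop = FALSE]
  nm <- null_model(y, X, trait_type)
  n_eff <- if (trait_type == "binary") sum(y == 1) else length(y)

  qual <- suppressMessages(
    filter_qualifying_variants(cohort$variants, maf_cutoff, cadd_cutoff))
  asn <- dplyr::filter(cohort$assignments,
                       .data$variant_id %in% qual$variant_id)
  maf_by_gene <- split(qual$maf[match(asn$variant_id, qual$variant_id)],
                       asn$gene_id)

  genes <- colnames(scores)
  rows <- purrr::map_dfr(genes, function(g) {
    eaf <- compute_eaf(maf_by_gene[[g]] %||% numeric(), n_eff, eaf_threshold)
    if (!eaf$passes) {
      return(tibble::tibble(gene_id = g, trait = trait, statistic = NA_real_,
                            p = NA_real_, beta = NA_real_,
                            eaf = eaf$eaf, eaf_pass = FALSE))
    }
    res <- suppressWarnings(
      impairment_association_test(scores[ok, g], y, X, trait_type, nm = nm))
    tibble::tibble(gene_id = g, trait = trait, statistic = res$statistic,
                   p = res$p, beta = res$beta, eaf = eaf$eaf,
                   eaf_pass = TRUE)
  })
  m <- sum(rows$eaf_pass)
  out <- bonferroni_correct(rows, m = max(m, 1))
  out$p_corrected[!out$eaf_pass] <- NA_real_
  class(out) <- c("rvat_assoc", class(out))
  attr(out, "m_tested") <- m
  attr(out, "trait_type") <- trait_type
  out
}

#' Conditional association test
#'
#' Re-runs the score test with caller-supplied conditioning dosage columns
#' (e.g. independently associated common variants near the gene) appended
#' to the covariates. Conditioning columns collinear with the existing
#' covariates are dropped with a warning. An empty conditioning set
#' reproduces the unconditional p value.
#'
#' @param psi per-individual impairment scores for the gene
#' @param conditioning numeric matrix of conditioning dosages (0 columns
#'   allowed)
#' @param y trait values
#' @param X covariate matrix including intercept
#' @param trait_type `"quantitative"` or `"binary"`
#' @return one-row tibble with `p_conditional` alongside the unconditional
#'   `p`
#' @export
conditional_association_test <- function(psi, conditioning, y, X,
                                         trait_type = "quantitative") {
  uncond <- suppressWarnings(
    impairment_association_test(psi, y, X, trait_type))
  Z <- as.matrix(conditioning)
  if (ncol(Z) > 0) {
    keep <- logical(ncol(Z))
    Xa <- X
    for (j in seq_len(ncol(Z))) {
      cand <- cbind(Xa, Z[, j])
      if (qr(cand)$rank > qr(Xa)$rank) {
        Xa <- cand
        keep[j] <- TRUE
      }
    }
    if (!all(keep)) {
      warn(sprintf("dropped %d collinear conditioning column(s)",
                   sum(!keep)))
    }
  } else {
    Xa <- X
  }
  cond <- suppressWarnings(
    impairment_association_test(psi, y, Xa, trait_type))
  dplyr::mutate(uncond, p_conditional = cond$p,
                n_conditioning = if (ncol(Z) > 0) sum(keep) else 0L)
}

#' Genomic inflation factor and Q-Q table
#'
#' `lambda` is the median of the 1-df chi-square quantiles of the observed
#' p values divided by the null median; the Q-Q table pairs expected and
#' observed `-log10(p)`.
#'
#' @param p vector of p values (>= 100 recommended)
#' @return list: `lambda`, `qq` tibble (class `rvat_qq`)
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  if (length(p) < 2) abort("need at least 2 p values")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chi) / qchisq(0.5, df = 1)
  n <- length(p)
  qq <- tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p)))
  class(qq) <- c("rvat_qq", class(qq))
  list(lambda = lambda, qq = qq)
}

# ---- pseudodosage export -------------------------------------------------

#' Export impairment scores as pseudovariant dosages
#'
#' Converts the individuals x genes score matrix into one pseudovariant
#' per gene with genotype probabilities `(psi, 0, 1 - psi)` for
#' (hom-alt, het, hom-ref), i.e. dosage `d = 2 * psi` in `[0, 2]`, so any
#' single-marker association tool can test gene scores. Formats: a TSV
#' dosage dialect (`individual_id`, `gene_id`, `dosage`) and a minimal
#' BGEN v1.2 file (layout 2, zlib-compressed, 16-bit probabilities).
#'
#' @param scores individuals x genes matrix with values in `[0, 1]`
#' @param path output file
#' @param format `"tsv"` or `"bgen"`
#' @return `path`, invisibly
#' @export
export_pseudodosage <- function(scores, path, format = c("tsv", "bgen")) {
  format <- match.arg(format)
  if (any(scores < 0 | scores > 1)) {
    abort("impairment scores must lie in [0, 1] for pseudodosage export")
  }
  if (format == "tsv") {
    long <- tibble::tibble(
      individual_id = rep(rownames(scores), times = ncol(scores)),
      gene_id = rep(colnames(scores), each = nrow(scores)),
      dosage = as.vector(2 * scores))
    readr::write_tsv(dplyr::mutate(long, dosage = sprintf("%.17g", .data$dosage)),
                     path)
  } else {
    write_bgen_pseudodosage(scores, path)
  }
  invisible(path)
}

#' Read pseudodosages back into a score matrix
#' @param path file written by [export_pseudodosage()]
#' @param format `"tsv"` or `"bgen"`
#' @return individuals x genes matrix of scores (`dosage / 2`)
#' @export
read_pseudodosage <- function(path, format = c("tsv", "bgen")) {
  format <- match.arg(format)
  if (format == "tsv") {
    long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    wide <- tidyr::pivot_wider(long, names_from = "gene_id",
                               values_from = "dosage")
    mat <- as.matrix(wide[, -1]) / 2
    rownames(mat) <- wide$individual_id
    mat
  } else {
    read_bgen_pseudodosage(path)
  }
}

# Minimal BGEN v1.2 writer: layout 2, zlib compression, 16-bit
# probabilities, one biallelic pseudovariant per gene, unphased diploid.
write_bgen_pseudodosage <- function(scores, path) {
  n <- nrow(scores); m <- ncol(scores)
  con <- file(path, "wb")
  on.exit(close(con))
  wr_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wr_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr_raw <- function(x) writeBin(x, con)

  sample_block <- local({
    ids <- rownames(scores)
    parts <- lapply(ids, function(s) {
      c(writeBin(as.integer(nchar(s)), raw(), size = 2, endian = "little"),
        charToRaw(s))
    })
    body <- do.call(c, parts)
    c(writeBin(as.integer(8 + length(body)), raw(), size = 4, endian = "little"),
      writeBin(as.integer(n), raw(), size = 4, endian = "little"),
      body)
  })
  header_len <- 20L
  offset <- header_len + length(sample_block)
  wr_u32(offset)
  wr_u32(header_len)
  wr_u32(m)
  wr_u32(n)
  wr_raw(charToRaw("bgen"))
  # flags: zlib (bits 0-1 = 1), layout 2 (bits 2-5 = 2), sample ids (bit 31)
  flags <- 1L + bitwShiftL(2L, 2) - .Machine$integer.max - 1L  # bit 31 set
  wr_u32(flags)
  wr_raw(sample_block)

  two16 <- 65535
  for (j in seq_len(m)) {
    gid <- colnames(scores)[j]
    wr_u16(nchar(gid)); wr_raw(charToRaw(gid))          # variant id
    wr_u16(nchar(gid)); wr_raw(charToRaw(gid))          # rsid
    wr_u16(2L); wr_raw(charToRaw("PS"))                 # chromosome
    wr_u32(j)                                           # position
    wr_u16(2L)                                          # K = 2 alleles
    wr_u32(1L); wr_raw(charToRaw("A"))
    wr_u32(1L); wr_raw(charToRaw("G"))

    psi <- scores[, j]
    p_homref <- round((1 - psi) * two16)
    p_het <- 0L
    probs <- rbind(p_homref, p_het)  # stored genotypes: hom-ref, het
    unc <- c(
      writeBin(as.integer(n), raw(), size = 4, endian = "little"),
      writeBin(2L, raw(), size = 2, endian = "little"),   # K
      as.raw(2), as.raw(2),                               # Pmin, Pmax ploidy
      as.raw(rep(2, n)),                                  # per-sample ploidy
      as.raw(0),                                          # unphased
      as.raw(16),                                         # 16-bit probs
      writeBin(as.integer(probs), raw(), size = 2, endian = "little"))
    comp <- memCompress(unc, type = "gzip")
    wr_u32(length(comp) + 4L)
    wr_u32(length(unc))
    wr_raw(comp)
  }
  invisible(path)
}

read_bgen_pseudodosage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_u32 <- function() readBin(con, "integer", 1, size = 4, endian = "little")
  rd_u16 <- function() readBin(con, "integer", 1, size = 2, endian = "little",
                               signed = FALSE)
  offset <- rd_u32()
  header_len <- rd_u32()
  m <- rd_u32(); n <- rd_u32()
  magic <- readChar(con, 4)
  if (!identical(magic, "bgen")) abort("not a BGEN file")
  invisible(rd_u32())  # flags (this reader only supports what the writer emits)
  lsi <- rd_u32(); stopifnot(rd_u32() == n)
  ids <- vapply(seq_len(n), function(i) readChar(con, rd_u16()), "")

  out <- matrix(NA_real_, n, m, dimnames = list(ids, NULL))
  genes <- character(m)
  for (j in seq_len(m)) {
    genes[j] <- readChar(con, rd_u16())
    invisible(readChar(con, rd_u16()))  # rsid
    invisible(readChar(con, rd_u16()))  # chrom
    invisible(rd_u32())                 # position
    k <- rd_u16()
    for (a in seq_len(k)) invisible(readChar(con, rd_u32()))
    clen <- rd_u32(); dlen <- rd_u32()
    comp <- readBin(con, "raw", clen - 4L)
    unc <- memDecompress(comp, type = "gzip")
    # skip N(4), K(2), Pmin/Pmax(2), ploidy(n), phased(1); read B(1)
    bbits <- as.integer(unc[4 + 2 + 2 + n + 1 + 1])
    stopifnot(bbits == 16)
    body <- unc[-(seq_len(4 + 2 + 2 + n + 2))]
    vals <- readBin(body, "integer", 2 * n, size = 2, endian = "little",
                    signed = FALSE)
    p_homref <- vals[seq(1, 2 * n, by = 2)] / 65535
    p_het <- vals[seq(2, 2 * n, by = 2)] / 65535
    out[, j] <- 1 - p_homref - p_het + p_het / 2  # psi = P(homalt) + P(het)/2
  }
  colnames(out) <- genes
  out
}
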