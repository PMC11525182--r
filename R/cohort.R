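#' Assign variants to genes by exon proximity
#'
#' A variant belongs to a gene if it lies inside one of the gene's exons or
#' within `window` base pairs of an exon boundary (1-based, closed
#' coordinates). A variant may be assigned to several genes; downstream
#' modules include it in every assigned gene.
#'
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`
#' @param gene_models data frame with one row per exon: `gene_id`, `chrom`,
#'   `exon_start`, `exon_end` (1-based, closed)
#' @param window maximum distance in base pairs from an exon (default 300)
#' @return tibble with columns `variant_id`, `gene_id`, `distance` (0 for
#'   exonic variants), one row per (variant, gene) assignment
#' @export
assign_variants_to_genes <- function(variants, gene_models, window = 300) {
  assert_that(all(c("variant_id", "chrom", "pos") %in% names(variants)),
              "`variants` needs columns variant_id, chrom, pos")
  assert_that(all(c("gene_id", "chrom", "exon_start", "exon_end") %in%
                    names(gene_models)),
              "`gene_models` needs columns gene_id, chrom, exon_start, exon_end")
  if (any(gene_models$exon_start > gene_models$exon_end)) {
    abort("malformed exon interval: start > end")
  }

  vdt <- data.table::data.table(
    chrom = as.character(variants$chrom),
    start = as.integer(variants$pos) - as.integer(window),
    end = as.integer(variants$pos) + as.integer(window),
    pos = as.integer(variants$pos),
    variant_id = variants$variant_id
  )
  edt <- data.table::data.table(
    chrom = as.character(gene_models$chrom),
    start = as.integer(gene_models$exon_start),
    end = as.integer(gene_models$exon_end),
    gene_id = gene_models$gene_id
  )
  data.table::setkey(edt, chrom, start, end)
  hits <- data.table::foverlaps(vdt, edt, type = "any", nomatch = NULL)
  if (nrow(hits) == 0) {
    return(tibble::tibble(variant_id = character(), gene_id = character(),
                          distance = integer()))
  }
  hits[, distance := pmax(0L, pmax(start - pos, pos - end))]
  out <- hits[, .(distance = min(distance)), by = .(variant_id, gene_id)]
  out <- out[distance <= window]
  tibble::as_tibble(out[order(variant_id, gene_id)])
}

#' Transform a minor allele frequency for use as a model annotation
#'
#' Maps an allele frequency `p` to `1 / sqrt(p * (1 - p))`, a strictly
#' decreasing function of `p` on (0, 0.5] that up-weights rarer variants.
#'
#' @param p allele frequency vector, all values strictly inside (0, 1)
#' @return transformed values
#' @examples
#' transform_maf(0.5)   # 2
#' transform_maf(0.001) # ~31.64
#' @export
transform_maf <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("allele frequencies must lie strictly inside (0, 1)")
  }
  (p * (1 - p))^(-0.5)
}

#' Filter to qualifying rare variants
#'
#' Keeps variants with MAF strictly below `maf_cutoff` and PHRED-scaled CADD
#' strictly above `cadd_cutoff`. The conventional cutoffs are MAF < 0.1% for
#' association testing and MAF < 1% for impairment-model training, with
#' CADD > 5 in both cases.
#'
#' @param variants data frame with columns `maf` and `cadd_phred`
#' @param maf_cutoff exclusive MAF upper bound, in (0, 1)
#' @param cadd_cutoff exclusive CADD lower bound (default 5)
#' @return the qualifying subset, same columns
#' @export
filter_qualifying_variants <- function(variants, maf_cutoff, cadd_cutoff = 5) {
  assert_that(is.numeric(maf_cutoff) && maf_cutoff > 0 && maf_cutoff < 1,
              "`maf_cutoff` must lie in (0, 1)")
  assert_that(is.numeric(cadd_cutoff) && cadd_cutoff >= 0,
              "`cadd_cutoff` must be non-negative")
  kept <- dplyr::filter(variants, .data$maf < maf_cutoff,
                        .data$cadd_phred > cadd_cutoff)
  inform(sprintf("qualifying variants: kept %d of %d (MAF < %g, CADD > %g)",
                 nrow(kept), nrow(variants), maf_cutoff, cadd_cutoff))
  kept
}

#' Rank-based inverse-normal transform of a phenotype
#'
#' Replaces non-missing values by standard-normal quantiles of their
#' mid-offset ranks, `qnorm((rank - 0.5) / n)`, using average ranks for
#' ties. Missing values are preserved.
#'
#' @param y numeric vector, at least two distinct non-missing values
#' @return transformed vector of the same length
#' @export
quantile_transform <- function(y) {
  ok <- !is.na(y)
  yy <- y[ok]
  assert_that(length(yy) >= 2, "need at least 2 non-missing values")
  if (length(unique(yy)) < 2) abort("constant phenotype cannot be rank-transformed")
  r <- rank(yy, ties.method = "average")
  out <- y
  out[ok] <- qnorm((r - 0.5) / length(yy))
  out
}

#' Cumulative and expected allele frequency of a gene's qualifying variants
#'
#' CAF is the sum of the qualifying variants' allele frequencies; EAF is
#' CAF times the effective cohort size (`n` individuals for quantitative
#' traits, the number of cases for binary traits). Genes are testable when
#' EAF >= `threshold`.
#'
#' @param mafs allele frequencies of the gene's qualifying variants (may be
#'   empty)
#' @param n effective cohort size (> 0)
#' @param threshold minimum EAF for testability (default 50)
#' @return one-row tibble: `caf`, `eaf`, `passes`
#' @export
compute_eaf <- function(mafs, n, threshold = 50) {
  assert_that(is.numeric(n) && length(n) == 1 && n > 0, "`n` must be positive")
  caf <- sum(mafs)
  eaf <- caf * n
  tibble::tibble(caf = caf, eaf = eaf, passes = eaf >= threshold)
}

#' Per-individual qualifying-variant sets
#'
#' Builds the unordered variant sets consumed by the impairment model: for
#' each individual carrying at least one qualifying variant assigned to a
#' requested gene, the distinct variants carried. Allele count 2 does not
#' duplicate a variant (set semantics); dosages stay available in the sparse
#' genotypes for burden/SKAT testing.
#'
#' @param genotypes a [sparse_genotypes] object
#' @param assignments variant-to-gene assignment table from
#'   [assign_variants_to_genes()]
#' @param qualifying_ids character vector of qualifying variant ids
#' @param genes genes to build sets for (default: all genes in `assignments`)
#' @return tibble with columns `individual_id`, `gene_id`, `variant_id`
#' @export
build_variant_sets <- function(genotypes, assignments, qualifying_ids,
                               genes = NULL) {
  genes <- genes %||% unique(assignments$gene_id)
  unknown <- setdiff(genes, unique(assignments$gene_id))
  if (length(unknown) > 0) {
    abort(paste0("unknown gene id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  asn <- dplyr::filter(assignments, .data$gene_id %in% genes,
                       .data$variant_id %in% qualifying_ids)
  mat <- genotypes$mat
  vidx <- match(asn$variant_id, genotypes$variant_id)
  keep <- !is.na(vidx)
  asn <- asn[keep, , drop = FALSE]
  vidx <- vidx[keep]
  if (nrow(asn) == 0) {
    return(tibble::tibble(individual_id = character(), gene_id = character(),
                          variant_id = character()))
  }
  sub <- methods::as(mat[, vidx, drop = FALSE], "TsparseMatrix")
  nz_keep <- sub@x > 0
  tibble::tibble(
    individual_id = genotypes$individual_id[sub@i[nz_keep] + 1L],
    gene_id = asn$gene_id[sub@j[nz_keep] + 1L],
    variant_id = asn$variant_id[sub@j[nz_keep] + 1L]
  ) |>
    dplyr::arrange(.data$individual_id, .data$gene_id, .data$variant_id)
}
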