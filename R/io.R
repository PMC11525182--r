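# File interchange: sparse genotype container, minimal VCF, TSV tables,
# YAML config. All writers are exact inverses of the matching readers
# (doubles serialized at 17 significant digits).

SPARSE_MAGIC <- "RVNTSPG1"

#' Write sparse genotypes to the package's binary container
#'
#' A small self-describing binary file: magic/version header, dimensions,
#' compressed-sparse-column index arrays (`p`, `i`), allele counts, MAFs,
#' and the row/column key strings. Exact round trip with
#' [read_sparse_genotypes()].
#'
#' @param genotypes a [sparse_genotypes] object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sparse_genotypes <- function(genotypes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  mat <- genotypes$mat
  writeChar(SPARSE_MAGIC, con, eos = NULL)
  writeBin(c(nrow(mat), ncol(mat), length(mat@x)), con, size = 8L)
  writeBin(as.integer(mat@p), con, size = 4L)
  writeBin(as.integer(mat@i), con, size = 4L)
  writeBin(as.integer(mat@x), con, size = 4L)
  writeBin(as.double(genotypes$maf), con, size = 8L)
  writeBin(genotypes$individual_id, con)
  writeBin(genotypes$variant_id, con)
  invisible(path)
}

#' Read sparse genotypes from the binary container
#' @param path file written by [write_sparse_genotypes()]
#' @return a [sparse_genotypes] object
#' @export
read_sparse_genotypes <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(SPARSE_MAGIC))
  if (!identical(magic, SPARSE_MAGIC)) abort("not a sparse genotype container")
  dims <- readBin(con, "integer", 3L, size = 8L)
  p <- readBin(con, "integer", dims[2] + 1L, size = 4L)
  i <- readBin(con, "integer", dims[3], size = 4L)
  x <- readBin(con, "integer", dims[3], size = 4L)
  maf <- readBin(con, "double", dims[2], size = 8L)
  ind <- readBin(con, "character", dims[1])
  var <- readBin(con, "character", dims[2])
  mat <- methods::new("dgCMatrix", i = i, p = p, x = as.double(x),
                      Dim = c(dims[1], dims[2]))
  sparse_genotypes(mat, ind, var, maf)
}

#' Write genotypes as a minimal GT-only VCF
#'
#' One ALT allele per record, fields CHROM..FORMAT plus one GT column per
#' individual. Intended for interchange of modest cohorts; the sparse
#' container is the scalable format.
#'
#' @param genotypes a [sparse_genotypes] object
#' @param variants variant tibble (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`)
#' @param path output `.vcf` path (uncompressed)
#' @return `path`, invisibly
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(identical(variants$variant_id, genotypes$variant_id))
  n <- nrow(genotypes$mat)
  m <- ncol(genotypes$mat)
  gt <- matrix("0/0", m, n)
  tm <- methods::as(genotypes$mat, "TsparseMatrix")
  gt[cbind(tm@j + 1L, tm@i + 1L)] <- ifelse(tm@x == 2, "1/1", "0/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=rvatnet",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$individual_id),
                    collapse = "\t"))
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-only VCF into sparse genotypes
#'
#' Uses the vcfR parser. MAF metadata is not carried by the minimal VCF;
#' it is taken from `maf` (usually the annotation table), falling back to
#' the empirical allele frequency.
#'
#' @param path VCF file
#' @param maf optional per-variant MAFs in file order
#' @return a [sparse_genotypes] object
#' @export
read_vcf <- function(path, maf = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  counts <- matrix(0L, nrow(gt), ncol(gt))
  counts[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  counts[gt %in% c("1/1", "1|1")] <- 2L
  mat <- methods::as(Matrix::Matrix(base::t(counts), sparse = TRUE),
                     "CsparseMatrix")
  inform(sprintf("read_vcf: %d variants x %d individuals", nrow(gt), ncol(gt)))
  emp <- Matrix::colSums(mat) / (2 * nrow(mat))
  sparse_genotypes(mat, colnames(gt), v@fix[, "ID"], maf %||% emp)
}

fmt_table <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                  ~ sprintf("%.17g", .x)))
}

read_typed_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  inform(sprintf("read %d records from %s", nrow(out), basename(path)))
  out
}

#' Write a cohort to a directory of interchange files
#'
#' Genotypes go to both the sparse container and a minimal VCF;
#' annotations, covariates, phenotypes and the ground-truth sidecar to
#' TSV; gene models to BED-like TSV (kept 1-based closed, as labelled in
#' the header); the configuration to YAML.
#'
#' @param cohort an `rvat_cohort`
#' @param dir output directory (created if missing)
#' @param vcf also write the VCF copy (default TRUE; skip for large
#'   cohorts)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir, vcf = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_sparse_genotypes(cohort$genotypes, fp("genotypes.bin"))
  if (vcf) write_vcf(cohort$genotypes, cohort$variants, fp("genotypes.vcf"))
  readr::write_tsv(fmt_table(cohort$variants), fp("annotations.tsv"))
  readr::write_tsv(fmt_table(cohort$covariates), fp("covariates.tsv"))
  readr::write_tsv(fmt_table(cohort$phenotypes), fp("phenotypes.tsv"))
  readr::write_tsv(fmt_table(cohort$gene_models), fp("gene_models.tsv"))
  readr::write_tsv(fmt_table(cohort$truth$variant_u), fp("truth_variants.tsv"))
  cfg <- cohort$config
  cfg$traits <- lapply(cfg$traits, function(tr) unclass(tr)[!vapply(tr, is.null, TRUE)])
  yaml::write_yaml(unclass(cfg), fp("config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Reconstructs genotypes from the sparse container and recomputes the
#' derived pieces (assignments, ground-truth impairment matrix) from the
#' stored tables.
#'
#' @param dir directory written by [write_cohort()]
#' @return an `rvat_cohort`
#' @export
read_cohort <- function(dir) {
  fp <- function(x) file.path(dir, x)
  cfg_raw <- yaml::read_yaml(fp("config.yaml"))
  traits <- lapply(cfg_raw$traits, function(tr) {
    do.call(trait_config, tr)
  })
  config <- sim_config(
    n_individuals = cfg_raw$n_individuals, n_genes = cfg_raw$n_genes,
    variants_per_gene = cfg_raw$variants_per_gene,
    maf_range = unlist(cfg_raw$maf_range),
    n_annotations = cfg_raw$n_annotations,
    n_causal_annotations = cfg_raw$n_causal_annotations,
    annotation_correlation = cfg_raw$annotation_correlation,
    impairment_form = cfg_raw$impairment_form,
    impairment_scale = cfg_raw$impairment_scale,
    traits = traits, n_pcs = cfg_raw$n_pcs, rng_seed = cfg_raw$rng_seed)
  geno <- read_sparse_genotypes(fp("genotypes.bin"))
  variants <- read_typed_tsv(fp("annotations.tsv"))
  gene_models <- read_typed_tsv(fp("gene_models.tsv"))
  covariates <- read_typed_tsv(fp("covariates.tsv"))
  phenotypes <- read_typed_tsv(fp("phenotypes.tsv"))
  truth_u <- read_typed_tsv(fp("truth_variants.tsv"))
  assignments <- assign_variants_to_genes(variants, gene_models)
  gene_ids <- sort(unique(gene_models$gene_id))
  U <- true_impairment_matrix(geno, assignments, truth_u, gene_ids)
  structure(
    list(config = config, variants = variants, gene_models = gene_models,
         genotypes = geno, assignments = assignments,
         covariates = covariates, phenotypes = phenotypes,
         truth = list(variant_u = truth_u, gene_impairment = U,
                      causal_annotations = seq_len(config$n_causal_annotations),
                      seed_genes = NULL)),
    class = "rvat_cohort")
}
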