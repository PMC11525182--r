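test_that("variant-to-gene assignment honours the 300 bp window, inclusively", {
  gm <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                       exon_start = 1000L, exon_end = 1500L, strand = "+")
  v <- tibble::tibble(
    variant_id = c("inside", "at300", "at301", "before297", "far"),
    chrom = "chr1",
    pos = c(1200L, 1800L, 1801L, 703L, 99999L))
  asn <- assign_variants_to_genes(v, gm, window = 300)
  expect_setequal(asn$variant_id, c("inside", "at300", "before297"))
  expect_equal(asn$distance[asn$variant_id == "inside"], 0L)
  expect_equal(asn$distance[asn$variant_id == "at300"], 300L)
  expect_equal(asn$distance[asn$variant_id == "before297"], 297L)
})

test_that("a variant can be assigned to several genes; bad exons error", {
  gm <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                       exon_start = c(1000L, 1400L),
                       exon_end = c(1300L, 1900L), strand = "+")
  v <- tibble::tibble(variant_id = "shared", chrom = "chr1", pos = 1350L)
  asn <- assign_variants_to_genes(v, gm)
  expect_setequal(asn$gene_id, c("g1", "g2"))
  bad <- tibble::tibble(gene_id = "g", chrom = "chr1",
                        exon_start = 10L, exon_end = 5L, strand = "+")
  expect_error(assign_variants_to_genes(v, bad), "malformed")
})

test_that("MAF transform matches 1/sqrt(p(1-p)) and rejects the boundary", {
  expect_equal(transform_maf(0.5), 2)
  expect_equal(transform_maf(0.001), 1 / sqrt(0.001 * 0.999), tolerance = 1e-12)
  expect_true(all(diff(transform_maf(seq(0.001, 0.5, by = 0.001))) < 0))
  expect_error(transform_maf(0), "strictly inside")
  expect_error(transform_maf(1), "strictly inside")
})

test_that("qualifying-variant filter is strict at both cutoffs and idempotent", {
  v <- tibble::tibble(variant_id = letters[1:5],
                      maf = c(0.0005, 0.001, 0.002, 0.01, 0.2),
                      cadd_phred = 10)
  expect_equal(nrow(suppressMessages(filter_qualifying_variants(v, 0.001))), 1)
  expect_equal(nrow(suppressMessages(filter_qualifying_variants(v, 0.01))), 3)
  v$cadd_phred <- 5
  expect_equal(nrow(suppressMessages(filter_qualifying_variants(v, 0.01))), 0)
  v$cadd_phred <- 10
  once <- suppressMessages(filter_qualifying_variants(v, 0.01))
  twice <- suppressMessages(filter_qualifying_variants(once, 0.01))
  expect_identical(once, twice)
})

test_that("quantile transform hits the normal grid, keeps order and NAs", {
  y <- c(3, 1, 4, 1.5, 9, NA, 2.6, 5, 7)  # 8 non-missing -> even n
  z <- quantile_transform(y)
  expect_true(is.na(z[6]))
  expect_equal(order(z[-6]), order(y[-6]))
  y_odd <- c(10, 20, 30, 40, 50)
  expect_equal(quantile_transform(y_odd)[3], 0)
  z2 <- quantile_transform(rnorm(501))
  expect_lt(abs(mean(z2)), 1e-6)
  expect_error(quantile_transform(rep(1, 10)), "constant")
})

test_that("EAF is CAF times n with an inclusive threshold at 50", {
  expect_equal(compute_eaf(0.001, 50000),
               tibble::tibble(caf = 0.001, eaf = 50, passes = TRUE))
  r <- compute_eaf(c(0.0004, 0.0006), 40000)
  expect_equal(r$caf, 0.001)
  expect_equal(r$eaf, 40)
  expect_false(r$passes)
  r2 <- compute_eaf(0.05, 900)  # binary trait: n = cases
  expect_equal(r2$eaf, 45)
  expect_false(r2$passes)
  r3 <- compute_eaf(numeric(), 10000)
  expect_equal(r3$caf, 0)
  expect_false(r3$passes)
  # linear in n, additive in MAFs
  expect_equal(compute_eaf(c(0.001, 0.002), 1000)$eaf,
               compute_eaf(0.001, 1000)$eaf + compute_eaf(0.002, 1000)$eaf)
  expect_equal(compute_eaf(0.003, 2000)$eaf, 2 * compute_eaf(0.003, 1000)$eaf)
})

test_that("variant sets contain distinct carried variants and account for all
           sparse entries", {
  co <- small_cohort()
  qual <- suppressMessages(filter_qualifying_variants(co$variants, 0.01))
  vs <- build_variant_sets(co$genotypes, co$assignments, qual$variant_id)
  # bookkeeping identity: sum over (i,j) of |V_ij| equals the nonzero count
  # restricted to assigned qualifying variants (multi-gene variants counted
  # once per gene)
  asn <- dplyr::filter(co$assignments, variant_id %in% qual$variant_id)
  vidx <- match(asn$variant_id, co$genotypes$variant_id)
  expect_equal(nrow(vs), sum(co$genotypes$mat[, vidx] > 0))
  # homozygous carriers appear once (set semantics)
  expect_false(any(duplicated(vs)))
  expect_error(build_variant_sets(co$genotypes, co$assignments,
                                  qual$variant_id, genes = "nope"),
               "unknown gene")
})

test_that("sparse container round trip is exact", {
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".bin")
  write_sparse_genotypes(co$genotypes, path)
  back <- read_sparse_genotypes(path)
  expect_identical(as.matrix(back$mat), as.matrix(co$genotypes$mat))
  expect_identical(back$individual_id, co$genotypes$individual_id)
  expect_identical(back$variant_id, co$genotypes$variant_id)
  expect_identical(back$maf, co$genotypes$maf)
})

test_that("VCF round trip preserves genotypes", {
  skip_if_not_installed("vcfR")
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co$genotypes, co$variants, path)
  back <- suppressMessages(read_vcf(path, maf = co$genotypes$maf))
  expect_identical(back$individual_id, co$genotypes$individual_id)
  expect_identical(as.character(back$variant_id),
                   co$genotypes$variant_id)
  expect_equal(as.matrix(back$mat), as.matrix(co$genotypes$mat),
               ignore_attr = TRUE)
})

test_that("cohort directory round trip reproduces genotypes, annotations and
           phenotypes exactly", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir, vcf = FALSE)
  back <- suppressMessages(read_cohort(dir))
  expect_identical(as.matrix(back$genotypes$mat), as.matrix(co$genotypes$mat))
  expect_equal(as.data.frame(back$variants), as.data.frame(co$variants))
  expect_equal(as.data.frame(back$phenotypes), as.data.frame(co$phenotypes))
  expect_equal(as.data.frame(back$covariates), as.data.frame(co$covariates))
  expect_equal(back$truth$gene_impairment, co$truth$gene_impairment)
  expect_equal(back$config$maf_range, co$config$maf_range)
})
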