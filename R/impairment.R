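# The gene impairment module: a permutation-invariant set network
#   psi(V) = sigmoid(rho(max_k phi(x_k)))
# with phi a two-layer MLP of width 20, element-wise maximum pooling over
# the variant dimension, and rho an MLP with two hidden layers of width 10
# and a linear output. Activations are leaky rectifiers (negative slope
# 0.01). Forward and backward passes are implemented with plain matrix
# operations; grouped max/argmax over the (individual, gene) pairs uses
# data.table, so scores are independent of variant order and of how
# individuals are batched.

PHI_WIDTH <- 20L
RHO_WIDTH <- 10L
LEAKY_SLOPE <- 0.01

leaky <- function(x, slope = LEAKY_SLOPE) ifelse(x > 0, x, slope * x)
dleaky <- function(x, slope = LEAKY_SLOPE) ifelse(x > 0, 1, slope)

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Create an untrained gene impairment module
#'
#' @param annotation_cols names of the annotation columns the module
#'   consumes, in order (the schema; scoring new data requires a match by
#'   name)
#' @param seed integer seed for parameter initialisation
#' @param activation `"leaky_relu"` (default) or `"linear"`; the latter is
#'   the linear ablation used to quantify what the nonlinearity buys
#' @return an object of class `impairment_module`
#' @export
new_impairment_module <- function(annotation_cols, seed = 1L,
                                  activation = c("leaky_relu", "linear")) {
  activation <- match.arg(activation)
  d <- length(annotation_cols)
  withr::local_seed(derive_seed(seed, "init"))
  params <- list(
    W1 = he_init(d, PHI_WIDTH), b1 = rep(0, PHI_WIDTH),
    W2 = he_init(PHI_WIDTH, PHI_WIDTH), b2 = rep(0, PHI_WIDTH),
    U1 = he_init(PHI_WIDTH, RHO_WIDTH), c1 = rep(0, RHO_WIDTH),
    U2 = he_init(RHO_WIDTH, RHO_WIDTH), c2 = rep(0, RHO_WIDTH),
    U3 = he_init(RHO_WIDTH, 1L), c3 = 0)
  structure(list(params = params,
                 annotation_cols = annotation_cols,
                 activation = activation,
                 center = rep(0, d), scale = rep(1, d),
                 maf_cutoff_train = NA_real_),
            class = "impairment_module")
}

#' @export
print.impairment_module <- function(x, ...) {
  cat(sprintf("<impairment_module> d=%d annotations, phi %d-%d, rho %d-%d-1, %s\n",
              length(x$annotation_cols), PHI_WIDTH, PHI_WIDTH, RHO_WIDTH,
              RHO_WIDTH, x$activation))
  invisible(x)
}

act_fun <- function(module) {
  if (module$activation == "linear") list(f = identity,
                                          df = function(x) rep(1, length(x)))
  else list(f = leaky, df = dleaky)
}

# phi forward on an m x d (already standardized) annotation matrix
phi_forward <- function(module, A) {
  p <- module$params
  act <- act_fun(module)
  Z1p <- sweep(A %*% p$W1, 2, p$b1, `+`)
  Z1 <- act$f(Z1p)
  Z2p <- sweep(Z1 %*% p$W2, 2, p$b2, `+`)
  list(Z1p = Z1p, Z1 = Z1, Z2p = Z2p, E = act$f(Z2p))
}

# rho forward on a P x PHI_WIDTH matrix of pooled gene embeddings
rho_forward <- function(module, Z) {
  p <- module$params
  act <- act_fun(module)
  H1p <- sweep(Z %*% p$U1, 2, p$c1, `+`)
  H1 <- act$f(H1p)
  H2p <- sweep(H1 %*% p$U2, 2, p$c2, `+`)
  H2 <- act$f(H2p)
  out <- as.vector(H2 %*% p$U3) + p$c3
  list(H1p = H1p, H1 = H1, H2p = H2p, H2 = H2, out = out,
       psi = plogis(out))
}

# Grouped element-wise max with argmax bookkeeping.
# E: m x W embedding matrix; var_row: carry rows into E; pair_id: integer
# group per carry row (1..P contiguous after ordering). Returns pooled
# matrix Z (P x W) in group order 1..P and the global carry-row index of
# each column's argmax.
grouped_max <- function(E, var_row, pair_id, n_pairs) {
  Wd <- ncol(E)
  ord <- order(pair_id)
  vr <- var_row[ord]
  gp <- pair_id[ord]
  C <- E[vr, , drop = FALSE]
  dt <- data.table::as.data.table(C)
  dt[, grp := gp]
  mx <- as.matrix(dt[, lapply(.SD, max), by = grp][order(grp)][, grp := NULL])
  wm <- as.matrix(dt[, lapply(.SD, which.max), by = grp][order(grp)][, grp := NULL])
  starts <- c(1L, cumsum(rle(gp)$lengths) + 1L)
  grp_ids <- rle(gp)$values
  Z <- matrix(0, n_pairs, Wd)
  AM <- matrix(NA_integer_, n_pairs, Wd)
  Z[grp_ids, ] <- mx
  AM[grp_ids, ] <- wm + starts[seq_along(grp_ids)] - 1L
  # AM holds indices into vr (ordered carry rows); convert to E rows
  AMv <- matrix(NA_integer_, n_pairs, Wd)
  AMv[grp_ids, ] <- matrix(vr[AM[grp_ids, ]], ncol = Wd)
  list(Z = Z, argmax_row = AMv, present = grp_ids)
}

# Forward pass over a carry table.
# A_std: standardized annotation matrix (qualifying variants, m x d)
# carry: data.frame/table with integer columns pair_id (1..n_pairs) and
#   var_row (rows of A_std). Pairs absent from carry (empty sets) score 0.
set_forward <- function(module, A_std, carry, n_pairs) {
  if (nrow(carry) == 0) {
    return(list(psi = rep(0, n_pairs), present = integer()))
  }
  ph <- phi_forward(module, A_std)
  gm <- grouped_max(ph$E, carry$var_row, carry$pair_id, n_pairs)
  rh <- rho_forward(module, gm$Z[gm$present, , drop = FALSE])
  psi <- rep(0, n_pairs)
  psi[gm$present] <- rh$psi
  list(psi = psi, phi = ph, gm = gm, rho = rh, present = gm$present)
}

# Backward pass: dpsi is the gradient of the loss wrt psi for each pair
# (length n_pairs; zeros for empty sets). Returns gradients for every
# parameter of phi and rho.
set_backward <- function(module, A_std, fw, dpsi) {
  p <- module$params
  act <- act_fun(module)
  pres <- fw$present
  rh <- fw$rho
  dout <- dpsi[pres] * rh$psi * (1 - rh$psi)
  # rho backward
  dU3 <- crossprod(rh$H2, dout)
  dc3 <- sum(dout)
  dH2 <- outer(dout, as.vector(p$U3))
  dH2p <- dH2 * act$df(rh$H2p)
  dU2 <- crossprod(rh$H1, dH2p)
  dc2 <- colSums(dH2p)
  dH1 <- dH2p %*% base::t(p$U2)
  dH1p <- dH1 * act$df(rh$H1p)
  dU1 <- crossprod(fw$gm$Z[pres, , drop = FALSE], dH1p)
  dc1 <- colSums(dH1p)
  dZ <- dH1p %*% base::t(p$U1)
  # route through the max: each pooled coordinate's gradient goes to the
  # argmax variant row
  m <- nrow(A_std)
  Wd <- ncol(dZ)
  dE <- matrix(0, m, Wd)
  am <- fw$gm$argmax_row[pres, , drop = FALSE]
  for (k in seq_len(Wd)) {
    acc <- rowsum(dZ[, k], group = am[, k])
    dE[as.integer(rownames(acc)), k] <- dE[as.integer(rownames(acc)), k] + acc[, 1]
  }
  # phi backward
  ph <- fw$phi
  dZ2p <- dE * act$df(ph$Z2p)
  dW2 <- crossprod(ph$Z1, dZ2p)
  db2 <- colSums(dZ2p)
  dZ1 <- dZ2p %*% base::t(p$W2)
  dZ1p <- dZ1 * act$df(ph$Z1p)
  dW1 <- crossprod(A_std, dZ1p)
  db1 <- colSums(dZ1p)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       U1 = dU1, c1 = dc1, U2 = dU2, c2 = dc2,
       U3 = dU3, c3 = dc3)
}

standardize_annotations <- function(module, A_raw) {
  sweep(sweep(A_raw, 2, module$center, `-`), 2, module$scale, `/`)
}

#' Score one variant set
#'
#' Applies the impairment module to the unordered set of annotation vectors
#' of the qualifying variants one individual carries in one gene. The empty
#' set scores exactly 0 (no qualifying rare variants, no measured
#' impairment); nonempty sets score strictly inside (0, 1).
#'
#' @param module an `impairment_module`
#' @param V matrix (or data frame) of annotation rows; column names must
#'   match the module's annotation schema (any order, matched by name)
#' @return scalar impairment score
#' @export
score_gene <- function(module, V) {
  if (is.null(V) || nrow(V) == 0) return(0)
  V <- as.matrix(as.data.frame(V))
  missing_cols <- setdiff(module$annotation_cols, colnames(V))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation schema mismatch; missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  V <- V[, module$annotation_cols, drop = FALSE]
  # duplicated members cannot change a max-pooled score; dropping them keeps
  # the invariance exact to the last bit regardless of BLAS blocking
  V <- V[!duplicated(V), , drop = FALSE]
  A <- standardize_annotations(module, V)
  carry <- data.frame(pair_id = rep(1L, nrow(A)), var_row = seq_len(nrow(A)))
  set_forward(module, A, carry, 1L)$psi
}

#' Impairment scores for a cohort
#'
#' Computes the individuals x genes matrix of impairment scores from the
#' module: qualifying variants (module's training MAF cutoff by default),
#' gene assignment, per-(individual, gene) set pooling. Non-carriers score
#' 0.
#'
#' @param module an `impairment_module`
#' @param cohort an `rvat_cohort`
#' @param genes genes to score (default: all)
#' @param maf_cutoff qualifying-variant MAF cutoff (default 0.001, the
#'   association convention)
#' @param cadd_cutoff CADD cutoff (default 5)
#' @return dense matrix, rownames individuals, colnames genes
#' @export
score_matrix <- function(module, cohort, genes = NULL, maf_cutoff = 0.001,
                         cadd_cutoff = 5) {
  genes <- genes %||% sort(unique(cohort$gene_models$gene_id))
  prep <- prepare_scoring(module, cohort, genes, maf_cutoff, cadd_cutoff)
  n <- length(cohort$genotypes$individual_id)
  out <- matrix(0, n, length(genes),
                dimnames = list(cohort$genotypes$individual_id, genes))
  if (nrow(prep$carry) == 0) return(out)
  fw <- set_forward(module, prep$A, prep$carry, prep$n_pairs)
  out[cbind(prep$pair_ind, prep$pair_gene)] <- fw$psi
  out
}

# Shared scoring prep: qualifying variants, schema check, standardized
# annotation matrix, carry table with dense pair ids.
prepare_scoring <- function(module, cohort, genes, maf_cutoff, cadd_cutoff) {
  missing_cols <- setdiff(module$annotation_cols, names(cohort$variants))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation schema mismatch; missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  qual <- suppressMessages(
    filter_qualifying_variants(cohort$variants, maf_cutoff, cadd_cutoff))
  carry <- build_variant_sets(cohort$genotypes, cohort$assignments,
                              qual$variant_id, genes = genes)
  if (nrow(carry) == 0) {
    return(list(carry = carry, n_pairs = 0L))
  }
  vkey <- unique(carry$variant_id)
  A_raw <- as.matrix(qual[match(vkey, qual$variant_id),
                          module$annotation_cols, drop = FALSE])
  pair_key <- paste(carry$individual_id, carry$gene_id, sep = "\r")
  pid <- match(pair_key, unique(pair_key))
  first <- !duplicated(pid)
  list(A = standardize_annotations(module, A_raw),
       carry = data.frame(pair_id = pid,
                          var_row = match(carry$variant_id, vkey)),
       n_pairs = max(pid),
       pair_ind = match(carry$individual_id[first],
                        cohort$genotypes$individual_id),
       pair_gene = match(carry$gene_id[first], genes))
}

#' Mean per-trait squared-error loss over an individual-phenotype batch
#'
#' @param predictions,targets numeric vectors over (individual, trait)
#'   pairs; pairs with missing targets are excluded
#' @param trait factor/character identifying each pair's trait
#' @return scalar: per-trait mean squared error, averaged over the traits
#'   present in the batch
#' @export
multitask_loss <- function(predictions, targets, trait) {
  ok <- !is.na(targets)
  if (!any(ok)) abort("batch contains no valid individual-phenotype pairs")
  se <- (predictions[ok] - targets[ok])^2
  mean(tapply(se, trait[ok], mean))
}
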