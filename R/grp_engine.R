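# Genotype -> imputed signature-gene expression -> genetically regulated
# cell-type proportions (GRPs). Deconvolution is unconstrained least
# squares: no non-negativity, no sum-to-one.

#' Impute tissue-level expression of the weighted genes
#'
#' \eqn{\hat B_{ig} = \sum_p d_{ip} w_{pg}} over the panel SNPs carrying a
#' weight for gene g. Alleles must already be harmonized
#' ([harmonize_alleles()]); genes with no usable SNP in the panel are
#' dropped with a message.
#'
#' @param panel a [genotype_panel()] oriented to the weight effect alleles.
#' @param weights an [expression_weights()].
#' @return object of class `ImputedExpression`: list with `B` (individuals
#'   x genes), `genes`, `tissue`.
#' @export
impute_expression <- function(panel, weights) {
  genes <- unique(weights$entries$gene)
  usable <- weights$entries$rsid %in% panel$snps$rsid
  kept_genes <- unique(weights$entries$gene[usable])
  dropped <- setdiff(genes, kept_genes)
  if (length(kept_genes) == 0) stop("no genes with usable SNPs in the panel")
  if (length(dropped) > 0)
    message(length(dropped), " gene(s) dropped: no weight SNPs in panel")
  W <- weights_as_matrix(weights, rsids = panel$snps$rsid, genes = kept_genes)
  B <- as.matrix(panel$dosages %*% W)
  rownames(B) <- panel$sample_ids
  structure(list(B = B, genes = kept_genes, tissue = weights$tissue),
            class = "ImputedExpression")
}

#' Transform eQTL weights into SNP-level cell-type loadings
#'
#' Computes \eqn{A = (S^\top S)^{-1}} and the SNP x cell-type matrix
#' \eqn{M = \hat\beta S A} over the genes shared between the weight set and
#' the signature matrix. `M[p, c]` is the contribution of one counted-allele
#' copy of SNP p to the GRP of cell type c.
#'
#' @param weights an [expression_weights()].
#' @param sig a [signature_matrix()].
#' @param cond_max error when the condition number of \eqn{S^\top S}
#'   exceeds this (default 1e8), unless `allow_pseudoinverse`.
#' @param min_genes minimum number of shared signature genes required for a
#'   stable test (default 50); fewer genes error unless `force = TRUE`
#'   (then a warning).
#' @param force proceed with a warning below `min_genes`.
#' @param allow_pseudoinverse fall back to the eigen pseudo-inverse with a
#'   warning when the condition number exceeds `cond_max`.
#' @return object of class `TransformedWeights`: list with `A` (C x C),
#'   `M` (SNP x cell type, sparse rows limited to weighted SNPs), `genes`,
#'   `cell_types`, `condition_number`, `tissue`.
#' @export
transform_weights <- function(weights, sig, cond_max = 1e8, min_genes = 50,
                              force = FALSE, allow_pseudoinverse = FALSE) {
  genes <- intersect(unique(weights$entries$gene), rownames(sig))
  if (length(genes) < min_genes) {
    msg <- sprintf("only %d shared signature genes (< %d); revise the gene set",
                   length(genes), min_genes)
    if (!force) stop(msg) else warning(msg)
  }
  if (length(genes) == 0) stop("no genes shared between weights and signature")
  S <- unclass(sig)[genes, , drop = FALSE]
  StS <- crossprod(S)
  ev <- eigen(StS, symmetric = TRUE)
  cond <- ev$values[1] / ev$values[length(ev$values)]
  if (!is.finite(cond) || cond < 0) cond <- Inf
  if (cond > cond_max) {
    if (!allow_pseudoinverse)
      stop(sprintf(paste("condition number of S'S is %.3g (> %.3g);",
                         "revise the signature gene set or merge cell types"),
                   cond, cond_max))
    warning("ill-conditioned S'S; using eigen pseudo-inverse")
    pos <- ev$values > ev$values[1] * 1e-12
    A <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  } else {
    A <- chol2inv(chol(StS))
  }
  dimnames(A) <- list(colnames(S), colnames(S))
  rsids <- unique(weights$entries$rsid[weights$entries$gene %in% genes])
  W <- weights_as_matrix(weights, rsids = rsids, genes = genes)
  M <- as.matrix(W %*% (S %*% A))
  structure(list(A = A, M = M, genes = genes, cell_types = colnames(S),
                 condition_number = cond, tissue = weights$tissue),
            class = "TransformedWeights")
}

#' Deconvolve imputed expression into genetically regulated proportions
#'
#' \eqn{\hat F = \hat B S (S^\top S)^{-1}}: the row-wise unconstrained
#' least-squares solution of \eqn{b_i \approx S f_i}. Per-cell-type
#' standard deviations over the panel individuals (denominator n-1) are
#' attached; a cell type with zero variance is flagged untestable.
#'
#' @param b an [impute_expression()] result.
#' @param tw a [transform_weights()] result built on the same signature.
#' @param sig the [signature_matrix()].
#' @return object of class `GrpMatrix`: list with `F` (individuals x cell
#'   types), `sd`, `untestable`, `tissue`.
#' @export
deconvolve <- function(b, tw, sig) {
  genes <- tw$genes
  if (!all(genes %in% b$genes))
    stop("imputed expression lacks gene(s) used by the weight transform: ",
         paste(head(setdiff(genes, b$genes)), collapse = ", "))
  S <- unclass(sig)[genes, , drop = FALSE]
  F_hat <- b$B[, genes, drop = FALSE] %*% S %*% tw$A
  colnames(F_hat) <- tw$cell_types
  sds <- apply(F_hat, 2, sd)
  untestable <- names(sds)[sds == 0]
  if (length(untestable) > 0)
    warning("cell type(s) with zero GRP variance flagged untestable: ",
            paste(untestable, collapse = ", "))
  structure(list(F = F_hat, sd = sds, untestable = untestable,
                 tissue = b$tissue),
            class = "GrpMatrix")
}

#' @export
print.GrpMatrix <- function(x, ...) {
  cat(sprintf("GrpMatrix '%s': %d individuals x %d cell types\n",
              x$tissue, nrow(x$F), ncol(x$F)))
  invisible(x)
}
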