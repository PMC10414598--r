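# Signature-matrix curation from cell-type-labelled single-cell
# expression: cell-type abundance filtering, one-vs-rest differential
# expression with Bonferroni control, and per-cell-type averaging.
# Input counts are expected to be normalized already (e.g. log-CPM); the
# module never re-normalizes.

#' Construct a labelled single-cell expression object
#'
#' @param expr cells x genes matrix of normalized expression, gene colnames.
#' @param cell_type character/factor label per cell (non-empty).
#' @param gene_ids optional gene ids (default: colnames of `expr`).
#' @return object of class `LabeledExpression`.
#' @export
labeled_expression <- function(expr, cell_type, gene_ids = NULL) {
  expr <- as.matrix(expr)
  if (is.null(gene_ids)) gene_ids <- colnames(expr)
  if (is.null(gene_ids)) stop("gene ids required (colnames or gene_ids)")
  colnames(expr) <- gene_ids
  cell_type <- as.character(cell_type)
  stopifnot(length(cell_type) == nrow(expr))
  if (any(is.na(cell_type) | cell_type == "")) stop("empty cell-type labels")
  structure(list(expr = expr, cell_type = cell_type, gene_ids = gene_ids),
            class = "LabeledExpression")
}

#' Drop sparsely observed cell types
#'
#' Keeps only cell types with strictly more than `min_cells` cells (rare
#' populations give unstable mean-expression profiles).
#'
#' @param le a [labeled_expression()].
#' @param min_cells threshold (default 50).
#' @return the filtered [labeled_expression()].
#' @export
filter_cell_types <- function(le, min_cells = 50) {
  stopifnot(min_cells >= 1)
  tab <- table(le$cell_type)
  keep_types <- names(tab)[tab > min_cells]
  if (length(keep_types) < 2)
    stop("fewer than 2 cell types remain; deconvolution undefined")
  keep <- le$cell_type %in% keep_types
  labeled_expression(le$expr[keep, , drop = FALSE], le$cell_type[keep])
}

#' Select signature genes by one-vs-rest differential expression
#'
#' For every gene and cell type, tests the cells of that type against all
#' other cells (Wilcoxon rank-sum or one-way ANOVA, which for two groups is
#' the equal-variance t-test). P-values are Bonferroni-corrected over all
#' genes x cell types at level `alpha`. A gene becomes a signature gene of
#' cell type c when it is significant for c, upregulated in c (mean in c
#' above the mean of the rest), and — unless `unique_only = FALSE` —
#' significant in no other cell type. Constant genes are skipped.
#'
#' @param le a [labeled_expression()].
#' @param method `"wilcoxon"` or `"anova"`.
#' @param alpha family-wise error level (default 0.05).
#' @param universe optional character vector restricting the result to the
#'   imputable gene universe (e.g. genes with trained eQTL models).
#' @param unique_only require significance in exactly one cell type.
#' @param min_logfc optional minimum mean difference in `c` vs rest
#'   (default 0, i.e. any upregulation).
#' @return named list (one element per cell type) of signature gene
#'   vectors; attribute `"pvalues"` holds the gene x cell-type p matrix.
#' @export
de_select <- function(le, method = c("wilcoxon", "anova"), alpha = 0.05,
                      universe = NULL, unique_only = TRUE, min_logfc = 0) {
  method <- match.arg(method)
  types <- sort(unique(le$cell_type))
  if (length(types) < 2) stop("need >= 2 cell types")
  G <- ncol(le$expr)
  pmat <- matrix(NA_real_, nrow = G, ncol = length(types),
                 dimnames = list(colnames(le$expr), types))
  upmat <- matrix(FALSE, nrow = G, ncol = length(types),
                  dimnames = dimnames(pmat))
  skipped <- character(0)
  for (g in seq_len(G)) {
    x <- le$expr[, g]
    if (sd(x) == 0) { skipped <- c(skipped, colnames(le$expr)[g]); next }
    for (ci in seq_along(types)) {
      inc <- le$cell_type == types[ci]
      diff_means <- mean(x[inc]) - mean(x[!inc])
      upmat[g, ci] <- diff_means > min_logfc
      pmat[g, ci] <- switch(method,
        wilcoxon = wilcox.test(x[inc], x[!inc], exact = FALSE)$p.value,
        anova = {
          fit <- aov(x ~ factor(inc))
          summary(fit)[[1]][["Pr(>F)"]][1]
        })
    }
  }
  if (length(skipped) > 0)
    message(length(skipped), " constant gene(s) skipped")
  n_tests <- sum(!is.na(pmat))
  sig <- !is.na(pmat) & pmat * n_tests <= alpha
  # a marker of one type is also significantly *depleted* in every other
  # type's one-vs-rest comparison; uniqueness counts upregulated hits only
  n_sig_up <- rowSums(sig & upmat)
  out <- lapply(seq_along(types), function(ci) {
    pick <- sig[, ci] & upmat[, ci]
    if (unique_only) pick <- pick & n_sig_up == 1
    g <- rownames(pmat)[pick]
    if (!is.null(universe)) g <- intersect(g, universe)
    g
  })
  names(out) <- types
  attr(out, "pvalues") <- pmat
  out
}

#' Average labelled expression into a signature matrix
#'
#' \eqn{S[g, c]} is the mean expression of gene g over the cells labelled
#' c. Warns (but proceeds) when fewer than 50 genes are selected, since the
#' association test requires at least 50 signature genes.
#'
#' @param le a [labeled_expression()].
#' @param genes character vector of selected signature genes (e.g. the
#'   union of a [de_select()] result).
#' @return a [signature_matrix()] (0-row when `genes` is empty).
#' @export
build_signature <- function(le, genes) {
  genes <- intersect(genes, colnames(le$expr))
  if (length(genes) == 0) {
    warning("empty gene selection; returning 0-row signature")
    types <- sort(unique(le$cell_type))
    return(structure(matrix(numeric(0), nrow = 0, ncol = length(types),
                            dimnames = list(NULL, types)),
                     class = c("SignatureMatrix", class(matrix()))))
  }
  if (length(genes) < 50)
    warning("fewer than 50 signature genes; association tests need >= 50")
  E <- le$expr[, genes, drop = FALSE]
  sums <- rowsum(E, group = le$cell_type)
  counts <- as.numeric(table(le$cell_type)[rownames(sums)])
  S <- t(sums / counts)
  signature_matrix(S[, sort(colnames(S)), drop = FALSE])
}
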