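# Downstream analyses of cell-type association results: cross-trait and
# cross-tissue Pearson correlations of z-score vectors, highest-expression
# gene-to-cell-type assignment, and the binomial enrichment test for
# differentially expressed gene lists.

#' Assemble a long association table
#'
#' @param tab data.frame with columns `trait`, `tissue`, `cell_type`, `z`
#'   (and optionally `p`, `p_bonf`); `(trait, tissue, cell_type)` must be
#'   unique.
#' @return the validated data.frame, class `AssociationTable`.
#' @export
association_table <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  stopifnot(all(c("trait", "tissue", "cell_type", "z") %in% names(tab)))
  if (anyDuplicated(tab[, c("trait", "tissue", "cell_type")]))
    stop("duplicate (trait, tissue, cell_type) rows")
  class(tab) <- c("AssociationTable", class(tab))
  tab
}

#' Trait-trait correlation of cell-type association profiles
#'
#' Each trait is represented by its vector of z-scores over all
#' (tissue, cell type) combinations (all testable cell types, significant
#' or not); pairs of traits are compared by Pearson correlation with
#' pairwise complete cases, and the correlation-test p-values are
#' Bonferroni-adjusted over trait pairs. Pairs with fewer than
#' `min_overlap` shared entries are left missing.
#'
#' @param tab an [association_table()].
#' @param min_overlap minimum shared entries per pair (default 3).
#' @return list of trait x trait matrices: `r`, `p`, `p_bonf`, `n`.
#' @export
trait_trait_correlation <- function(tab, min_overlap = 3) {
  key <- paste(tab$tissue, tab$cell_type, sep = "|")
  traits <- sort(unique(tab$trait))
  keys <- sort(unique(key))
  Z <- matrix(NA_real_, nrow = length(keys), ncol = length(traits),
              dimnames = list(keys, traits))
  Z[cbind(match(key, keys), match(tab$trait, traits))] <- tab$z
  k <- length(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- complete.cases(Z[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < min_overlap) next
    ct <- cor.test(Z[ok, i], Z[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  n_pairs <- k * (k - 1) / 2
  p_bonf <- pmin(p * n_pairs, 1)
  diag(p_bonf) <- 0
  list(r = r, p = p, p_bonf = p_bonf, n = n)
}

#' Tissue-tissue correlation through shared cell types
#'
#' For the cell types present in both tissues, the z-scores across all
#' traits are stacked into one vector per tissue and compared by Pearson
#' correlation.
#'
#' @param tab an [association_table()].
#' @param tissue_a,tissue_b tissue names.
#' @return list with `r`, `p`, `n`, `shared_cell_types`; `r` is `NA` when
#'   no cell types are shared.
#' @export
tissue_tissue_correlation <- function(tab, tissue_a, tissue_b) {
  a <- tab[tab$tissue == tissue_a, ]
  b <- tab[tab$tissue == tissue_b, ]
  shared <- intersect(unique(a$cell_type), unique(b$cell_type))
  if (length(shared) == 0) {
    message("no shared cell types between ", tissue_a, " and ", tissue_b)
    return(list(r = NA_real_, p = NA_real_, n = 0L,
                shared_cell_types = character(0)))
  }
  a <- a[a$cell_type %in% shared, ]
  b <- b[b$cell_type %in% shared, ]
  key_a <- paste(a$trait, a$cell_type)
  key_b <- paste(b$trait, b$cell_type)
  common <- intersect(key_a, key_b)
  v1 <- a$z[match(common, key_a)]
  v2 <- b$z[match(common, key_b)]
  if (length(common) < 3 || sd(v1) == 0 || sd(v2) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(common),
                shared_cell_types = shared))
  ct <- cor.test(v1, v2)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common),
       shared_cell_types = shared)
}

#' Assign each gene to its highest-expression cell type
#'
#' With `standardize = TRUE`, expression is first z-scored across genes
#' within each cell type, and the argmax is taken over the standardized
#' values (relative expression extremity); with `FALSE` (default) the raw
#' maximum is used. Ties are broken by the lexicographically first cell
#' type and flagged.
#'
#' @param S a [signature_matrix()] (or any gene x cell-type mean matrix).
#' @param standardize z-score within cell type before the argmax.
#' @return data.frame with `gene`, `cell_type`, `tied`.
#' @export
assign_genes_to_celltypes <- function(S, standardize = FALSE) {
  S <- as.matrix(S)
  if (ncol(S) < 2) stop("need >= 2 cell types")
  ord <- order(colnames(S))
  S <- S[, ord, drop = FALSE]
  if (standardize) S <- scale(S)
  best <- apply(S, 1, function(x) which(x == max(x))[1])
  tied <- apply(S, 1, function(x) sum(x == max(x)) > 1)
  data.frame(gene = rownames(S), cell_type = colnames(S)[best], tied = tied,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Binomial cell-type enrichment of a DE gene list
#'
#' For each cell type c, counts the DE genes assigned to c and tests
#' whether that count deviates from the expectation under the cell type's
#' baseline share of the gene universe, by an exact binomial test
#' (two-sided by default, so both enrichment and depletion register);
#' Bonferroni correction is applied over cell types.
#'
#' @param de_genes character vector of DE genes (must lie in `universe`).
#' @param assignment an [assign_genes_to_celltypes()] result covering the
#'   universe.
#' @param universe character vector of background genes.
#' @param alternative passed to [stats::binom.test()] (default
#'   `"two.sided"`).
#' @return data.frame with one row per cell type: `cell_type`, `k`, `n`,
#'   `baseline`, `fold_change`, `p`, `p_bonf`.
#' @export
celltype_enrichment <- function(de_genes, assignment, universe,
                                alternative = "two.sided") {
  if (length(universe) == 0) stop("empty gene universe")
  if (!all(de_genes %in% universe)) stop("de_genes must be a subset of universe")
  assignment <- assignment[assignment$gene %in% universe, , drop = FALSE]
  types <- sort(unique(assignment$cell_type))
  n <- length(de_genes)
  res <- do.call(rbind, lapply(types, function(ct) {
    assigned <- assignment$gene[assignment$cell_type == ct]
    k <- length(intersect(de_genes, assigned))
    baseline <- length(assigned) / length(universe)
    p <- binom.test(k, n, p = baseline, alternative = alternative)$p.value
    data.frame(cell_type = ct, k = k, n = n, baseline = baseline,
               fold_change = (k / n) / baseline, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_bonf <- pmin(1, res$p * length(types))
  res
}
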