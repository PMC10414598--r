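# Per-tissue cis elastic-net expression imputation models: covariate
# residualization, cis-window SNP selection, cross-validated glmnet fits,
# and the FDR + median-accuracy gene filters.

#' Bundle genotypes, expression and covariates for weight training
#'
#' @param panel a [genotype_panel()].
#' @param expression numeric matrix, individuals x genes, with gene colnames.
#' @param genes data.frame with columns `gene`, `chr`, `tss` (1-based TSS).
#' @param covariates optional individuals x K numeric matrix (genotype PCs,
#'   expression factors, ...). Sample order must match the panel.
#' @return object of class `TrainingDataset`.
#' @export
training_dataset <- function(panel, expression, genes, covariates = NULL) {
  expression <- as.matrix(expression)
  stopifnot(nrow(expression) == nrow(panel$dosages))
  if (!is.null(rownames(expression)) &&
      !identical(rownames(expression), panel$sample_ids))
    stop("expression sample ids do not match the panel (same order required)")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chr", "tss") %in% names(genes)), all(genes$tss > 0))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(expression))
  }
  structure(list(panel = panel, expression = expression, genes = genes,
                 covariates = covariates),
            class = "TrainingDataset")
}

#' Residualize expression on covariates
#'
#' Replaces each gene's expression by its OLS residuals against the
#' covariate matrix plus an intercept (with intercept only, this is simple
#' centering). Errors when the covariates are rank deficient, naming the
#' collinear columns.
#'
#' @param ds a [training_dataset()].
#' @return the dataset with residualized expression; covariates kept for
#'   bookkeeping.
#' @export
residualize_expression <- function(ds) {
  n <- nrow(ds$expression)
  C <- cbind(`(Intercept)` = rep(1, n), ds$covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ds$expression <- qr.resid(qrC, ds$expression)
  ds
}

#' Select cis-SNPs around a gene's transcription start site
#'
#' SNPs on the gene's chromosome with `|pos - tss| <= window` (boundary
#' inclusive); the conventional window is 1 Mb.
#'
#' @param panel a [genotype_panel()].
#' @param chr chromosome of the gene.
#' @param tss transcription start site (1-based).
#' @param window half-width in bp (default 1e6).
#' @return integer vector of SNP indices into the panel (possibly empty).
#' @export
select_cis_snps <- function(panel, chr, tss, window = 1e6) {
  stopifnot(window > 0)
  which(panel$snps$chr == as.character(chr) &
          abs(panel$snps$pos - tss) <= window)
}

#' Train one gene's cis elastic-net imputation model
#'
#' Fits a cross-validated elastic net of (standardized) residualized
#' expression on cis dosages with the mixing parameter held fixed and the
#' penalty chosen by internal CV. Imputation accuracy is the squared
#' correlation between out-of-fold predictions and the observed values;
#' `cv_pvalue` is the correlation-test p-value of that association. Fold
#' assignment is deterministic given `seed`.
#'
#' @param X_cis dosage submatrix (individuals x cis-SNPs).
#' @param y residualized expression vector.
#' @param alpha elastic-net mixing (default 0.5).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param standardize_y scale `y` to unit variance before fitting; the
#'   scale factor is returned so weights can be mapped back.
#' @param lambda optional penalty sequence passed to glmnet.
#' @return list with `weights` (named, nonzero only, dosage scale),
#'   `cv_r2`, `cv_pvalue`, `y_scale`.
#' @export
train_gene_model <- function(X_cis, y, alpha = 0.5, folds = 10, seed = 1,
                             standardize_y = TRUE, lambda = NULL) {
  X_cis <- as.matrix(X_cis)
  n <- length(y)
  stopifnot(nrow(X_cis) == n, ncol(X_cis) >= 1, n >= 2 * folds)
  y_scale <- 1
  if (standardize_y) {
    s <- sd(y)
    if (s > 0) { y <- y / s; y_scale <- s }
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  # glmnet needs >= 2 columns; pad single-SNP models with a zero column
  pad <- ncol(X_cis) == 1
  Xfit <- if (pad) cbind(X_cis, 0) else X_cis
  fit <- glmnet::cv.glmnet(Xfit, y, alpha = alpha, foldid = foldid,
                           keep = TRUE, lambda = lambda, standardize = TRUE)
  i <- match(fit$lambda.min, fit$lambda)
  pred <- fit$fit.preval[, i]
  b <- as.numeric(coef(fit, s = "lambda.min"))[-1]
  if (pad) b <- b[1]
  names(b) <- colnames(X_cis)
  if (all(b == 0) || sd(pred) == 0) {
    return(list(weights = numeric(0), cv_r2 = 0, cv_pvalue = 1,
                y_scale = y_scale))
  }
  ct <- cor.test(pred, y)
  list(weights = b[b != 0], cv_r2 = unname(ct$estimate)^2,
       cv_pvalue = ct$p.value, y_scale = y_scale)
}

#' Train weights for all genes of a tissue and apply the quality filters
#'
#' Trains a cis elastic-net model per gene, computes Benjamini-Hochberg
#' q-values over all trained genes' CV p-values, and retains genes with
#' `q < fdr_max` whose CV accuracy is at or above the median accuracy of
#' the FDR-passing genes (both flags are stored for every gene).
#'
#' @param ds a [training_dataset()]; expression should already be
#'   residualized (see [residualize_expression()]).
#' @param fdr_max FDR threshold (default 0.05).
#' @param window cis window half-width in bp.
#' @param alpha,folds,seed passed to [train_gene_model()]; the per-gene seed
#'   is derived from `seed` deterministically.
#' @param median_over population over which the median accuracy is taken:
#'   FDR-passing genes (default) or all trained genes.
#' @param tissue tissue label.
#' @return an [expression_weights()] with entries for retained genes and
#'   quality statistics for every trained gene.
#' @export
build_weight_set <- function(ds, fdr_max = 0.05, window = 1e6, alpha = 0.5,
                             folds = 10, seed = 1,
                             median_over = c("fdr_passing", "all"),
                             tissue = "tissue") {
  median_over <- match.arg(median_over)
  genes <- ds$genes
  stopifnot(nrow(genes) >= 2)
  seeds <- derive_seeds(seed, nrow(genes))
  fits <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    idx <- select_cis_snps(ds$panel, genes$chr[i], genes$tss[i], window)
    if (length(idx) == 0) {
      fits[[i]] <- list(weights = numeric(0), cv_r2 = 0, cv_pvalue = 1)
      next
    }
    fits[[i]] <- train_gene_model(ds$panel$dosages[, idx, drop = FALSE],
                                  ds$expression[, genes$gene[i]],
                                  alpha = alpha, folds = folds, seed = seeds[i])
  }
  stats <- data.frame(gene = genes$gene,
                      cv_r2 = vapply(fits, `[[`, numeric(1), "cv_r2"),
                      cv_pvalue = vapply(fits, `[[`, numeric(1), "cv_pvalue"),
                      stringsAsFactors = FALSE)
  stats$fdr_q <- p.adjust(stats$cv_pvalue, method = "BH")
  stats$pass_fdr <- stats$fdr_q < fdr_max
  pop <- if (median_over == "fdr_passing") stats$cv_r2[stats$pass_fdr] else stats$cv_r2
  med <- if (length(pop) > 0) median(pop) else Inf
  stats$pass_median <- stats$cv_r2 >= med
  stats$kept <- stats$pass_fdr & stats$pass_median
  if (!any(stats$kept)) {
    warning("no genes survive the FDR and median-accuracy filters")
    return(expression_weights(
      data.frame(gene = character(0), rsid = character(0),
                 effect_allele = character(0), other_allele = character(0),
                 weight = numeric(0)),
      gene_stats = stats, tissue = tissue))
  }
  snps <- ds$panel$snps
  entries <- do.call(rbind, lapply(which(stats$kept), function(i) {
    w <- fits[[i]]$weights
    if (length(w) == 0) return(NULL)
    j <- match(names(w), snps$rsid)
    data.frame(gene = genes$gene[i], rsid = names(w),
               effect_allele = snps$counted_allele[j],
               other_allele = snps$other_allele[j],
               weight = unname(w), stringsAsFactors = FALSE)
  }))
  if (is.null(entries) || nrow(entries) == 0) {
    warning("retained genes have empty weight vectors")
    entries <- data.frame(gene = character(0), rsid = character(0),
                          effect_allele = character(0),
                          other_allele = character(0), weight = numeric(0))
  }
  expression_weights(entries, gene_stats = stats, tissue = tissue)
}
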