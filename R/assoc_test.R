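# The summary-statistic cell-type association test: a burden-style sum of
# per-SNP GWAS z-scores weighted by sd(X_p) * M[p,c], normalised by the
# reference-panel GRP standard deviation.

#' Cell-type association z-scores from GWAS summary statistics
#'
#' For every testable cell type c,
#' \deqn{z_c = \sum_p sd(X_p)\, z_p\, M_{p,c} \, / \, sd(\hat F_c),}
#' summing over the SNPs of the transformed weight matrix. SNPs absent from
#' the GWAS contribute zero (their count is reported per cell type rather
#' than renormalising, which would silently change the null variance).
#' Two-sided normal p-values and a per-tissue Bonferroni adjustment over
#' the testable cell types are attached.
#'
#' Inputs must share one allele orientation — run [harmonize_alleles()]
#' first so the GWAS z, the panel dosages and the weights all count the
#' same allele per SNP.
#'
#' @param gwas a [gwas_summary()] (harmonized).
#' @param tw a [transform_weights()] result.
#' @param panel the reference [genotype_panel()] (harmonized) supplying
#'   `sd(X_p)`.
#' @param grp the [deconvolve()] result on the same panel supplying
#'   `sd(F_c)`.
#' @param alpha significance level for the Bonferroni call (default 0.05).
#' @param sd_x optional precomputed [panel_sd()] vector (named by rsid);
#'   avoids recomputation in tight simulation loops.
#' @return data.frame of class `CellAssociation` with columns `tissue`,
#'   `cell_type`, `z`, `p`, `p_bonf`, `significant`, `n_snps_used`,
#'   `n_snps_missing`, `n_genes_used`, `direction`.
#' @export
cwas_z <- function(gwas, tw, panel, grp, alpha = 0.05, sd_x = NULL) {
  rsids <- rownames(tw$M)
  in_panel <- rsids %in% panel$snps$rsid
  if (!any(in_panel)) stop("no transformed-weight SNPs present in the panel")
  zmap <- gwas$snp$z[match(rsids, gwas$snp$rsid)]
  n_missing <- sum(is.na(zmap) & in_panel)
  if (all(is.na(zmap) | !in_panel)) stop("no overlapping SNPs between GWAS and weights")
  zmap[is.na(zmap)] <- 0
  if (is.null(sd_x)) sd_x <- panel_sd(panel)
  sdx <- rep(0, length(rsids))
  sdx[in_panel] <- sd_x[rsids[in_panel]]
  if (any(abs(zmap) > 37))
    warning("|z| > 37 for some SNPs; the small-effect approximation may be poor")
  testable <- setdiff(tw$cell_types, grp$untestable)
  if (length(testable) == 0) stop("no testable cell types (all zero GRP variance)")
  num <- as.numeric(crossprod(tw$M[, testable, drop = FALSE], sdx * zmap))
  zc <- num / grp$sd[testable]
  p <- 2 * pnorm(-abs(zc))
  C <- length(testable)
  res <- data.frame(tissue = tw$tissue, cell_type = testable, z = zc, p = p,
                    p_bonf = pmin(1, p * C), significant = p * C <= alpha,
                    n_snps_used = sum(in_panel) - n_missing,
                    n_snps_missing = n_missing,
                    n_genes_used = length(tw$genes),
                    direction = sign(zc),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("CellAssociation", class(res))
  res
}

#' Rank cell types by significance
#'
#' Tie-breaking for the "most significant cell type": smallest p, then
#' largest |z|, then lexicographic cell-type name.
#'
#' @param results a `CellAssociation` data.frame.
#' @return the data.frame sorted, most significant first.
#' @export
rank_cell_types <- function(results) {
  results[order(results$p, -abs(results$z), results$cell_type), , drop = FALSE]
}

#' Down-sample GWAS summary statistics
#'
#' Emulates a study with 1/R of the original sample size: every z is
#' divided by \eqn{\sqrt R}, sample sizes by R, and p-values recomputed.
#'
#' @param gwas a [gwas_summary()].
#' @param R ratio of original to target sample size, >= 1.
#' @return the rescaled [gwas_summary()].
#' @export
downsample_z <- function(gwas, R) {
  if (!is.numeric(R) || length(R) != 1 || R < 1) stop("R must be a scalar >= 1")
  s <- gwas$snp
  s$z <- s$z / sqrt(R)
  s$n <- s$n / R
  s$p <- 2 * pnorm(-abs(s$z))
  gwas_summary(s, trait = gwas$trait)
}

#' Bonferroni adjustment over a tissue's cell types
#'
#' @param results a `CellAssociation` data.frame for one tissue.
#' @param alpha significance level (default 0.05).
#' @return `results` with `p_bonf` and `significant` recomputed using
#'   C = number of rows.
#' @export
apply_bonferroni <- function(results, alpha = 0.05) {
  if (length(unique(results$tissue)) > 1)
    stop("apply_bonferroni expects results from a single tissue")
  C <- nrow(results)
  results$p_bonf <- pmin(1, results$p * C)
  results$significant <- results$p * C <= alpha
  results
}
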