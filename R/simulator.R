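# Fully synthetic study generator and Monte-Carlo harness: LD-structured
# diploid genotypes, sparse cis weights, signature matrices, phenotypes
# with controlled GRP heritability, per-SNP GWAS, and the evaluation
# metrics (power, type-I error, top-selection rate, direction consistency,
# false identification rate).

#' Specify a simulation study
#'
#' Defaults are the package's scaled study conditions: 5,000 individuals,
#' 2,000 SNPs with AR-1 haplotype LD 0.3 and MAF ~ U(0.05, 0.5), 100
#' signature genes carrying 1-5 cis SNPs each, 8 cell types, 200 Monte
#' Carlo replicates per stratum.
#'
#' @param n_individuals panel/GWAS sample size.
#' @param n_snps total SNP count.
#' @param n_genes signature genes per tissue.
#' @param n_celltypes cell types per tissue.
#' @param ld AR-1 correlation of the latent haplotype field.
#' @param maf_range range of the uniform allele-frequency distribution.
#' @param h2 grid of phenotype variance fractions explained by the causal
#'   cell type's GRP (0 = global null).
#' @param signature_fraction fraction(s) of signature genes known to the
#'   test; the data-generating signature stays complete.
#' @param n_replicates Monte Carlo replicates per (h2, fraction) stratum.
#' @param snps_per_gene candidate cis-SNP counts per gene.
#' @param n_chrom number of chromosomes the SNPs are split over (the AR-1
#'   field restarts at each boundary).
#' @param seed master seed; everything downstream is derived from it.
#' @return object of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_individuals = 5000, n_snps = 2000,
                            n_genes = 100, n_celltypes = 8, ld = 0.3,
                            maf_range = c(0.05, 0.5),
                            h2 = seq(0.01, 0.09, by = 0.01),
                            signature_fraction = 1, n_replicates = 200,
                            snps_per_gene = 1:5, n_chrom = 1, seed = 1) {
  stopifnot(n_snps >= 1, all(h2 >= 0), all(h2 < 1),
            all(signature_fraction > 0), all(signature_fraction <= 1),
            n_replicates >= 1, ld >= 0, ld < 1)
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 n_genes = n_genes, n_celltypes = n_celltypes, ld = ld,
                 maf_range = maf_range, h2 = h2,
                 signature_fraction = signature_fraction,
                 n_replicates = n_replicates, snps_per_gene = snps_per_gene,
                 n_chrom = n_chrom, seed = seed),
            class = "SimulationSpec")
}

#' Simulate an LD-structured diploid genotype panel
#'
#' Each individual carries two haplotypes; each haplotype is a latent
#' standard-Gaussian AR-1 field over SNPs, thresholded at the per-SNP
#' allele-frequency quantile, so adjacent-SNP dosage correlation decays
#' geometrically with distance. MAFs are drawn uniformly from `maf_range`.
#' SNP positions are spaced 1 kb apart within each chromosome.
#'
#' @param spec a [simulation_spec()] (fields n_individuals, n_snps, ld,
#'   maf_range, n_chrom are used).
#' @param seed integer seed.
#' @return a [genotype_panel()].
#' @export
simulate_genotypes <- function(spec, seed = spec$seed) {
  set.seed(seed)
  n <- spec$n_individuals; p <- spec$n_snps
  maf <- runif(p, spec$maf_range[1], spec$maf_range[2])
  thr <- qnorm(maf)
  chrom <- rep(seq_len(spec$n_chrom), length.out = p)
  chrom <- sort(chrom)
  new_chrom <- c(TRUE, diff(chrom) != 0)
  dos <- matrix(0, nrow = n, ncol = p)
  z <- NULL
  for (j in seq_len(p)) {
    e <- rnorm(2 * n)
    z <- if (new_chrom[j]) e else spec$ld * z + sqrt(1 - spec$ld^2) * e
    hap <- z < thr[j]
    dos[, j] <- hap[seq_len(n)] + hap[n + seq_len(n)]
  }
  pos <- integer(p)
  for (k in seq_len(spec$n_chrom)) {
    idx <- which(chrom == k)
    pos[idx] <- seq_along(idx) * 1000L
  }
  snps <- data.frame(rsid = paste0("rs", seq_len(p)), chr = as.character(chrom),
                     pos = pos, counted_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  genotype_panel(dos, snps, sample_ids = paste0("id", seq_len(n)))
}

#' Simulate sparse cis weights and a well-conditioned signature matrix
#'
#' The available SNPs are tiled into one contiguous block per gene; each
#' gene receives 1-5 cis SNPs drawn from its own block with independent
#' N(0, 1) weights, giving every gene a local cis architecture. The
#' signature matrix is |N(0, 1)| entries plus a marker boost: genes are
#' assigned round-robin to cell types and the marker entry is raised, so
#' every cell type has a set of genes whose expression is maximal in that
#' column. The draw is repeated (up to 100 times) until the condition
#' number of \eqn{S^\top S} is below `cond_max`.
#'
#' @param spec a [simulation_spec()].
#' @param panel the [genotype_panel()] the weights refer to.
#' @param seed integer seed.
#' @param snp_subset optional integer indices into the panel restricting
#'   the SNP pool (e.g. one chromosome for one tissue).
#' @param tissue tissue label; gene ids are prefixed with it so two
#'   simulated tissues have disjoint gene sets.
#' @param marker_boost added to marker entries of S (default 3).
#' @param cond_max redraw S until cond(S'S) is below this (default 1e4).
#' @return list with `weights` (an [expression_weights()]), `signature`
#'   (a [signature_matrix()]), and `genes` (gene/chr/tss table).
#' @export
simulate_weights_and_signature <- function(spec, panel, seed = spec$seed,
                                           snp_subset = NULL,
                                           tissue = "tissueA",
                                           marker_boost = 3, cond_max = 1e4) {
  set.seed(seed)
  pool <- if (is.null(snp_subset)) seq_len(nrow(panel$snps)) else snp_subset
  G <- spec$n_genes; C <- spec$n_celltypes
  stopifnot(length(pool) >= G)
  block <- split(pool, cut(seq_along(pool), G, labels = FALSE))
  gene_ids <- sprintf("%s_gene%03d", tissue, seq_len(G))
  entries <- vector("list", G)
  genes <- data.frame(gene = gene_ids, chr = NA_character_, tss = NA_integer_,
                      stringsAsFactors = FALSE)
  for (g in seq_len(G)) {
    k <- sample(spec$snps_per_gene, 1)
    k <- min(k, length(block[[g]]))
    idx <- sort(sample(block[[g]], k))
    entries[[g]] <- data.frame(gene = gene_ids[g],
                               rsid = panel$snps$rsid[idx],
                               effect_allele = panel$snps$counted_allele[idx],
                               other_allele = panel$snps$other_allele[idx],
                               weight = rnorm(k), stringsAsFactors = FALSE)
    mid <- idx[ceiling(k / 2)]
    genes$chr[g] <- panel$snps$chr[mid]
    genes$tss[g] <- panel$snps$pos[mid]
  }
  weights <- expression_weights(do.call(rbind, entries), tissue = tissue)
  marker <- rep_len(seq_len(C), G)
  for (try in seq_len(100)) {
    S <- matrix(abs(rnorm(G * C)), nrow = G, ncol = C,
                dimnames = list(gene_ids, sprintf("%s_ct%d", tissue, seq_len(C))))
    S[cbind(seq_len(G), marker)] <- S[cbind(seq_len(G), marker)] + marker_boost
    ev <- eigen(crossprod(S), symmetric = TRUE, only.values = TRUE)$values
    if (ev[C] > 0 && ev[1] / ev[C] < cond_max) break
    if (try == 100) stop("could not draw a signature with cond(S'S) < cond_max")
  }
  list(weights = weights, signature = signature_matrix(S), genes = genes)
}

#' Simulate a phenotype driven by one cell type's GRP
#'
#' \eqn{Y = \hat F_{c^*}\gamma + \varepsilon} with unit residual variance
#' and \eqn{\gamma = \sqrt{h^2/(1-h^2)\cdot 1/var(\hat F_{c^*})}}, so the
#' GRP explains a fraction h2 of the phenotype variance in expectation.
#' `h2 = 0` gives the null phenotype \eqn{Y = \varepsilon}.
#'
#' @param grp a [deconvolve()] result.
#' @param cell_type name or index of the causal cell type.
#' @param h2 target heritability in `[0, 1)`.
#' @param seed integer seed.
#' @return numeric phenotype vector with attribute `gamma`.
#' @export
simulate_phenotype <- function(grp, cell_type, h2, seed = 1) {
  if (h2 >= 1) stop("h2 must be < 1")
  f <- grp$F[, cell_type]
  if (h2 > 0 && sd(f) == 0) stop("causal cell type has zero GRP variance")
  gamma <- if (h2 == 0) 0 else sqrt(h2 / (1 - h2) / var(f))
  set.seed(seed)
  y <- as.numeric(f * gamma + rnorm(length(f)))
  attr(y, "gamma") <- gamma
  y
}

#' Per-SNP GWAS by marginal ordinary least squares
#'
#' Regresses the phenotype on each SNP's dosage with an intercept and
#' optional covariates (via residualization, which gives the same
#' t-statistics as the joint fit). Constant dosage columns get z = 0,
#' p = 1 and are flagged.
#'
#' @param panel a [genotype_panel()].
#' @param y phenotype vector.
#' @param covariates optional individuals x K matrix.
#' @return a [gwas_summary()]; the `snp` table carries a `flagged` column
#'   for degenerate SNPs.
#' @export
run_gwas <- function(panel, y, covariates = NULL) {
  X <- panel$dosages
  n <- nrow(X)
  stopifnot(length(y) == n)
  Cm <- cbind(rep(1, n), covariates)
  Q <- qr.Q(qr(Cm))
  yr <- as.numeric(y - Q %*% crossprod(Q, y))
  if (sum(yr^2) <= 1e-12 * sum((y - mean(y))^2)) {
    # covariates explain the phenotype perfectly; every marginal test is null
    snp <- data.frame(rsid = panel$snps$rsid, a1 = panel$snps$counted_allele,
                      a2 = panel$snps$other_allele, z = 0, p = 1, n = n,
                      beta = 0, se = Inf, flagged = TRUE,
                      stringsAsFactors = FALSE)
    return(gwas_summary(snp, trait = "simulated"))
  }
  P <- crossprod(Q, X)
  Sxx <- colSums(X^2) - colSums(P^2)
  Sxy <- as.numeric(crossprod(X, yr))
  df <- n - ncol(Cm) - 1
  flagged <- Sxx <= 1e-10 * n
  beta <- ifelse(flagged, 0, Sxy / Sxx)
  rss <- pmax(sum(yr^2) - beta * Sxy, 0)
  se <- ifelse(flagged, Inf, sqrt(rss / df / pmax(Sxx, 1e-300)))
  z <- ifelse(flagged | rss == 0, 0, beta / se)
  snp <- data.frame(rsid = panel$snps$rsid,
                    a1 = panel$snps$counted_allele,
                    a2 = panel$snps$other_allele,
                    z = z, p = 2 * pnorm(-abs(z)), n = n,
                    beta = beta, se = se, flagged = flagged,
                    stringsAsFactors = FALSE)
  gwas_summary(snp, trait = "simulated")
}

# internal: transform + deconvolve + test for a gene subset, reusing the
# full imputation matrix
test_with_genes <- function(genes_used, weights, sig, b, gwas, sd_x,
                            alpha = 0.05) {
  w <- weights
  w$entries <- w$entries[w$entries$gene %in% genes_used, , drop = FALSE]
  tw <- transform_weights(w, sig, min_genes = 1)
  grp <- deconvolve(b, tw, sig)
  cwas_z(gwas, tw, panel = NULL_panel_stub(b, sd_x), grp = grp,
         alpha = alpha, sd_x = sd_x)
}

# cwas_z only touches panel$snps$rsid and sd via sd_x; build a light stub
NULL_panel_stub <- function(b, sd_x) {
  list(snps = data.frame(rsid = names(sd_x), stringsAsFactors = FALSE))
}

#' Run a Monte-Carlo simulation study
#'
#' Generates one synthetic study per the spec and evaluates the
#' summary-statistic cell-type test over replicates. Two designs:
#'
#' * `"power"` — one tissue; the phenotype is driven by `causal_celltype`'s
#'   GRP at each h2 of the grid; reports power (Bonferroni detection of the
#'   causal cell type), top-selection rate, direction consistency among
#'   significant replicates, false identification rate, and per-cell-type
#'   unadjusted rejection rates.
#' * `"cross_tissue"` — two independent tissues on separate chromosomes
#'   with disjoint gene sets; the phenotype is driven by a tissue-B cell
#'   type and the test is applied to tissue A, whose per-cell-type
#'   rejection rates estimate the type-I error.
#'
#' The panel, weights and signatures are generated once per call (one
#' reference sample serves the whole grid) unless `fresh_genotypes = TRUE`,
#' which redraws them per stratum. Phenotype noise and the known-gene mask
#' are redrawn every replicate; the mask is applied to the signature used
#' by the test, never to the data-generating signature. All randomness is
#' derived hierarchically from `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @param design `"power"` or `"cross_tissue"`.
#' @param causal_celltype index of the causal cell type (within tissue B
#'   for the cross-tissue design).
#' @param alpha significance level (default 0.05).
#' @param fresh_genotypes redraw the panel each stratum.
#' @param keep_replicates also return the per-replicate records.
#' @return object of class `SimulationReport`: list with `metrics` (one row
#'   per h2 x fraction), `type1` (per-cell-type unadjusted rejection
#'   rates), `spec`, and optionally `replicates`.
#' @export
run_replicates <- function(spec, design = c("power", "cross_tissue"),
                           causal_celltype = 1, alpha = 0.05,
                           fresh_genotypes = FALSE, keep_replicates = FALSE) {
  design <- match.arg(design)
  if (design == "cross_tissue" && spec$n_chrom < 2)
    spec$n_chrom <- 2
  n_h2 <- length(spec$h2)
  root <- derive_seeds(spec$seed, 3)
  stratum_seeds <- derive_seeds(root[3], n_h2)

  build_study <- function(panel_seed, tissue_seed) {
    panel <- simulate_genotypes(spec, seed = panel_seed)
    sd_x <- panel_sd(panel)
    names(sd_x) <- panel$snps$rsid
    tseeds <- derive_seeds(tissue_seed, 2)
    if (design == "power") {
      simA <- simulate_weights_and_signature(spec, panel, seed = tseeds[1],
                                             tissue = "tissueA")
      simB <- NULL
    } else {
      simA <- simulate_weights_and_signature(
        spec, panel, seed = tseeds[1],
        snp_subset = which(panel$snps$chr == "1"), tissue = "tissueA")
      simB <- simulate_weights_and_signature(
        spec, panel, seed = tseeds[2],
        snp_subset = which(panel$snps$chr != "1"), tissue = "tissueB")
    }
    bA <- impute_expression(panel, simA$weights)
    twA <- transform_weights(simA$weights, simA$signature, min_genes = 1)
    grpA <- deconvolve(bA, twA, simA$signature)
    causal <- if (design == "power") {
      list(grp = grpA, name = colnames(grpA$F)[causal_celltype])
    } else {
      bB <- impute_expression(panel, simB$weights)
      twB <- transform_weights(simB$weights, simB$signature, min_genes = 1)
      grpB <- deconvolve(bB, twB, simB$signature)
      list(grp = grpB, name = colnames(grpB$F)[causal_celltype])
    }
    list(panel = panel, sd_x = sd_x, simA = simA, bA = bA, twA = twA,
         grpA = grpA, causal = causal)
  }

  study <- if (!fresh_genotypes) build_study(root[1], root[2]) else NULL
  fractions <- spec$signature_fraction
  records <- list()
  for (i in seq_len(n_h2)) {
    h2 <- spec$h2[i]
    if (fresh_genotypes) {
      ss <- derive_seeds(stratum_seeds[i], 2)
      study <- build_study(ss[1], ss[2])
    }
    rep_seeds <- derive_seeds(stratum_seeds[i], spec$n_replicates)
    gene_pool <- study$simA$genes$gene
    for (r in seq_len(spec$n_replicates)) {
      sr <- derive_seeds(rep_seeds[r], 1 + length(fractions))
      y <- simulate_phenotype(study$causal$grp, causal_celltype, h2,
                              seed = sr[1])
      gw <- run_gwas(study$panel, y)
      for (fi in seq_along(fractions)) {
        f <- fractions[fi]
        if (f >= 1) {
          res <- cwas_z(gw, study$twA, study$panel, study$grpA,
                        alpha = alpha, sd_x = study$sd_x)
        } else {
          set.seed(sr[1 + fi])
          keep <- sample(gene_pool, max(1, round(f * length(gene_pool))))
          res <- test_with_genes(keep, study$simA$weights,
                                 study$simA$signature, study$bA, gw,
                                 study$sd_x, alpha = alpha)
        }
        res$h2 <- h2; res$fraction <- f; res$replicate <- r
        res$gamma <- attr(y, "gamma")
        res$causal <- design == "power" & res$cell_type == study$causal$name
        top <- rank_cell_types(res)$cell_type[1]
        res$is_top <- res$cell_type == top
        records[[length(records) + 1]] <- res
      }
    }
  }
  rec <- as.data.frame(data.table::rbindlist(records))
  metrics <- do.call(rbind, lapply(
    split(rec, list(rec$h2, rec$fraction), drop = TRUE),
    function(d) summarize_stratum(d, alpha)))
  metrics <- metrics[order(metrics$fraction, metrics$h2), , drop = FALSE]
  rownames(metrics) <- NULL
  t1 <- do.call(rbind, lapply(
    split(rec, list(rec$h2, rec$fraction, rec$cell_type), drop = TRUE),
    function(d) data.frame(h2 = d$h2[1], fraction = d$fraction[1],
                           cell_type = d$cell_type[1],
                           rejection_rate = mean(d$p <= alpha),
                           n_replicates = nrow(d))))
  rownames(t1) <- NULL
  out <- list(metrics = metrics, type1 = t1, design = design, spec = spec)
  if (keep_replicates) out$replicates <- rec
  structure(out, class = "SimulationReport")
}

summarize_stratum <- function(d, alpha) {
  nrep <- length(unique(d$replicate))
  causal <- d[d$causal, , drop = FALSE]
  has_causal <- nrow(causal) > 0
  power <- if (has_causal) mean(causal$significant) else NA_real_
  top_rate <- if (has_causal) mean(causal$is_top) else NA_real_
  sig <- causal[causal$significant, , drop = FALSE]
  direction_rate <- if (has_causal && nrow(sig) > 0)
    mean(sign(sig$z) == sign(sig$gamma)) else NA_real_
  noncausal <- d[!d$causal, , drop = FALSE]
  fir <- if (nrow(noncausal) > 0) mean(noncausal$significant) else NA_real_
  data.frame(h2 = d$h2[1], fraction = d$fraction[1], n_replicates = nrep,
             power = power, top_rate = top_rate,
             direction_rate = direction_rate, fir = fir)
}

#' @export
print.SimulationReport <- function(x, ...) {
  cat(sprintf("SimulationReport (%s design): %d strata x %d replicates\n",
              x$design, nrow(x$metrics), x$spec$n_replicates))
  print(x$metrics, digits = 3)
  invisible(x)
}
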