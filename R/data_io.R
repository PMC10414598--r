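# Readers, writers and allele harmonization for the external formats:
# PLINK bed/bim/fam and VCF genotype panels, GWAS summary statistics TSVs,
# expression-weight tables and signature matrices.

#' Construct a genotype panel object
#'
#' A `GenotypePanel` holds real-valued allele dosages (individuals x SNPs,
#' in `[0, 2]`, allowing imputed dosages) together with per-SNP metadata.
#' The *counted* allele is the allele whose copies the dosage counts; it is
#' the reference orientation for all downstream allele harmonization.
#'
#' @param dosages numeric matrix, individuals x SNPs.
#' @param snps data.frame with columns `rsid`, `chr`, `pos` (1-based),
#'   `counted_allele`, `other_allele`. A `maf` column is recomputed.
#' @param sample_ids character vector, one per row of `dosages`.
#' @return An object of class `GenotypePanel`: list with elements
#'   `dosages`, `snps` (including folded `maf`), `sample_ids`.
#' @export
genotype_panel <- function(dosages, snps, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(dosages)))
  }
  stopifnot(nrow(snps) == ncol(dosages), length(sample_ids) == nrow(dosages))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("rsid", "chr", "pos", "counted_allele", "other_allele")
  miss <- setdiff(req, names(snps))
  if (length(miss) > 0) stop("snps table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(snps$rsid)) stop("duplicate rsids in panel")
  # sporadic missing dosages are mean-imputed per SNP before any variance use
  if (anyNA(dosages)) {
    for (j in which(colSums(is.na(dosages)) > 0)) {
      m <- mean(dosages[, j], na.rm = TRUE)
      if (is.nan(m)) m <- 0
      dosages[is.na(dosages[, j]), j] <- m
    }
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snps$rsid
  snps$maf <- panel_maf(dosages)
  structure(list(dosages = dosages, snps = snps, sample_ids = sample_ids),
            class = "GenotypePanel")
}

# folded allele frequency from dosages
panel_maf <- function(dosages) {
  af <- colMeans(dosages) / 2
  pmin(af, 1 - af)
}

#' @export
print.GenotypePanel <- function(x, ...) {
  cat(sprintf("GenotypePanel: %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  chromosomes: %s; MAF range %.3f-%.3f\n",
              paste(unique(x$snps$chr), collapse = ","),
              min(x$snps$maf), max(x$snps$maf)))
  invisible(x)
}

#' Per-SNP genotype standard deviations of a panel
#'
#' Sample standard deviation (denominator n-1) of each dosage column; these
#' are the `sd(X_p)` normalizers of the summary-statistic test.
#'
#' @param panel a `GenotypePanel`.
#' @return named numeric vector, one entry per SNP.
#' @export
panel_sd <- function(panel) {
  apply(panel$dosages, 2, sd)
}

#' Read a genotype reference panel
#'
#' Reads either a PLINK bed/bim/fam triple (pass the path with or without
#' the `.bed` extension) or a VCF (dosage = ALT-allele count from GT), then
#' drops SNPs at or below the MAF threshold. The counted allele is the PLINK
#' A1 allele, or the VCF ALT allele; this orientation is recorded in the SNP
#' table and respected by [harmonize_alleles()].
#'
#' @param path path to `.bed` (or the prefix) or to a `.vcf`/`.vcf.gz` file.
#' @param maf_min SNPs with folded MAF <= `maf_min` are removed
#'   (default 0.05, the usual common-variant threshold).
#' @return a [genotype_panel()].
#' @export
read_genotype_panel <- function(path, maf_min = 0.05) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  panel <- if (grepl("\\.vcf(\\.gz)?$", path)) read_vcf_panel(path) else read_plink(path)
  keep <- panel$snps$maf > maf_min
  if (!any(keep)) stop("no polymorphic SNPs remain after MAF filtering (empty panel)")
  subset_panel(panel, which(keep))
}

subset_panel <- function(panel, snp_idx) {
  genotype_panel(panel$dosages[, snp_idx, drop = FALSE],
                 panel$snps[snp_idx, , drop = FALSE],
                 panel$sample_ids)
}

#' Read a PLINK bed/bim/fam triple
#'
#' Minimal reader for SNP-major PLINK 1 binary genotypes. Missing genotypes
#' are mean-imputed per SNP by [genotype_panel()]. Dosages count copies of
#' the bim A1 allele.
#'
#' @param prefix path prefix (with or without `.bed`).
#' @return a [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing PLINK file member: ", p)
  fam <- data.table::fread(paths[3], header = FALSE)
  bim <- data.table::fread(paths[2], header = FALSE,
                           col.names = c("chr", "rsid", "cm", "pos", "a1", "a2"),
                           colClasses = list(character = c(1, 5, 6)))
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = 3 + ceiling(n / 4) * p)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file: ", paths[1])
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  body <- raw[-(1:3)]
  bps <- ceiling(n / 4)
  # 2-bit codes per individual: 00 hom A1 (2), 01 missing, 10 het (1), 11 hom A2 (0)
  codes <- matrix(0L, nrow = 4 * bps, ncol = p)
  bytes <- matrix(as.integer(body), nrow = bps, ncol = p)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bps, by = 4), ] <- bytes %% 4L
    bytes <- bytes %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0)  # index by code + 1
  dosages <- matrix(lookup[codes + 1L], nrow = n, ncol = p)
  snps <- data.frame(rsid = bim$rsid, chr = as.character(bim$chr), pos = bim$pos,
                     counted_allele = bim$a1, other_allele = bim$a2,
                     stringsAsFactors = FALSE)
  genotype_panel(dosages, snps, sample_ids = as.character(fam[[2]]))
}

#' Write a genotype panel as a PLINK bed/bim/fam triple
#'
#' Dosages are rounded to the nearest hard call {0, 1, 2}; the counted
#' allele is written as A1.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- nrow(panel$dosages); p <- ncol(panel$dosages)
  fam <- data.frame(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  bim <- data.frame(panel$snps$chr, panel$snps$rsid, 0, panel$snps$pos,
                    panel$snps$counted_allele, panel$snps$other_allele)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  hard <- round(panel$dosages)
  code <- matrix(c(3L, 2L, 0L)[hard + 1L], nrow = n)  # dosage 0,1,2 -> code 3,2,0
  bps <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4 * bps, ncol = p)
  codes[seq_len(n), ] <- code
  bytes <- matrix(0L, nrow = bps, ncol = p)
  mult <- 1L
  for (k in 0:3) {
    bytes <- bytes + codes[seq(k + 1, 4 * bps, by = 4), , drop = FALSE] * mult
    mult <- mult * 4L
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a genotype panel from a VCF
#'
#' Dosages are ALT-allele counts parsed from the GT field; the counted
#' allele is ALT. Multi-allelic and non-SNP records are dropped.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @return a [genotype_panel()].
#' @export
read_vcf_panel <- function(path) {
  if (!file.exists(path)) stop("missing VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !grepl(",", fix$ALT)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  # count ALT alleles in GT strings like 0/1, 1|1; missing -> NA
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    out[ok] <- vapply(strsplit(g[ok], "[/|]"),
                      function(a) sum(a == "1"), numeric(1))
    out
  }
  dosages <- matrix(count_alt(t(gt)), nrow = ncol(gt),
                    dimnames = list(colnames(gt), rownames(gt)))
  snps <- data.frame(rsid = fix$ID, chr = fix$CHROM, pos = as.integer(fix$POS),
                     counted_allele = fix$ALT, other_allele = fix$REF,
                     stringsAsFactors = FALSE)
  genotype_panel(dosages, snps, sample_ids = colnames(gt))
}

#' Construct a GWAS summary-statistics object
#'
#' @param snp data.frame with columns `rsid`, `a1` (effect allele), `a2`
#'   (other allele), `z`, `p`, `n`.
#' @param trait trait label.
#' @return object of class `GwasSummary`.
#' @export
gwas_summary <- function(snp, trait = "trait") {
  snp <- as.data.frame(snp, stringsAsFactors = FALSE)
  stopifnot(all(c("rsid", "a1", "a2", "z") %in% names(snp)))
  if (is.null(snp$p)) snp$p <- 2 * pnorm(-abs(snp$z))
  if (is.null(snp$n)) snp$n <- NA_real_
  structure(list(snp = snp, trait = trait), class = "GwasSummary")
}

#' @export
print.GwasSummary <- function(x, ...) {
  cat(sprintf("GwasSummary '%s': %d SNPs, median |z| = %.2f\n",
              x$trait, nrow(x$snp), median(abs(x$snp$z))))
  invisible(x)
}

#' Read GWAS summary statistics from a TSV
#'
#' Expects a header with at least `SNP`, `A1`, `A2` and one of: `Z`;
#' `BETA` + `SE`; or `BETA` + `N` (then \eqn{z = \sqrt{n}\,\beta}).
#' Column matching is case-insensitive. A missing `P` column is filled from
#' the two-sided normal tail; rows without a usable effect are dropped and
#' their count reported via a message.
#'
#' @param path TSV path.
#' @param trait trait label (default: file name).
#' @return a [gwas_summary()].
#' @export
read_gwas_summary <- function(path, trait = NULL) {
  if (is.null(trait)) trait <- sub("\\.[^.]*$", "", basename(path))
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  names(d) <- toupper(names(d))
  need <- c("SNP", "A1", "A2")
  if (!all(need %in% names(d))) stop("GWAS file lacks column(s): ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  if (!any(c("Z", "BETA") %in% names(d)))
    stop("no usable effect column (need Z, or BETA with SE or N)")
  n <- if ("N" %in% names(d)) as.numeric(d$N) else rep(NA_real_, nrow(d))
  z <- rep(NA_real_, nrow(d))
  if ("Z" %in% names(d)) z <- as.numeric(d$Z)
  if ("BETA" %in% names(d)) {
    beta <- as.numeric(d$BETA)
    fill <- is.na(z)
    if ("SE" %in% names(d)) {
      se <- as.numeric(d$SE)
      ok <- fill & !is.na(beta) & !is.na(se) & se > 0
      z[ok] <- beta[ok] / se[ok]
      fill <- is.na(z)
    }
    ok <- fill & !is.na(beta) & !is.na(n)
    z[ok] <- sqrt(n[ok]) * beta[ok]
  }
  drop <- is.na(z)
  if (any(drop)) message(sum(drop), " row(s) dropped: no usable effect columns")
  d <- d[!drop, , drop = FALSE]; z <- z[!drop]; n <- n[!drop]
  p <- if ("P" %in% names(d)) as.numeric(d$P) else rep(NA_real_, nrow(d))
  p[is.na(p)] <- 2 * pnorm(-abs(z[is.na(p)]))
  gwas_summary(data.frame(rsid = d$SNP, a1 = d$A1, a2 = d$A2,
                          z = z, p = p, n = n, stringsAsFactors = FALSE),
               trait = trait)
}

#' Construct an expression weight set
#'
#' Sparse per-tissue cis-eQTL weights: one row per (gene, SNP) pair, with
#' the allele whose dosage the weight multiplies, plus per-gene
#' cross-validation quality statistics.
#'
#' @param entries data.frame with columns `gene`, `rsid`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @param gene_stats data.frame with columns `gene`, `cv_r2`, `cv_pvalue`,
#'   and optionally `fdr_q`, `pass_fdr`, `pass_median`.
#' @param tissue tissue label.
#' @return object of class `ExpressionWeightSet`.
#' @export
expression_weights <- function(entries, gene_stats = NULL, tissue = "tissue") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "rsid", "effect_allele", "other_allele", "weight")
                %in% names(entries)))
  if (anyDuplicated(entries[, c("gene", "rsid")]))
    stop("duplicate (gene, rsid) pairs in weight set")
  if (any(!is.finite(entries$weight))) stop("non-finite weights")
  entries <- entries[entries$weight != 0, , drop = FALSE]
  if (is.null(gene_stats))
    gene_stats <- data.frame(gene = unique(entries$gene), cv_r2 = NA_real_,
                             cv_pvalue = NA_real_, stringsAsFactors = FALSE)
  structure(list(entries = entries, gene_stats = gene_stats, tissue = tissue),
            class = "ExpressionWeightSet")
}

#' @export
print.ExpressionWeightSet <- function(x, ...) {
  cat(sprintf("ExpressionWeightSet '%s': %d genes, %d SNP-gene weights\n",
              x$tissue, length(unique(x$entries$gene)), nrow(x$entries)))
  invisible(x)
}

#' Read / write an expression weight table
#'
#' TSV with columns `gene`, `rsid`, `effect_allele`, `other_allele`,
#' `weight`, `cv_r2`, `cv_pvalue`, `fdr_q`.
#'
#' @param path TSV path.
#' @param tissue tissue label (default: file name).
#' @return an [expression_weights()].
#' @export
read_weights <- function(path, tissue = NULL) {
  if (is.null(tissue)) tissue <- sub("\\.[^.]*$", "", basename(path))
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stat_cols <- intersect(c("cv_r2", "cv_pvalue", "fdr_q"), names(d))
  gs <- unique(d[, c("gene", stat_cols), drop = FALSE])
  expression_weights(d[, c("gene", "rsid", "effect_allele", "other_allele", "weight")],
                     gene_stats = gs, tissue = tissue)
}

#' @rdname read_weights
#' @param weights an [expression_weights()] object.
#' @export
write_weights <- function(weights, path) {
  d <- merge(weights$entries, weights$gene_stats, by = "gene", sort = FALSE)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Construct / validate a signature matrix
#'
#' A signature matrix holds the mean cell-type-specific expression of the
#' signature genes (genes in rows, cell types in columns); deconvolution
#' solves \eqn{\hat B \approx \hat F S^\top} for \eqn{\hat F}.
#'
#' @param S numeric matrix with gene rownames and cell-type colnames.
#' @return `S` with class `SignatureMatrix`.
#' @export
signature_matrix <- function(S) {
  S <- as.matrix(S)
  if (is.null(rownames(S))) stop("signature matrix needs gene rownames")
  if (is.null(colnames(S))) stop("signature matrix needs cell-type colnames")
  if (ncol(S) < 1) stop("signature matrix needs at least one cell type")
  if (anyDuplicated(rownames(S))) stop("duplicated gene ids in signature matrix")
  if (any(!is.finite(S))) stop("non-finite entries in signature matrix")
  class(S) <- c("SignatureMatrix", class(matrix()))
  S
}

#' Read a signature matrix TSV (first column gene ids, remaining columns
#' cell types)
#'
#' @param path TSV path.
#' @return a [signature_matrix()].
#' @export
read_signature <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(d) < 3) stop("signature TSV needs >= 2 cell-type columns")
  genes <- as.character(d[[1]])
  if (anyDuplicated(genes)) stop("duplicated gene ids in signature TSV")
  S <- as.matrix(d[, -1, drop = FALSE])
  rownames(S) <- genes
  signature_matrix(S)
}

#' @rdname read_signature
#' @param S a [signature_matrix()].
#' @export
write_signature <- function(S, path) {
  d <- data.frame(gene = rownames(S), as.data.frame(unclass(S)),
                  check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

is_strand_ambiguous <- function(a1, a2) {
  pair <- paste0(toupper(a1), toupper(a2))
  pair %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize alleles across weights, GWAS summary statistics and panel
#'
#' Restricts all three inputs to their shared rsids, orients everything to
#' the weight set's effect allele: GWAS z-scores are sign-flipped when the
#' GWAS effect allele is the weight's *other* allele, and panel dosages are
#' flipped (`2 - d`) when the counted allele is the weight's other allele.
#' SNPs whose allele pairs neither match nor swap are dropped (alleles are
#' never strand-flipped; strand-ambiguous A/T and C/G SNPs are retained and
#' matched by exact pair unless `drop_ambiguous = TRUE`).
#'
#' @param weights an [expression_weights()].
#' @param gwas a [gwas_summary()].
#' @param panel a [genotype_panel()].
#' @param drop_ambiguous drop strand-ambiguous (A/T, C/G) SNPs up front.
#' @return list with the aligned `weights`, `gwas`, `panel` and a
#'   `dropped` data.frame of counts by reason. Idempotent: applying it to
#'   its own output changes nothing.
#' @export
harmonize_alleles <- function(weights, gwas, panel, drop_ambiguous = FALSE) {
  wsnp <- unique(weights$entries[, c("rsid", "effect_allele", "other_allele")])
  if (anyDuplicated(wsnp$rsid))
    stop("inconsistent allele annotation within weight set")
  rs <- Reduce(intersect, list(wsnp$rsid, gwas$snp$rsid, panel$snps$rsid))
  if (length(rs) == 0) stop("no shared rsids across weights, GWAS and panel")
  wsnp <- wsnp[match(rs, wsnp$rsid), ]
  g <- gwas$snp[match(rs, gwas$snp$rsid), ]
  pidx <- match(rs, panel$snps$rsid)
  psnp <- panel$snps[pidx, ]

  n_ambig <- 0L
  keep_ambig <- rep(TRUE, length(rs))
  if (drop_ambiguous) {
    keep_ambig <- !is_strand_ambiguous(wsnp$effect_allele, wsnp$other_allele)
    n_ambig <- sum(!keep_ambig)
  }
  g_match <- g$a1 == wsnp$effect_allele & g$a2 == wsnp$other_allele
  g_swap  <- g$a1 == wsnp$other_allele  & g$a2 == wsnp$effect_allele
  p_match <- psnp$counted_allele == wsnp$effect_allele &
             psnp$other_allele == wsnp$other_allele
  p_swap  <- psnp$counted_allele == wsnp$other_allele &
             psnp$other_allele == wsnp$effect_allele
  ok <- keep_ambig & (g_match | g_swap) & (p_match | p_swap)
  n_irrec <- sum(keep_ambig & !((g_match | g_swap) & (p_match | p_swap)))
  if (!any(ok)) stop("no SNPs with reconcilable alleles remain")
  if (mean(!ok) > 0.5)
    warning(sprintf("%.0f%% of shared SNPs dropped during harmonization",
                    100 * mean(!ok)))

  rs <- rs[ok]
  g <- g[ok, ]; wsnp <- wsnp[ok, ]
  g$z <- ifelse(g_swap[ok], -g$z, g$z)
  g$a1 <- wsnp$effect_allele; g$a2 <- wsnp$other_allele

  pidx <- pidx[ok]
  dos <- panel$dosages[, pidx, drop = FALSE]
  flip <- p_swap[ok]
  if (any(flip)) dos[, flip] <- 2 - dos[, flip]
  psnp <- panel$snps[pidx, ]
  psnp$counted_allele <- wsnp$effect_allele
  psnp$other_allele <- wsnp$other_allele
  panel2 <- genotype_panel(dos, psnp, panel$sample_ids)

  w2 <- weights
  w2$entries <- weights$entries[weights$entries$rsid %in% rs, , drop = FALSE]
  list(weights = w2,
       gwas = gwas_summary(g, trait = gwas$trait),
       panel = panel2,
       dropped = data.frame(reason = c("ambiguous", "irreconcilable"),
                            n = c(n_ambig, n_irrec)))
}
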