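test_that("PLINK round trip preserves hard-call dosages and metadata", {
  panel <- tiny_panel(n = 17, p = 8, seed = 3)  # n not divisible by 4
  prefix <- file.path(tempdir(), "rt_panel")
  write_plink(panel, prefix)
  back <- read_plink(prefix)
  expect_equal(unname(back$dosages), unname(round(panel$dosages)))
  expect_equal(back$snps$rsid, panel$snps$rsid)
  expect_equal(back$snps$counted_allele, panel$snps$counted_allele)
  expect_equal(back$sample_ids, panel$sample_ids)
})

test_that("MAF filtering removes rare SNPs at the threshold", {
  set.seed(1)
  dos <- cbind(matrix(rbinom(50 * 5, 2, 0.3), 50),
               c(1, rep(0, 49)))  # last SNP MAF = 0.01
  snps <- data.frame(rsid = paste0("rs", 1:6), chr = "1", pos = 1:6 * 100,
                     counted_allele = "A", other_allele = "G")
  prefix <- file.path(tempdir(), "maf_panel")
  write_plink(genotype_panel(dos, snps), prefix)
  panel <- read_genotype_panel(prefix, maf_min = 0.05)
  expect_equal(ncol(panel$dosages), 5)
  expect_false("rs6" %in% panel$snps$rsid)
})

test_that("missing PLINK member and monomorphic panels error informatively", {
  panel <- tiny_panel(n = 10, p = 3, seed = 5)
  prefix <- file.path(tempdir(), "err_panel")
  write_plink(panel, prefix)
  file.remove(paste0(prefix, ".bim"))
  expect_error(read_plink(prefix), "bim")
  prefix2 <- file.path(tempdir(), "mono_panel")
  mono <- genotype_panel(matrix(2, nrow = 10, ncol = 2),
                         data.frame(rsid = c("a", "b"), chr = "1", pos = 1:2,
                                    counted_allele = "A", other_allele = "G"))
  write_plink(mono, prefix2)
  expect_error(read_genotype_panel(prefix2), "empty")
})

test_that("VCF genotypes are read as ALT-allele counts", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tI1\tI2\tI3",
           "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1",
           "1\t300\trs3\tA\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0")
  path <- file.path(tempdir(), "tiny.vcf")
  writeLines(vcf, path)
  panel <- read_vcf_panel(path)
  expect_equal(unname(panel$dosages[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(panel$dosages[, "rs2"]), c(2, 0, 1))
  expect_equal(panel$snps$counted_allele, c("A", "T", "T"))
  # missing GT mean-imputed from the observed cells
  expect_equal(unname(panel$dosages[2, "rs3"]), 0.5)
})

test_that("GWAS reader fills z from beta columns and p from z", {
  path <- file.path(tempdir(), "sumstats.tsv")
  writeLines(c("SNP\tA1\tA2\tZ\tBETA\tSE\tN",
               "rs1\tA\tG\tNA\t0.02\tNA\t10000",   # z = sqrt(n) beta = 2
               "rs2\tC\tT\t1.96\tNA\tNA\t5000",
               "rs3\tG\tA\tNA\t0.5\t0.25\t5000"),  # z = beta/se = 2
             path)
  g <- read_gwas_summary(path)
  expect_equal(g$snp$z, c(2, 1.96, 2), tolerance = 1e-12)
  expect_equal(g$snp$p[2], 2 * pnorm(-1.96), tolerance = 1e-12)
  # every retained row's z agrees with an independent per-row recomputation
  oracle <- c(sqrt(10000) * 0.02, 1.96, 0.5 / 0.25)
  expect_equal(g$snp$z, oracle, tolerance = 1e-12)
})

test_that("GWAS reader drops unusable rows and errors without effect columns", {
  path <- file.path(tempdir(), "sumstats2.tsv")
  writeLines(c("SNP\tA1\tA2\tBETA\tSE", "rs1\tA\tG\t0.1\t0.05",
               "rs2\tC\tT\t0.1\tNA"), path)
  expect_message(g <- read_gwas_summary(path), "dropped")
  expect_equal(nrow(g$snp), 1)
  path2 <- file.path(tempdir(), "sumstats3.tsv")
  writeLines(c("SNP\tA1\tA2\tP", "rs1\tA\tG\t0.5"), path2)
  expect_error(read_gwas_summary(path2), "effect")
})

test_that("allele harmonization flips, drops and is idempotent", {
  w <- expression_weights(data.frame(
    gene = "g1", rsid = c("rs1", "rs2", "rs3"),
    effect_allele = c("G", "A", "A"), other_allele = c("A", "G", "G"),
    weight = c(0.5, 0.3, 0.2)))
  gw <- gwas_summary(data.frame(
    rsid = c("rs1", "rs2", "rs3"), a1 = c("A", "A", "C"),
    a2 = c("G", "G", "T"), z = c(2, 1, 3), n = 1000))
  panel <- tiny_panel(n = 30, p = 3, seed = 2,
                      counted = c("A", "A", "A"), other = c("G", "G", "G"))
  h <- harmonize_alleles(w, gw, panel)
  # rs1: GWAS effect allele equals the weight's other allele -> z flipped
  expect_equal(h$gwas$snp$z[h$gwas$snp$rsid == "rs1"], -2)
  expect_equal(h$gwas$snp$z[h$gwas$snp$rsid == "rs2"], 1)
  # rs3 alleles (C,T) vs (A,G): irreconcilable, dropped
  expect_false("rs3" %in% h$gwas$snp$rsid)
  # panel counted allele mismatching the weight effect allele -> dosage flipped
  expect_equal(unname(h$panel$dosages[, "rs1"]),
               unname(2 - panel$dosages[, "rs1"]))
  # idempotence
  h2 <- harmonize_alleles(h$weights, h$gwas, h$panel)
  expect_equal(h2$gwas$snp, h$gwas$snp)
  expect_equal(h2$panel$dosages, h$panel$dosages)
})

test_that("harmonization of a scrambled fixture matches a brute-force oracle", {
  set.seed(9)
  p <- 40
  eff <- sample(c("A", "C"), p, replace = TRUE)
  oth <- ifelse(eff == "A", "G", "T")
  w <- expression_weights(data.frame(
    gene = "g1", rsid = paste0("rs", 1:p), effect_allele = eff,
    other_allele = oth, weight = rnorm(p)))
  swap <- sample(c(TRUE, FALSE), p, replace = TRUE)
  z0 <- rnorm(p)
  gw <- gwas_summary(data.frame(
    rsid = paste0("rs", 1:p),
    a1 = ifelse(swap, oth, eff), a2 = ifelse(swap, eff, oth),
    z = z0, n = 1000))
  panel <- tiny_panel(n = 25, p = p, seed = 4, counted = eff, other = oth)
  h <- harmonize_alleles(w, gw, panel)
  # brute force: align every SNP by hand
  oracle <- ifelse(swap, -z0, z0)
  expect_equal(h$gwas$snp$z, oracle[match(h$gwas$snp$rsid, paste0("rs", 1:p))])
  expect_equal(nrow(h$gwas$snp), p)
})

test_that("drop_ambiguous removes A/T and C/G SNPs", {
  w <- expression_weights(data.frame(
    gene = "g1", rsid = c("rs1", "rs2"),
    effect_allele = c("A", "A"), other_allele = c("T", "G"),
    weight = c(0.5, 0.5)))
  gw <- gwas_summary(data.frame(rsid = c("rs1", "rs2"), a1 = "A",
                                a2 = c("T", "G"), z = c(1, 1), n = 100))
  panel <- tiny_panel(n = 30, p = 2, seed = 2, counted = c("A", "A"),
                      other = c("T", "G"))
  h <- harmonize_alleles(w, gw, panel, drop_ambiguous = TRUE)
  expect_equal(h$gwas$snp$rsid, "rs2")
  expect_equal(h$dropped$n[h$dropped$reason == "ambiguous"], 1)
})

test_that("signature TSV round trip is exact and malformed input errors", {
  S <- signature_matrix(matrix(rnorm(6), 3, 2,
                               dimnames = list(c("g1", "g2", "g3"),
                                               c("ctA", "ctB"))))
  path <- file.path(tempdir(), "sig.tsv")
  write_signature(S, path)
  back <- read_signature(path)
  expect_equal(unclass(back), unclass(S), tolerance = 1e-12)

  writeLines(c("gene\tctA\tctB", "g1\t1\t2", "g1\t3\t4"),
             file.path(tempdir(), "dup.tsv"))
  expect_error(read_signature(file.path(tempdir(), "dup.tsv")), "uplicate")
  writeLines(c("gene\tctA", "g1\t1"), file.path(tempdir(), "one.tsv"))
  expect_error(read_signature(file.path(tempdir(), "one.tsv")), "cell-type")
})

test_that("an LM22-shaped random signature validates with finite conditioning", {
  set.seed(2)
  S <- matrix(abs(rnorm(547 * 22)), 547, 22,
              dimnames = list(sprintf("g%03d", 1:547), sprintf("ct%02d", 1:22)))
  sig <- signature_matrix(S)
  ev <- eigen(crossprod(sig), symmetric = TRUE, only.values = TRUE)$values
  expect_true(is.finite(ev[1] / ev[22]))
  w <- expression_weights(data.frame(
    gene = sprintf("g%03d", 1:100), rsid = paste0("rs", 1:100),
    effect_allele = "A", other_allele = "G", weight = rnorm(100)))
  tw <- transform_weights(w, sig)
  expect_true(is.finite(tw$condition_number))
})

test_that("weight table round trip keeps entries and gene stats", {
  w <- expression_weights(
    data.frame(gene = c("g1", "g1", "g2"), rsid = c("rs1", "rs2", "rs3"),
               effect_allele = "A", other_allele = "G",
               weight = c(0.5, -0.2, 1)),
    gene_stats = data.frame(gene = c("g1", "g2"), cv_r2 = c(0.3, 0.1),
                            cv_pvalue = c(1e-5, 0.2), fdr_q = c(2e-5, 0.2)))
  path <- file.path(tempdir(), "w.tsv")
  write_weights(w, path)
  back <- read_weights(path)
  expect_equal(back$entries$weight, w$entries$weight)
  expect_equal(sort(back$gene_stats$cv_r2), sort(w$gene_stats$cv_r2))
})
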