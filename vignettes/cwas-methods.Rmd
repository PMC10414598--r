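---
title: "Genetically regulated cell-type proportions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetically regulated cell-type proportions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-type composition of a tissue is both heritable and disease-relevant,
but observed proportions (from single-cell assays or bulk deconvolution)
are confounded by disease status, treatment and environment. The component
of a cell type's proportion that is predictable from germline genotypes —
its *genetically regulated proportion* (GRP) — is fixed at conception, so
an association between a GRP and a trait is far less exposed to reverse
causation. `cwas` estimates GRPs and tests their trait associations using
only GWAS summary statistics, a reference genotype panel, cis-eQTL
expression weights and a cell-type signature matrix.

## Model

Three linear stages compose the framework.

**Imputation.** For signature gene $g$ in tissue $t$, expression is
imputed from cis genotypes as $\hat B_{t} = X \hat\beta_t$, where
$\hat\beta_t$ are sparse elastic-net weights over SNPs within 1 Mb of each
gene's TSS. Only cis effects are modelled: trans-eQTL effects are too
weakly estimated at current reference sizes to contribute usable weights.

**Deconvolution.** With a signature matrix $S_t \in \mathbb{R}^{G \times
C}$ of mean cell-type-specific expression of the $G$ signature genes, the
GRP matrix is the unconstrained least-squares solution of
$\hat B_t \approx \hat F_t S_t^\top$:
$$\hat F_t = \hat B_t S_t (S_t^\top S_t)^{-1}.$$
No non-negativity or sum-to-one constraint is imposed: with only summary
statistics downstream there is no tractable closed-form test statistic
under such constraints, and imputed expression (often covariate-adjusted)
is not sign-definite anyway. Unconstrained GRPs correlate well with
constrained deconvolution estimates in practice, and the association test
below only needs them up to location and scale.

**Association.** The trait model is $Y = \sum_c \hat F_{(\cdot,c)}
\gamma_c + \eta$. When individual-level data are unavailable, the marginal
effect of cell type $c$ is estimated indirectly from the GWAS z-scores
$z_p$. Writing $A = (S^\top S)^{-1}$ and $M = \hat\beta\, S A$ (a SNP ×
cell-type matrix: the contribution of one allele copy to each GRP), the
standardised statistic is the burden-style sum
$$z_c \;\approx\; \frac{\sum_p \mathrm{sd}(X_p)\, z_p\, M_{p,c}}
{\mathrm{sd}(\hat F_c)},$$
where both standard deviations are estimated on the same reference panel
(they must refer to one population, since they jointly calibrate the
statistic's scale). The approximation assumes any single SNP or single
GRP explains a small fraction of trait variance; a diagnostic warns when
$|z_p| > 37$. Under the null, $z_c$ is standard normal; with orthogonal
standardized genotypes this is exact up to Monte-Carlo error, and LD
between weighted SNPs is carried through $M$. Two-sided p-values are
Bonferroni-corrected over the testable cell types within each tissue.

Identities worth knowing (all tested): rescaling $S \to kS$ leaves $z_c$
unchanged; negating one signature column flips only that cell type's
sign; with one SNP, one gene and one cell type the statistic collapses to
$z_c = z_p$; and for every individual the $\hat F$ row equals the
ordinary least-squares fit of their imputed expression on the signature
columns.

## Parameters that matter

* **Elastic-net mixing** `alpha = 0.5` with the penalty chosen by 10-fold
  cross-validation (`cv.glmnet`), the standard compromise for correlated
  cis-SNPs.
* **Cis window** 1 Mb either side of the TSS, boundary inclusive.
* **MAF filter** 0.05: weights and panels are restricted to common SNPs.
* **Gene quality filters**: Benjamini–Hochberg q < 0.05 on the CV
  correlation p-values over all trained genes in the tissue, then CV
  accuracy at or above the median of the FDR-passing genes. "At or above"
  rather than "strictly above" keeps ties stable; the comparison
  population is configurable (`median_over`). Imputation accuracy is
  defined as the squared correlation between out-of-fold predictions and
  observed residualized expression — out-of-fold rather than in-sample,
  so it estimates the replication accuracy the association stage relies
  on.
* **Signature size**: at least 50 shared signature genes are required per
  tissue (`min_genes`); fewer genes make $S^\top S$ and
  $\mathrm{sd}(\hat F_c)$ unstable. `force = TRUE` downgrades the error
  to a warning.
* **Conditioning**: $A$ is computed by a symmetric positive-definite
  solve; when $\mathrm{cond}(S^\top S)$ exceeds `cond_max` (default 1e8)
  the transform errors, advising a revised gene set — or, with
  `allow_pseudoinverse = TRUE`, falls back to an eigen pseudo-inverse
  with a warning.
* **Cell-count filter**: cell types with ≤ 50 cells are dropped before
  signature curation; means over fewer cells are too unstable.
* **Down-sampling**: `downsample_z` rescales $z/\sqrt R$ to emulate a
  study of $1/R$ the sample size.

## Allele harmonization

All joins are by rsID. Everything is oriented to the weight set's effect
allele: GWAS z-scores are sign-flipped when the GWAS effect allele equals
the weight's other allele, and panel dosages are flipped ($2-d$) when the
counted allele mismatches. Allele pairs that neither match nor swap are
dropped and counted; alleles are never strand-flipped. Strand-ambiguous
(A/T, C/G) SNPs are retained and matched by exact pair — conservative,
since a silent strand flip on an ambiguous SNP would corrupt the sign of
its contribution — with `drop_ambiguous = TRUE` available. Sporadic
missing dosages are mean-imputed per SNP; SNPs missing from the GWAS
contribute zero to the burden sum rather than being dropped and
renormalized, which would silently change the null variance. The
harmonization is idempotent.

## Signature curation

Signature genes are selected by one-vs-rest differential expression per
cell type (Wilcoxon rank-sum or one-way ANOVA), Bonferroni-corrected over
genes × cell types at α = 0.05. A gene qualifies for a cell type when it
is significant there, upregulated (mean above the rest), and upregulated-
significant in *no other* cell type; the uniqueness rule counts only
upregulated hits, because a genuine marker of one type is automatically
significantly depleted in every other type's comparison. The hurdle-model
DE frameworks built for raw droplet counts are deliberately not
reproduced here; the module expects normalized (e.g. log-CPM), adequately
deep or denoised input and never re-normalizes. Selected genes are
intersected with the imputable gene universe, and the signature entry is
the plain mean over the cells of each type. Minimum log-fold-change
thresholds are exposed (`min_logfc`) rather than hard-coded, since
sensible values vary by dataset and platform.

## The simulation harness

The simulator exists to answer one question: does the summary-statistic
test recover the individual-level answer at realistic scale? It generates
every layer of a study:

* **Genotypes** — two haplotypes per individual, each a latent
  standard-Gaussian AR-1 field (default correlation 0.3) thresholded at
  the allele-frequency quantile, MAF ~ U(0.05, 0.5). This reproduces the
  two features the statistic is sensitive to — local LD and an allele
  frequency spectrum — while remaining fully synthetic and seedable. It
  does **not** model long-range LD, population structure, or realistic
  recombination maps, so passing tests say nothing about confounding by
  stratification in real GWAS.
* **Weights and signature** — 1–5 cis SNPs per gene with N(0,1) effects
  drawn within per-gene SNP blocks; the signature is |N(0,1)| plus a
  marker boost with genes assigned round-robin to cell types, redrawn
  until cond(S'S) < 1e4. The boost gives each cell type a marker set, the
  shared non-marker mass keeps GRP columns realistically correlated.
* **Phenotype** — $Y = \hat F_{c^*}\gamma + \varepsilon$ with unit noise
  variance and $\gamma$ set so the causal GRP explains exactly the target
  $h^2$ of trait variance (grid 0.01–0.09 for power; 0 for the null).
* **GWAS** — vectorized per-SNP OLS with intercept and optional
  covariates (the simulated data carry no stratification, so covariates
  default to none).

Study conditions are fixed at 5,000 individuals, 2,000 SNPs, 100
signature genes, 8 cell types, 200 replicates per stratum (600 for the
null design) — a size chosen so a full calibration run completes in
minutes on one CPU while keeping the binomial Monte-Carlo error on a 5%
rate near one percentage point. The known-signature-fraction masking
(0.5–1.0) is applied to the signature *used by the test*; the
data-generating signature stays complete, mirroring the practical
situation where single-cell-derived signatures are incomplete.

Within one harness call the panel, weights and signature are generated
once and reused across all strata — the design mimics a single reference
sample serving a whole experiment — while phenotype noise and the gene
mask are redrawn every replicate (`fresh_genotypes = TRUE` redraws
everything per stratum). All randomness derives hierarchically from one
master seed; identical seeds give byte-identical reports.

**Cross-tissue null.** For type-I error the phenotype is driven by a cell
type of an independent second tissue, and the first tissue is tested. The
two tissues are placed on *separate chromosomes* (the AR-1 field restarts
at the boundary) with disjoint gene sets. This is deliberate: with both
tissues interleaved on one chromosome, residual LD across gene-block
boundaries induces a small but fixed genetic correlation between the two
tissues' GRPs, the null hypothesis is then genuinely false, and rejection
rates measure that leakage rather than the test's calibration. Separate
chromosomes are also the realistic reading of "independent tissues":
different tissues' signature genes are largely different loci.

## Numerical policy

* $A$ via Cholesky (`chol2inv`); eigen pseudo-inverse only on explicit
  opt-in.
* Standard deviations use denominator $n-1$ throughout (panel dosages and
  GRPs alike).
* Imputed expression enters deconvolution uncentered — the estimator
  contains no centering term, and $\mathrm{sd}(\hat F_c)$ is unaffected
  by location shifts.
* Constant dosage columns in the GWAS get $z = 0$, $p = 1$ and a flag; a
  covariate set that explains the phenotype perfectly nulls every test.
* Residualized expression is standardized to unit variance before
  elastic-net fitting (the scale factor is recorded), making weights
  comparable across genes.
* Ranking ties break by smallest p, then largest |z|, then cell-type
  name.
* Degenerate cell types ($\mathrm{sd}(\hat F_c) = 0$) are flagged
  untestable and omitted from results with a warning.

## Design choices made where the design was open

* **FDR population**: q-values are computed over all trained genes per
  tissue, not only converged models.
* **Gene-to-cell-type assignment** (for the enrichment test) offers both
  the raw argmax and the per-cell-type z-scored argmax; ties break
  lexicographically and are flagged.
* **Binomial enrichment** is two-sided by default so both enrichment and
  depletion register; one-sided tests are available.
* **Trait–trait correlations** use the z-scores of *all* testable cell
  types, significant or not, with pairwise complete cases (never
  zero-filling missing combinations).
* **PEER-style expression factors** are not estimated internally;
  covariates enter as a precomputed matrix.
* The permutation-based variant of the association test (for strongly
  correlated cell types) is not implemented; its interface is reserved.

## What the calibration shows — and what it cannot

The packaged acceptance study verifies, on the synthetic conditions
above: ≥ 98% detection of the causal cell type across the h² grid with
the complete signature; the causal cell type ranked first in the large
majority of replicates from h² = 0.04; sign agreement between $z_{c^*}$
and the simulated effect among significant calls; per-cell-type type-I
error at the nominal 5% in the cross-tissue null; power monotone in
signature completeness; and r > 0.99 agreement between the
summary-statistic $z_c$ and individual-level OLS z-scores. None of this
certifies behaviour under population stratification, mis-specified
signatures, cross-ancestry weight transfer, or genuine trans effects —
the known limitations of the framework.
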