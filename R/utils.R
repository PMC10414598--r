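# hierarchical seeding: child seeds drawn deterministically from a parent
# seed, kept within 32-bit integer range
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# sparse SNP x gene weight matrix aligned to given rsid/gene orderings
weights_as_matrix <- function(weights, rsids = NULL, genes = NULL) {
  e <- weights$entries
  if (is.null(rsids)) rsids <- unique(e$rsid)
  if (is.null(genes)) genes <- unique(e$gene)
  e <- e[e$rsid %in% rsids & e$gene %in% genes, , drop = FALSE]
  Matrix::sparseMatrix(i = match(e$rsid, rsids), j = match(e$gene, genes),
                       x = e$weight, dims = c(length(rsids), length(genes)),
                       dimnames = list(rsids, genes))
}
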