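# Small fixture builders shared across test files. Everything is generated
# in code at test time; no stored binary data.

# random dosage panel with simple SNP metadata
tiny_panel <- function(n = 20, p = 6, seed = 1, chr = "1",
                       counted = rep("A", p), other = rep("G", p)) {
  set.seed(seed)
  dos <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.5)[rep(seq_len(p), each = n)]),
                nrow = n)
  snps <- data.frame(rsid = paste0("rs", seq_len(p)), chr = chr,
                     pos = seq_len(p) * 1000L, counted_allele = counted,
                     other_allele = other, stringsAsFactors = FALSE)
  genotype_panel(dos, snps, sample_ids = paste0("s", seq_len(n)))
}

# one complete small synthetic study: panel, weights, signature, imputed
# expression, transformed weights, GRPs
tiny_study <- function(n = 500, n_snps = 300, n_genes = 60, n_celltypes = 4,
                       seed = 1, ld = 0.3) {
  spec <- simulation_spec(n_individuals = n, n_snps = n_snps,
                          n_genes = n_genes, n_celltypes = n_celltypes,
                          ld = ld, seed = seed)
  seeds <- cwas:::derive_seeds(seed, 2)
  panel <- simulate_genotypes(spec, seed = seeds[1])
  sim <- simulate_weights_and_signature(spec, panel, seed = seeds[2])
  b <- impute_expression(panel, sim$weights)
  tw <- transform_weights(sim$weights, sim$signature)
  grp <- deconvolve(b, tw, sim$signature)
  list(spec = spec, panel = panel, weights = sim$weights,
       signature = sim$signature, genes = sim$genes, b = b, tw = tw,
       grp = grp)
}

# labelled single-cell fixture with planted per-type marker genes
marker_sc_fixture <- function(n_types = 3, cells_per_type = 80,
                              markers_per_type = 20, n_noise_genes = 40,
                              effect = 5, seed = 1) {
  set.seed(seed)
  types <- LETTERS[seq_len(n_types)]
  cell_type <- rep(types, each = cells_per_type)
  n_cells <- length(cell_type)
  G <- n_types * markers_per_type + n_noise_genes
  expr <- matrix(rnorm(n_cells * G), nrow = n_cells)
  marker_of <- rep(c(types, NA), c(rep(markers_per_type, n_types), n_noise_genes))
  for (g in seq_len(G)) {
    if (!is.na(marker_of[g]))
      expr[cell_type == marker_of[g], g] <- expr[cell_type == marker_of[g], g] + effect
  }
  colnames(expr) <- sprintf("g%03d", seq_len(G))
  list(le = labeled_expression(expr, cell_type),
       marker_of = setNames(marker_of, colnames(expr)))
}
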