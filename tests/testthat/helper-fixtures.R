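# Small in-code builders used across test files.

# A CPM-scale matrix from a named list of per-type per-gene cell values.
# `values` is a genes x cells matrix; annotation assigns cells to types.
toy_matrix <- function(values, genes, cells, scale = "cpm") {
  m <- matrix(values, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, cells))
  as_expression_matrix(m, scale = scale)
}

# Profile built directly from per-type means with `n_cells` cells each,
# every cell carrying the type mean (so detection is 1 where mean > 0).
profile_from_means <- function(means, n_cells = 5L) {
  # means: genes x types matrix
  genes <- rownames(means)
  types <- colnames(means)
  cells <- as.vector(outer(seq_len(n_cells), types,
                           function(i, t) paste0(t, "_c", i)))
  ann <- cell_annotation(cells, rep(types, each = n_cells))
  vals <- means[, rep(types, each = n_cells), drop = FALSE]
  colnames(vals) <- cells
  m <- as_expression_matrix(vals, scale = "cpm")
  summarise_cell_types(m, ann, genes)
}

# Default small random fixture for oracle comparisons.
random_fixture <- function(seed, n_cell_types = 5, cells_per_type = 40,
                           n_genes = 80, n_pairs = 12, ...) {
  generate_fixture(fixture_config(
    n_cell_types = n_cell_types, cells_per_type = cells_per_type,
    n_genes = n_genes, n_pairs = n_pairs, seed = seed, ...))
}

fixture_profile <- function(fx) {
  m <- normalise_cpm(fx$expression)
  summarise_cell_types(m, fx$annotation,
                       unique(c(fx$pairs$ligand, fx$pairs$receptor)))
}

edge_key_str <- function(edges) {
  paste(edges$sender, toupper(edges$ligand), toupper(edges$receptor),
        edges$receiver, sep = "|")
}
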