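## Shared fixture builders; everything is generated in code.

make_counts <- function(values, cells = NULL, genes = NULL) {
  values <- as.matrix(values)
  cells <- cells %||% sprintf("c%02d", seq_len(nrow(values)))
  genes <- genes %||% sprintf("g%02d", seq_len(ncol(values)))
  expression_matrix(values, gene_ids = genes, cell_ids = cells,
                    layer_tag = "counts")
}

make_norm <- function(values, cells = NULL, genes = NULL) {
  values <- as.matrix(values)
  cells <- cells %||% sprintf("c%02d", seq_len(nrow(values)))
  genes <- genes %||% sprintf("g%02d", seq_len(ncol(values)))
  expression_matrix(values, gene_ids = genes, cell_ids = cells,
                    layer_tag = "normalized")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Small synthetic population used by several integration tests.
small_population <- function(seed = 7, n = 120,
                             props = c(0.4, 0.4, 0.2)) {
  cfg <- synth_config(
    conditions = list(pop = c(immunogenic = props[1],
                              tolerogenic = props[2],
                              ambivalent = props[3])),
    n_cells_per_condition = n, n_signature_genes = 60,
    n_background_genes = 40, seed = seed)
  list(config = cfg, population = generate_population(cfg),
       axes = synth_axes(cfg))
}
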