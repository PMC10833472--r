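# In-code fixtures shared across test files.

# CountMatrix from a dense integer matrix with auto ids.
toy_cm <- function(m, gene_ids = NULL, cell_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("g%02d", seq_len(nrow(m)))
  cell_ids <- cell_ids %||% sprintf("c%02d", seq_len(ncol(m)))
  CountMatrix(m, gene_ids = gene_ids, cell_ids = cell_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NormalizedMatrix directly from a dense value matrix (bypasses counts) for
# unit tests of scoring/DEG arithmetic.
toy_nm <- function(v, gene_ids = NULL, cell_ids = NULL) {
  gene_ids <- gene_ids %||% (rownames(v) %||% sprintf("g%02d", seq_len(nrow(v))))
  cell_ids <- cell_ids %||% (colnames(v) %||% sprintf("c%02d", seq_len(ncol(v))))
  dimnames(v) <- list(gene_ids, cell_ids)
  structure(list(values = methods::as(Matrix::Matrix(v, sparse = TRUE),
                                      "generalMatrix"),
                 gene_ids = gene_ids, cell_ids = cell_ids, scale = 1e4),
            class = "NormalizedMatrix")
}

toy_meta <- function(cell_ids, group, cell_type = "T") {
  data.frame(cell_id = cell_ids, sample_id = "s1",
             group = rep_len(group, length(cell_ids)),
             cell_type = rep_len(cell_type, length(cell_ids)),
             stringsAsFactors = FALSE)
}

# Small simulation used by several modules: one or two cell types, modest
# depth, no injected effects unless supplied.
quick_sim <- function(seed, n_genes = 500,
                      cell_types = list(sim_cell_type("Hep", 100, 100)),
                      ...) {
  simulate_counts(sim_config(n_genes = n_genes, cell_types = cell_types,
                             zonation = list(enabled = FALSE), seed = seed,
                             ...))
}

# A DEG table row in wilcoxon_deg's output shape, for set-algebra tests.
deg_row <- function(gene, cell_type, lfc, significant = TRUE) {
  data.frame(gene = gene, cell_type = cell_type, avg_log2FC = lfc,
             p = 0.001, p_adj = 0.01, pct_aged = 0.5, pct_young = 0.5,
             direction = ifelse(lfc >= 0, "up", "down"),
             significant = significant, stringsAsFactors = FALSE)
}
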