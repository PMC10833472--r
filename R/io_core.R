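# Data model and standard-format I/O shared by all stages.
#
# Counts are stored sparse (Matrix::dgCMatrix) with genes as rows and cells
# as columns, the 10x convention. Classes are lightweight S3 lists in the
# DGEList style.

#' Construct a sparse UMI count matrix container
#'
#' @param counts Matrix-like of non-negative integer UMI counts, genes in
#'   rows and cells in columns.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param cell_ids Character vector of unique cell identifiers (barcodes);
#'   defaults to `colnames(counts)`.
#' @return An object of class `CountMatrix` with fields `counts` (a
#'   `dgCMatrix`), `gene_ids` and `cell_ids`.
#' @export
CountMatrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on counts)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    stop(sprintf("dimension mismatch: counts is %d x %d but %d gene ids and %d cell ids given",
                 nrow(counts), ncol(counts), length(gene_ids), length(cell_ids)))
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers (UMI counts)")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Per-cell total UMI counts
#' @param cm A `CountMatrix`.
#' @return Named numeric vector of column sums.
#' @export
total_umi <- function(cm) Matrix::colSums(cm$counts)

#' Per-cell number of detected genes (count > 0)
#' @param cm A `CountMatrix`.
#' @return Named integer vector.
#' @export
n_genes_detected <- function(cm) Matrix::colSums(cm$counts > 0)

#' Per-cell mitochondrial UMI fraction
#'
#' Mitochondrial genes are identified by an id prefix; annotations vary
#' between assemblies so the prefix is a configuration key.
#'
#' @param cm A `CountMatrix`.
#' @param mito_gene_prefix Gene-id prefix marking mitochondrial genes.
#' @return Named numeric vector in [0, 1] (0 for zero-total cells).
#' @export
pct_mito <- function(cm, mito_gene_prefix = "MT-") {
  mito <- startsWith(cm$gene_ids, mito_gene_prefix)
  tot <- total_umi(cm)
  m <- if (any(mito)) Matrix::colSums(cm$counts[mito, , drop = FALSE]) else rep(0, ncol(cm$counts))
  out <- ifelse(tot > 0, m / tot, 0)
  names(out) <- cm$cell_ids
  out
}

#' Read a 10x-style Matrix Market count triplet
#'
#' Reads `matrix.mtx` (coordinate integer, genes as rows), a gene-id file
#' (one id per line; an optional second symbol column is ignored) and a
#' barcode file.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param genes_path Path to the gene id file (TSV, first column used).
#' @param barcodes_path Path to the barcode file (one id per line).
#' @return A [CountMatrix()].
#' @export
read_counts <- function(mtx_path, genes_path, barcodes_path) {
  for (p in c(mtx_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(genes)) {
    stop(sprintf("format error: matrix declares %d rows but gene file has %d ids",
                 nrow(m), length(genes)))
  }
  if (ncol(m) != length(barcodes)) {
    stop(sprintf("format error: matrix declares %d columns but barcode file has %d ids",
                 ncol(m), length(barcodes)))
  }
  if (any(m@x != round(m@x))) stop("format error: non-integer entries in count matrix")
  CountMatrix(m, gene_ids = genes, cell_ids = barcodes)
}

#' Write a count matrix as a Matrix Market triplet
#'
#' @param cm A [CountMatrix()].
#' @param dir Output directory (created if missing); files are written as
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(cm$counts, paths[1L])
  writeLines(cm$gene_ids, paths[2L])
  writeLines(cm$cell_ids, paths[3L])
  invisible(paths)
}

#' Build a per-cell metadata table with QC statistics
#'
#' @param cm A [CountMatrix()].
#' @param sample_id Per-cell sample id (recycled if length 1).
#' @param group Per-cell age group, each `"young"` or `"aged"`.
#' @param cell_type Optional per-cell type label.
#' @param mito_gene_prefix Prefix identifying mitochondrial gene ids.
#' @return A data.frame with columns `cell_id`, `sample_id`, `group`,
#'   `cell_type`, `n_genes`, `total_umi`, `pct_mito`.
#' @export
make_cell_meta <- function(cm, sample_id, group, cell_type = NA_character_,
                           mito_gene_prefix = "MT-") {
  n <- length(cm$cell_ids)
  group <- rep_len(as.character(group), n)
  bad <- setdiff(unique(group), c("young", "aged"))
  if (length(bad)) stop(sprintf("group must be 'young' or 'aged'; got: %s",
                                paste(bad, collapse = ", ")))
  data.frame(cell_id = cm$cell_ids,
             sample_id = rep_len(as.character(sample_id), n),
             group = group,
             cell_type = rep_len(as.character(cell_type), n),
             n_genes = as.integer(n_genes_detected(cm)),
             total_umi = as.integer(total_umi(cm)),
             pct_mito = as.numeric(pct_mito(cm, mito_gene_prefix)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write the cell-metadata TSV
#'
#' Tab-separated with header; required columns `cell_id`, `sample_id`,
#' `group`, optional `cell_type` and QC columns.
#'
#' @param path File path.
#' @return `read_cell_meta`: a data.frame.
#' @export
read_cell_meta <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  for (col in intersect(c("cell_id", "sample_id", "group", "cell_type"),
                        names(meta))) {
    meta[[col]] <- as.character(meta[[col]])
  }
  need <- c("cell_id", "sample_id", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop(sprintf("cell meta missing columns: %s",
                                 paste(miss, collapse = ", ")))
  meta
}

#' @rdname read_cell_meta
#' @param meta A cell-metadata data.frame.
#' @export
write_cell_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter low-quality cells
#'
#' Cells with fewer than `min_genes` detected genes or a mitochondrial UMI
#' fraction of more than `max_pct_mito` are excluded. Both rules are
#' evaluated independently, so a cell can be counted in both failure tallies;
#' `n_pass` is the count of cells failing neither.
#'
#' @param cm A [CountMatrix()].
#' @param meta Cell-metadata data.frame covering all cells in `cm`.
#' @param min_genes Minimum detected genes to keep a cell (kept iff
#'   `n_genes >= min_genes`).
#' @param max_pct_mito Maximum tolerated mitochondrial fraction (kept iff
#'   `pct_mito <= max_pct_mito`; the threshold itself passes).
#' @param mito_gene_prefix Prefix identifying mitochondrial gene ids.
#' @return A list with `counts` (filtered `CountMatrix`), `meta` (filtered
#'   rows, QC columns refreshed) and `report` (a `QCReport` list:
#'   `n_input_cells`, `n_pass_cells`, `n_fail_min_genes`, `n_fail_mito`,
#'   `thresholds`).
#' @export
qc_filter <- function(cm, meta, min_genes = 200, max_pct_mito = 0.05,
                      mito_gene_prefix = "MT-") {
  stopifnot(inherits(cm, "CountMatrix"))
  if (!all(cm$cell_ids %in% meta$cell_id)) {
    stop("meta must cover every cell in the count matrix")
  }
  ng <- n_genes_detected(cm)
  pm <- pct_mito(cm, mito_gene_prefix)
  fail_genes <- ng < min_genes
  fail_mito <- pm > max_pct_mito
  keep <- !fail_genes & !fail_mito
  report <- structure(list(
    n_input_cells = length(keep),
    n_pass_cells = sum(keep),
    n_fail_min_genes = sum(fail_genes),
    n_fail_mito = sum(fail_mito),
    thresholds = list(min_genes = min_genes, max_pct_mito = max_pct_mito,
                      mito_gene_prefix = mito_gene_prefix)), class = "QCReport")
  if (!any(keep)) {
    warning("qc_filter removed every cell; returning an empty matrix")
  }
  out <- CountMatrix(cm$counts[, keep, drop = FALSE],
                     gene_ids = cm$gene_ids, cell_ids = cm$cell_ids[keep])
  meta <- meta[match(out$cell_ids, meta$cell_id), , drop = FALSE]
  meta$n_genes <- as.integer(ng[keep])
  meta$total_umi <- as.integer(total_umi(out))
  meta$pct_mito <- as.numeric(pm[keep])
  row.names(meta) <- NULL
  list(counts = out, meta = meta, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QC: %d cells in, %d pass (%d fail min_genes=%d, %d fail mito>%g)\n",
              x$n_input_cells, x$n_pass_cells, x$n_fail_min_genes,
              x$thresholds$min_genes, x$n_fail_mito, x$thresholds$max_pct_mito))
  invisible(x)
}

#' Log1p counts-per-10k normalization
#'
#' `value(g, c) = log(1 + count(g, c) * scale / total_umi(c))` with natural
#' log; the standard log1p-CP10K transform used by all downstream stages.
#'
#' @param cm A [CountMatrix()].
#' @param scale Per-cell scale factor (default 1e4).
#' @return A `NormalizedMatrix`: list with sparse `values`, `gene_ids`,
#'   `cell_ids` and the `scale` used.
#' @export
normalize_log1p_cp10k <- function(cm, scale = 1e4) {
  stopifnot(inherits(cm, "CountMatrix"))
  tot <- total_umi(cm)
  if (any(tot == 0)) {
    stop("cells with zero total UMI present; run qc_filter first")
  }
  v <- cm$counts
  v@x <- log1p(v@x * scale / rep.int(tot, diff(v@p)))
  structure(list(values = v, gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
                 scale = scale), class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix (log1p-CP%g): %d genes x %d cells\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)
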