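# Gene-set module scores with binned expression controls, young-group
# cell-identity marker sets, identity drift between age groups, and
# marker-score hepatocyte zonation assignment.

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name<TAB>description<TAB>gene...`.
#'
#' @param path File path.
#' @return `read_gmt`: a named list of character gene vectors, with the
#'   description line stored in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop(sprintf("malformed GMT line(s): %s",
                             paste(which(bad), collapse = ", ")))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character gene vectors.
#' @param description Optional per-set description column.
#' @export
write_gmt <- function(sets, path, description = names(sets)) {
  lines <- mapply(function(nm, ds, genes)
    paste(c(nm, ds, genes), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' @keywords internal
# Equal-frequency expression bins over genes (by mean expression rank).
.expression_bins <- function(gene_means, n_bins) {
  n <- length(gene_means)
  if (n_bins > n) stop("n_bins must not exceed the number of genes")
  r <- rank(gene_means, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

#' Binned-control gene-set module score
#'
#' Genes are placed into `n_bins` equal-frequency bins by mean expression
#' across cells. For each set gene, `n_ctrl` control genes are drawn
#' uniformly with replacement from its bin; the score of a cell is the mean
#' over set genes of (set-gene value minus the mean value of its drawn
#' controls). `n_ctrl = Inf` uses every gene in the bin (deterministic).
#'
#' @param nm A `NormalizedMatrix`.
#' @param genes Character vector of set genes (or a single-set list).
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100); `Inf` for
#'   the whole bin.
#' @param seed Integer seed for the control draws.
#' @param set_name Label stored on the result.
#' @return A `ScoreVector`: named numeric scores per cell with attributes
#'   `set_name` and `parameters`.
#' @export
module_score <- function(nm, genes, n_bins = 24, n_ctrl = 100, seed = 1L,
                         set_name = "set") {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (is.list(genes)) genes <- unlist(genes, use.names = FALSE)
  present <- intersect(genes, nm$gene_ids)
  missing <- setdiff(genes, nm$gene_ids)
  if (!length(present)) {
    stop(sprintf("gene set '%s' has no genes in the matrix (missing: %s)",
                 set_name, paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (length(missing)) {
    warning(sprintf("set '%s': %d gene(s) absent from matrix", set_name,
                    length(missing)))
  }
  v <- nm$values
  gene_means <- Matrix::rowMeans(v)
  bins <- .expression_bins(gene_means, n_bins)
  names(bins) <- nm$gene_ids

  set.seed(derive_seed(seed, paste0("module_score:", set_name)))
  set_vals <- as.matrix(v[present, , drop = FALSE])
  ctrl_means <- matrix(0, length(present), ncol(v))
  for (i in seq_along(present)) {
    bin_genes <- nm$gene_ids[bins == bins[present[i]]]
    ctrl <- if (is.infinite(n_ctrl)) bin_genes
            else bin_genes[sample.int(length(bin_genes), n_ctrl, replace = TRUE)]
    ctrl_means[i, ] <- Matrix::colMeans(v[ctrl, , drop = FALSE])
  }
  score <- colMeans(set_vals - ctrl_means)
  names(score) <- nm$cell_ids
  structure(score, set_name = set_name,
            parameters = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
            class = c("ScoreVector", "numeric"))
}

#' Young-group cell-identity marker sets
#'
#' For each cell type, a one-vs-rest Wilcoxon rank-sum marker test on young
#' cells only; genes passing `avg_log2FC >= lfc_min` and adjusted
#' `p <= padj_max` are ranked by fold change (descending, ties broken by
#' gene id) and the top `top_n` retained.
#'
#' @param nm A `NormalizedMatrix`.
#' @param meta Cell metadata with `cell_id`, `group`, `cell_type`.
#' @param top_n Markers kept per type (default 50).
#' @param lfc_min Minimum avg_log2FC (default 0.5).
#' @param padj_max Maximum BH-adjusted p (default 0.05).
#' @param min_cells Cell types with fewer young cells are skipped with a
#'   warning (default 3).
#' @return Named list of character marker vectors, one per retained type.
#' @export
young_identity_sets <- function(nm, meta, top_n = 50, lfc_min = 0.5,
                                padj_max = 0.05, min_cells = 3) {
  young <- meta[meta$group == "young", , drop = FALSE]
  if (!nrow(young)) stop("no young cells in meta")
  types <- sort(unique(young$cell_type))
  sets <- list()
  for (ct in types) {
    in_type <- young$cell_id[young$cell_type == ct]
    rest <- young$cell_id[young$cell_type != ct]
    if (length(in_type) < min_cells) {
      warning(sprintf("cell type '%s' has < %d young cells; excluded",
                      ct, min_cells))
      next
    }
    tab <- .rank_sum_table(nm, in_type, rest, min_pct = 0.1,
                           lfc_prefilter = lfc_min)
    tab <- tab[tab$avg_log2FC >= lfc_min & tab$p_adj <= padj_max, ,
               drop = FALSE]
    tab <- tab[order(-tab$avg_log2FC, tab$gene), , drop = FALSE]
    if (nrow(tab) < top_n) {
      warning(sprintf("cell type '%s': only %d of %d requested markers pass",
                      ct, nrow(tab), top_n))
    }
    sets[[ct]] <- utils::head(tab$gene, top_n)
  }
  sets
}

#' Cell-identity drift between age groups
#'
#' Scores each identity set over all cells with [module_score()] and
#' compares young vs aged scores per cell type with a two-sided Wilcoxon
#' rank-sum test; BH adjustment across cell types.
#'
#' @param nm A `NormalizedMatrix`.
#' @param meta Cell metadata with `cell_id`, `group`, `cell_type`.
#' @param sets Named list from [young_identity_sets()].
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return data.frame with per-type mean scores, drift (aged minus young),
#'   `p` and BH-adjusted `p_adj`.
#' @export
identity_drift <- function(nm, meta, sets, n_bins = 24, n_ctrl = 100,
                           seed = 1L) {
  rows <- lapply(names(sets), function(ct) {
    sc <- module_score(nm, sets[[ct]], n_bins = n_bins, n_ctrl = n_ctrl,
                       seed = seed, set_name = ct)
    cells <- meta[meta$cell_type == ct, , drop = FALSE]
    sy <- sc[cells$cell_id[cells$group == "young"]]
    sa <- sc[cells$cell_id[cells$group == "aged"]]
    data.frame(cell_type = ct,
               mean_young = mean(sy), mean_aged = mean(sa),
               drift = mean(sa) - mean(sy),
               p = rank_sum_test(sa, sy)$p,
               n_young = length(sy), n_aged = length(sa),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  row.names(out) <- NULL
  out
}

#' Assign hepatocytes to zonation compartments by marker score terciles
#'
#' Computes the axis score d(c) = module_score(PC markers) minus
#' module_score(PP markers) and cuts it at its terciles: below the lower
#' tercile is periportal (PP), above the upper tercile pericentral (PC),
#' everything else (boundaries included) mid-zonal (MZ).
#'
#' @param nm A `NormalizedMatrix`.
#' @param cells Character vector of hepatocyte cell ids.
#' @param pp_set,pc_set Periportal / pericentral marker gene vectors.
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return data.frame with `cell_id`, `score_pp`, `score_pc`, `d`,
#'   `zone` in {"PP", "MZ", "PC"}.
#' @export
zonation_assign <- function(nm, cells, pp_set, pc_set, n_bins = 24,
                            n_ctrl = 100, seed = 1L) {
  if (length(cells) < 3) stop("zonation_assign needs at least 3 hepatocytes")
  if (!length(pp_set) || !length(pc_set)) {
    stop("both PP and PC marker sets must be non-empty")
  }
  sub <- structure(list(values = nm$values[, cells, drop = FALSE],
                        gene_ids = nm$gene_ids, cell_ids = cells,
                        scale = nm$scale), class = "NormalizedMatrix")
  spp <- module_score(sub, pp_set, n_bins, n_ctrl, seed, set_name = "PP")
  spc <- module_score(sub, pc_set, n_bins, n_ctrl, seed, set_name = "PC")
  d <- as.numeric(spc) - as.numeric(spp)
  q <- stats::quantile(d, c(1, 2) / 3, names = FALSE)
  zone <- ifelse(d < q[1L], "PP", ifelse(d > q[2L], "PC", "MZ"))
  data.frame(cell_id = cells, score_pp = as.numeric(spp),
             score_pc = as.numeric(spc), d = d, zone = zone,
             stringsAsFactors = FALSE, row.names = NULL)
}
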