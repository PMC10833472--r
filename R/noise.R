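# Transcriptional-noise pipeline: equal-UMI down-sampling (multivariate
# hypergeometric), group-balanced cell sampling, per-cell distance to the
# (cell type, age group) centroid, aged/young ratio tests and
# noise-correlated gene detection.

#' Down-sample every cell to an equal UMI total
#'
#' Each retained cell's counts are replaced by a without-replacement draw of
#' exactly `target_umi` UMIs from its observed UMIs (multivariate
#' hypergeometric); cells with fewer than `target_umi` total UMIs are
#' dropped. Cells at exactly the target are kept unchanged.
#'
#' @param cm A [CountMatrix()].
#' @param target_umi Target total per cell (>= 1).
#' @param seed Integer seed.
#' @return A [CountMatrix()] whose columns each sum to `target_umi`.
#' @export
downsample_umi <- function(cm, target_umi, seed = 1L) {
  stopifnot(inherits(cm, "CountMatrix"), target_umi >= 1)
  tot <- total_umi(cm)
  keep <- which(tot >= target_umi)
  if (!length(keep)) {
    warning(sprintf("no cell has >= %d UMIs; returning an empty matrix",
                    target_umi))
    return(CountMatrix(cm$counts[, 0, drop = FALSE],
                       gene_ids = cm$gene_ids, cell_ids = character()))
  }
  set.seed(derive_seed(seed, "downsample_umi"))
  m <- cm$counts[, keep, drop = FALSE]
  p <- m@p; ii <- m@i; xx <- m@x
  new_x <- xx
  for (j in seq_along(keep)) {
    lo <- p[j] + 1L; hi <- p[j + 1L]
    if (hi < lo) next
    cnt <- xx[lo:hi]
    n_tot <- sum(cnt)
    if (n_tot == target_umi) next
    # draw target_umi of the n_tot UMIs without replacement; map each drawn
    # UMI index back to its gene via the cumulative count boundaries
    drawn <- sample.int(n_tot, target_umi)
    gene_of <- findInterval(drawn - 1L, cumsum(cnt), left.open = FALSE) + 1L
    new_x[lo:hi] <- tabulate(gene_of, nbins = length(cnt))
  }
  m@x <- as.double(new_x)
  m <- Matrix::drop0(m)
  CountMatrix(m, gene_ids = cm$gene_ids, cell_ids = cm$cell_ids[keep])
}

#' Balance young and aged cell numbers within each cell type
#'
#' Per cell type, `m = min(n_young, n_aged)` cells are sampled uniformly
#' from each group; types with `m < min_cells` are excluded with a warning.
#' When a group already has exactly `m` cells, all of them are selected.
#'
#' @param meta Cell metadata with `cell_id`, `group`, `cell_type`.
#' @param min_cells Minimum per-group size to keep a type (default 20).
#' @param seed Integer seed.
#' @return Character vector of selected cell ids.
#' @export
balance_groups <- function(meta, min_cells = 20, seed = 1L) {
  set.seed(derive_seed(seed, "balance_groups"))
  sel <- character()
  for (ct in sort(unique(meta$cell_type))) {
    young <- meta$cell_id[meta$cell_type == ct & meta$group == "young"]
    aged <- meta$cell_id[meta$cell_type == ct & meta$group == "aged"]
    m <- min(length(young), length(aged))
    if (m < min_cells) {
      warning(sprintf("cell type '%s' has < %d cells in a group; excluded",
                      ct, min_cells))
      next
    }
    pick <- function(x) if (length(x) == m) x else x[sample.int(length(x), m)]
    sel <- c(sel, pick(young), pick(aged))
  }
  sel
}

#' Per-cell transcriptional noise (distance to centroid)
#'
#' On balanced, depth-equalized counts: normalize (log1p-CP10K), restrict to
#' genes detected in at least `gene_min_pct` of the cell type's retained
#' cells, and measure each cell's Euclidean distance to the mean normalized
#' vector of its (cell type, age group).
#'
#' @param cm Balanced and down-sampled [CountMatrix()].
#' @param meta Cell metadata covering the retained cells.
#' @param gene_min_pct Detection fraction for the per-type gene space
#'   (default 0.1).
#' @return `NoiseTable` data.frame: `cell_id`, `cell_type`, `group`,
#'   `noise`, `degenerate` (single-cell group flag); parameters stored as
#'   attributes.
#' @export
transcriptional_noise <- function(cm, meta, gene_min_pct = 0.1) {
  stopifnot(inherits(cm, "CountMatrix"))
  nm <- normalize_log1p_cp10k(cm)
  meta <- meta[match(cm$cell_ids, meta$cell_id), , drop = FALSE]
  rows <- list()
  for (ct in sort(unique(meta$cell_type))) {
    cells <- meta$cell_id[meta$cell_type == ct]
    v <- nm$values[, cells, drop = FALSE]
    det <- Matrix::rowMeans(v > 0) >= gene_min_pct
    v <- v[det, , drop = FALSE]
    grp <- meta$group[match(cells, meta$cell_id)]
    for (g in unique(grp)) {
      gc <- cells[grp == g]
      vg <- as.matrix(v[, gc, drop = FALSE])
      centroid <- rowMeans(vg)
      noise <- sqrt(colSums((vg - centroid)^2))
      rows[[paste(ct, g)]] <- data.frame(
        cell_id = gc, cell_type = ct, group = g, noise = as.numeric(noise),
        degenerate = length(gc) == 1L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  attr(out, "gene_min_pct") <- gene_min_pct
  out
}

#' Aged/young noise ratio per cell type
#'
#' `log2(median aged noise / median young noise)` with a two-sided Wilcoxon
#' rank-sum test on the per-cell noises and BH adjustment across cell
#' types. A zero young median yields an NA ratio with a reason.
#'
#' @param nt A `NoiseTable` from [transcriptional_noise()].
#' @return `NoiseSummary` data.frame: `cell_type`, `log2_ratio`, `p`,
#'   `p_adj`, `n_young`, `n_aged`, `note`.
#' @export
noise_ratio <- function(nt) {
  rows <- lapply(sort(unique(nt$cell_type)), function(ct) {
    x <- nt[nt$cell_type == ct, , drop = FALSE]
    ny <- x$noise[x$group == "young"]
    na_ <- x$noise[x$group == "aged"]
    if (!length(ny) || !length(na_)) {
      stop(sprintf("cell type '%s' lacks one group; balance first", ct))
    }
    my <- stats::median(ny); ma <- stats::median(na_)
    if (my == 0 || ma == 0) {
      return(data.frame(cell_type = ct, log2_ratio = NA_real_, p = NA_real_,
                        n_young = length(ny), n_aged = length(na_),
                        note = sprintf("%s median noise is 0",
                                       if (my == 0) "young" else "aged"),
                        stringsAsFactors = FALSE))
    }
    data.frame(cell_type = ct, log2_ratio = log2(ma / my),
               p = rank_sum_test(na_, ny)$p,
               n_young = length(ny), n_aged = length(na_),
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out[, c("cell_type", "log2_ratio", "p", "p_adj", "n_young", "n_aged",
          "note")]
}

#' Genes whose expression tracks transcriptional noise
#'
#' Per gene, the Pearson correlation between per-cell noise and per-cell
#' normalized expression over one cell type's balanced cells (both age
#' groups pooled); p from the t-distribution transform of r, BH over tested
#' genes. Reported genes satisfy `|r| > r_min` (strict) and `fdr <
#' fdr_max`.
#'
#' @param nm A `NormalizedMatrix` (same cell universe as `nt` or larger).
#' @param nt A `NoiseTable`.
#' @param cell_type Cell type to analyse.
#' @param r_min Correlation threshold, strict (default 0.6).
#' @param fdr_max FDR threshold (default 0.05).
#' @return `NoiseGeneTable` data.frame of passing genes: `gene`,
#'   `pearson_r`, `p`, `fdr`, `direction`; attributes `n_tested` and
#'   `n_constant`.
#' @export
noise_correlated_genes <- function(nm, nt, cell_type, r_min = 0.6,
                                   fdr_max = 0.05) {
  x <- nt[nt$cell_type == cell_type, , drop = FALSE]
  cells <- intersect(x$cell_id, nm$cell_ids)
  if (length(cells) < 3) stop("need >= 3 overlapping cells")
  noise <- x$noise[match(cells, x$cell_id)]
  v <- as.matrix(nm$values[, cells, drop = FALSE])
  sds <- apply(v, 1L, stats::sd)
  keep <- sds > 0 & stats::sd(noise) > 0
  n_constant <- sum(!keep)
  v <- v[keep, , drop = FALSE]
  r <- as.numeric(stats::cor(noise, t(v)))
  n <- length(cells)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fdr <- bh_adjust(p)
  sel <- abs(r) > r_min & fdr < fdr_max
  out <- data.frame(gene = rownames(v)[sel], pearson_r = r[sel],
                    p = p[sel], fdr = fdr[sel],
                    direction = ifelse(r[sel] >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$pearson_r)), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "n_tested") <- length(r)
  attr(out, "n_constant") <- n_constant
  out
}

#' Bin cells by noise rank within each age group
#'
#' Equal-frequency bins by noise rank within group; ties broken
#' deterministically by cell id.
#'
#' @param nt A `NoiseTable` (one cell type).
#' @param n_bins Number of bins (default 20; must not exceed the group
#'   size).
#' @return data.frame `cell_id`, `group`, `bin`.
#' @export
bin_by_noise <- function(nt, n_bins = 20) {
  rows <- lapply(split(nt, nt$group), function(x) {
    n <- nrow(x)
    if (n_bins > n) stop("n_bins must not exceed cells per group")
    o <- order(x$noise, x$cell_id)
    r <- integer(n); r[o] <- seq_len(n)
    data.frame(cell_id = x$cell_id, group = x$group,
               bin = as.integer(ceiling(r * n_bins / n)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Default equal-UMI target for a cell set
#'
#' The minimum post-QC cell total within the analyzed cells, floored at
#' `cap` (cells under the cap are dropped by [downsample_umi()]).
#'
#' @param cm A [CountMatrix()].
#' @param cap Lower cap (default 1000).
#' @return Integer target UMI.
#' @export
default_target_umi <- function(cm, cap = 1000) {
  max(cap, min(total_umi(cm)))
}
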