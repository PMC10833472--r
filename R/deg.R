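# Aging-DEG calling (Wilcoxon rank-sum, Seurat-style fold-change
# convention), BH adjustment, cross-cell-type sharing, 14-class zonation
# overlap modules, and signed overlap with an external signature.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by enumeration of all rank assignments when both groups have at
#' most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_max Largest per-group size for the exact branch (default 8).
#' @return List with `statistic` (U for `x`), `p` and `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && nx <= exact_max && ny <= exact_max) {
    # enumerate rank-sum distribution over all C(nx+ny, nx) assignments
    w <- utils::combn(nx + ny, nx, FUN = sum)
    wx <- u + nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(w <= wx), mean(w >= wx)))
    return(list(statistic = u, p = p, method = "exact"))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p = 1, method = "degenerate"))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p = p, method = "normal")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in [0, 1] (no NA).
#' @return Adjusted p-values (monotone, clipped to <= 1), same order as
#'   input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p))) stop("bh_adjust: NA/NaN p-values not allowed")
  .assert_prob(p, "p")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' @keywords internal
# Rank-sum DEG table between two cell groups on normalized values.
# Group a is the numerator of the fold change (aged, or the in-type group).
# p is computed only for genes passing both the detection and the |lfc|
# prefilter (the tool convention), but the BH denominator is the number of
# detection-passing genes: restricting the adjustment to the lfc-selected
# subset does not control FDR, because a null gene that reaches the lfc
# threshold by chance almost surely has a small p as well (the same
# fluctuation drives both). Untested detected genes count as p = 1.
.rank_sum_table <- function(nm, cells_a, cells_b, min_pct = 0.1,
                            lfc_prefilter = 0.25, exact_max = 8) {
  va <- nm$values[, cells_a, drop = FALSE]
  vb <- nm$values[, cells_b, drop = FALSE]
  ea <- va; ea@x <- expm1(ea@x)
  eb <- vb; eb@x <- expm1(eb@x)
  lfc <- log2(Matrix::rowMeans(ea) + 1) - log2(Matrix::rowMeans(eb) + 1)
  pct_a <- Matrix::rowMeans(va > 0)
  pct_b <- Matrix::rowMeans(vb > 0)
  detected <- pct_a >= min_pct | pct_b >= min_pct
  test <- detected & abs(lfc) >= lfc_prefilter
  idx <- which(test)
  p <- rep(NA_real_, length(idx))
  if (length(idx)) {
    da <- as.matrix(va[idx, , drop = FALSE])
    db <- as.matrix(vb[idx, , drop = FALSE])
    for (i in seq_along(idx)) {
      p[i] <- rank_sum_test(da[i, ], db[i, ], exact_max = exact_max)$p
    }
  }
  n_skip <- sum(detected) - length(idx)
  p_adj <- bh_adjust(c(p, rep(1, n_skip)))[seq_along(p)]
  data.frame(gene = nm$gene_ids[idx],
             avg_log2FC = as.numeric(lfc[idx]),
             p = p, p_adj = p_adj,
             pct_a = as.numeric(pct_a[idx]), pct_b = as.numeric(pct_b[idx]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call aging DEGs for one cell type
#'
#' Aged vs young comparison within a cell type. A gene is tested if detected
#' in at least `min_pct` of either group and `|avg_log2FC| >=
#' lfc_prefilter`, with `avg_log2FC = log2(mean(expm1(aged)) + 1) -
#' log2(mean(expm1(young)) + 1)` on normalized values. Two-sided rank-sum
#' per gene; BH adjustment uses all detection-passing genes as the
#' denominator (prefiltered-out genes enter as p = 1), so the fold-change
#' prefilter does not bias the FDR control. The significant set is
#' `p_adj <= padj_max` and `|avg_log2FC| >= lfc_sig`.
#'
#' @param nm A `NormalizedMatrix`.
#' @param meta Cell metadata with `cell_id`, `group`, `cell_type`.
#' @param cell_type Cell type to analyse.
#' @param min_pct Detection fraction threshold (default 0.1).
#' @param lfc_prefilter Pre-test |avg_log2FC| filter (default 0.25).
#' @param padj_max,lfc_sig Significance thresholds (defaults 0.05, 0.25).
#' @return data.frame of `DEGRecord`s: `gene`, `cell_type`, `avg_log2FC`,
#'   `p`, `p_adj`, `pct_aged`, `pct_young`, `direction`, `significant`.
#' @export
wilcoxon_deg <- function(nm, meta, cell_type, min_pct = 0.1,
                         lfc_prefilter = 0.25, padj_max = 0.05,
                         lfc_sig = 0.25) {
  cells <- meta[meta$cell_type == cell_type, , drop = FALSE]
  aged <- cells$cell_id[cells$group == "aged"]
  young <- cells$cell_id[cells$group == "young"]
  if (length(aged) < 3 || length(young) < 3) {
    stop(sprintf("cell type '%s' needs >= 3 cells per group (%d aged, %d young)",
                 cell_type, length(aged), length(young)))
  }
  tab <- .rank_sum_table(nm, aged, young, min_pct, lfc_prefilter)
  data.frame(gene = tab$gene, cell_type = cell_type,
             avg_log2FC = tab$avg_log2FC, p = tab$p, p_adj = tab$p_adj,
             pct_aged = tab$pct_a, pct_young = tab$pct_b,
             direction = ifelse(tab$avg_log2FC >= 0, "up", "down"),
             significant = tab$p_adj <= padj_max &
               abs(tab$avg_log2FC) >= lfc_sig,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' DEGs shared across cell types
#'
#' Counts, per gene and direction, the cell types in which the gene is a
#' significant DEG with that direction; a gene can appear once as "up" and
#' once as "down" (for different cell types).
#'
#' @param deg_tables Named list of [wilcoxon_deg()] tables (names = cell
#'   types; unnamed tables use their `cell_type` column).
#' @param k_min Minimum number of sharing cell types (default 3).
#' @return data.frame with `gene`, `direction`, `cell_types`
#'   (comma-separated), `k`.
#' @export
shared_degs <- function(deg_tables, k_min = 3) {
  if (length(deg_tables) < k_min) {
    stop(sprintf("need at least k_min = %d DEG tables", k_min))
  }
  recs <- do.call(rbind, lapply(deg_tables, function(t)
    t[t$significant, c("gene", "cell_type", "direction"), drop = FALSE]))
  if (is.null(recs) || !nrow(recs)) {
    return(data.frame(gene = character(), direction = character(),
                      cell_types = character(), k = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(recs$gene, recs$direction, sep = "\r")
  sp <- split(recs$cell_type, key)
  keys <- names(sp)
  k <- lengths(lapply(sp, unique))
  keep <- k >= k_min
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[[`, "", 1L),
    direction = vapply(parts, `[[`, "", 2L),
    cell_types = vapply(sp[keep], function(x)
      paste(sort(unique(x)), collapse = ","), ""),
    k = as.integer(k[keep]), stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$k, out$gene, out$direction), , drop = FALSE]
}

#' @keywords internal
# Canonical enumeration of the 14 overlap module classes: ids 1..7 are the
# non-empty subsets of {PP, MZ, PC} for direction "up" (singletons, pairs,
# triple), ids 8..14 the same subsets for "down".
.module_subsets <- c("PP", "MZ", "PC", "PP+MZ", "PP+PC", "MZ+PC", "PP+MZ+PC")

#' The 14 overlap module classes
#'
#' @return data.frame with `module_id` 1..14, `direction`, `subtypes`.
#' @export
module_classes <- function() {
  data.frame(module_id = 1:14,
             direction = rep(c("up", "down"), each = 7L),
             subtypes = rep(.module_subsets, 2L),
             stringsAsFactors = FALSE)
}

#' Classify zonation DEGs into the 14 overlap modules
#'
#' Each gene significant in at least one hepatocyte subtype is assigned the
#' class (direction, non-empty subset of {PP, MZ, PC} where significant) —
#' 2 directions x 7 subsets = 14 modules. Genes with discordant directions
#' across subtypes are excluded from the modules and reported separately.
#'
#' @param deg_pp,deg_mz,deg_pc [wilcoxon_deg()] tables for the periportal,
#'   mid-zonal and pericentral subtypes.
#' @return List with `modules` (data.frame `gene`, `direction`,
#'   `subtypes`, `module_id`) and `discordant` (data.frame `gene`,
#'   `details`).
#' @export
overlap_modules <- function(deg_pp, deg_mz, deg_pc) {
  tabs <- list(PP = deg_pp, MZ = deg_mz, PC = deg_pc)
  recs <- do.call(rbind, lapply(names(tabs), function(st) {
    t <- tabs[[st]]
    t <- t[t$significant, , drop = FALSE]
    if (!nrow(t)) return(NULL)
    data.frame(gene = t$gene, subtype = st, direction = t$direction,
               stringsAsFactors = FALSE)
  }))
  empty_mod <- data.frame(gene = character(), direction = character(),
                          subtypes = character(), module_id = integer(),
                          stringsAsFactors = FALSE)
  empty_dis <- data.frame(gene = character(), details = character(),
                          stringsAsFactors = FALSE)
  if (is.null(recs) || !nrow(recs)) {
    return(list(modules = empty_mod, discordant = empty_dis))
  }
  cls <- module_classes()
  rows <- lapply(split(recs, recs$gene), function(g) {
    if (length(unique(g$direction)) > 1L) {
      return(data.frame(gene = g$gene[1L],
                        details = paste(g$subtype, g$direction, sep = ":",
                                        collapse = ";"),
                        module_id = NA_integer_, direction = NA_character_,
                        subtypes = NA_character_, stringsAsFactors = FALSE))
    }
    st <- c("PP", "MZ", "PC")[c("PP", "MZ", "PC") %in% g$subtype]
    lab <- paste(st, collapse = "+")
    id <- cls$module_id[cls$direction == g$direction[1L] & cls$subtypes == lab]
    data.frame(gene = g$gene[1L], details = NA_character_, module_id = id,
               direction = g$direction[1L], subtypes = lab,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  modules <- all[!is.na(all$module_id),
                 c("gene", "direction", "subtypes", "module_id"), drop = FALSE]
  modules <- modules[order(modules$module_id, modules$gene), , drop = FALSE]
  discordant <- all[is.na(all$module_id), c("gene", "details"), drop = FALSE]
  row.names(modules) <- row.names(discordant) <- NULL
  list(modules = modules, discordant = discordant)
}

#' Signed overlap between aging DEGs and an external signed signature
#'
#' Intersects by gene id (case-insensitive by default) and classifies each
#' shared gene by sign agreement.
#'
#' @param deg_table A [wilcoxon_deg()] table (significant rows used).
#' @param external data.frame with columns `gene` and `sign` (`"+"`/`"-"`,
#'   or numeric where the sign is taken).
#' @param case_insensitive Match ids case-insensitively (default TRUE).
#' @return List of character vectors `co_up`, `co_down`, `discordant`
#'   (DEG-table gene ids).
#' @export
signed_external_overlap <- function(deg_table, external,
                                    case_insensitive = TRUE) {
  sig <- deg_table[deg_table$significant, , drop = FALSE]
  esign <- external$sign
  if (is.numeric(esign)) esign <- ifelse(esign >= 0, "+", "-")
  key <- function(x) if (case_insensitive) toupper(x) else x
  ext_up <- key(external$gene[esign == "+"])
  ext_dn <- key(external$gene[esign == "-"])
  k <- key(sig$gene)
  hit <- k %in% c(ext_up, ext_dn)
  if (!any(hit)) warning("no overlap between DEGs and external signature")
  deg_up <- sig$direction == "up"
  list(co_up = sig$gene[deg_up & k %in% ext_up],
       co_down = sig$gene[!deg_up & k %in% ext_dn],
       discordant = sig$gene[(deg_up & k %in% ext_dn) |
                               (!deg_up & k %in% ext_up)])
}

#' Read an external signed gene signature (2-column TSV: gene, sign)
#' @param path File path (header optional; detected on first line).
#' @return data.frame with `gene`, `sign`.
#' @export
read_signature <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  header <- identical(tolower(first[1:2]), c("gene", "sign"))
  utils::read.table(path, sep = "\t", header = header,
                    col.names = c("gene", "sign"),
                    stringsAsFactors = FALSE)
}
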