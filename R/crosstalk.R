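# Ligand-receptor interaction scoring with a cell-type-label permutation
# null, per-group significance, and young/aged differential networks.

#' Read a ligand-receptor pair table (2-column TSV: ligand, receptor)
#' @param path File path (header optional; detected).
#' @return data.frame with `ligand`, `receptor`, `pair_id`.
#' @export
read_lr_pairs <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  header <- identical(tolower(first[1:2]), c("ligand", "receptor"))
  tab <- utils::read.table(path, sep = "\t", header = header,
                           col.names = c("ligand", "receptor"),
                           stringsAsFactors = FALSE)
  tab$pair_id <- paste(tab$ligand, tab$receptor, sep = "_")
  tab
}

#' @keywords internal
# Per-(gene, cell type) mean expression and detection fraction for a set of
# cells; labels is a factor of cell-type labels aligned to the columns.
.cluster_stats <- function(E, labels) {
  M <- stats::model.matrix(~ 0 + labels)
  colnames(M) <- levels(labels)
  cnt <- colSums(M)
  means <- (E %*% M) %*% diag(1 / cnt, length(cnt))
  colnames(means) <- levels(labels)
  pct <- ((E > 0) %*% M) %*% diag(1 / cnt, length(cnt))
  colnames(pct) <- levels(labels)
  list(means = means, pct = pct)
}

#' Score ligand-receptor interactions in one age group
#'
#' `score = (mean ligand expression over sender cells + mean receptor
#' expression over receiver cells) / 2` on normalized values, for every
#' ordered (sender, receiver) cell-type pair. A record passes the
#' expression filter only if the ligand is detected in strictly more than
#' `min_pct` of sender cells and the receptor in strictly more than
#' `min_pct` of receiver cells; filtered records are retained with
#' `expressed = FALSE`.
#'
#' @param nm A `NormalizedMatrix`.
#' @param meta Cell metadata with `cell_id`, `group`, `cell_type`.
#' @param pairs data.frame from [read_lr_pairs()] (columns `ligand`,
#'   `receptor`, optional `pair_id`).
#' @param group `"young"` or `"aged"`.
#' @param min_pct Detection threshold, strict (default 0.1).
#' @return data.frame: `pair_id`, `ligand`, `receptor`, `sender`,
#'   `receiver`, `group`, `score`, `pct_ligand_sender`,
#'   `pct_receptor_receiver`, `expressed`.
#' @export
interaction_score <- function(nm, meta, pairs, group, min_pct = 0.1) {
  if (is.null(pairs$pair_id)) {
    pairs$pair_id <- paste(pairs$ligand, pairs$receptor, sep = "_")
  }
  known <- pairs$ligand %in% nm$gene_ids & pairs$receptor %in% nm$gene_ids
  if (any(!known)) {
    warning(sprintf("%d pair(s) with genes absent from matrix skipped",
                    sum(!known)))
    pairs <- pairs[known, , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no usable ligand-receptor pairs")
  cells <- meta[meta$group == group, , drop = FALSE]
  types <- sort(unique(cells$cell_type))
  if (length(types) < 2) stop("need >= 2 cell types in the group")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  E <- as.matrix(nm$values[genes, cells$cell_id, drop = FALSE])
  st <- .cluster_stats(E, factor(cells$cell_type, levels = types))
  combos <- expand.grid(sender = types, receiver = types,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    lg <- pairs$ligand[i]; rc <- pairs$receptor[i]
    data.frame(pair_id = pairs$pair_id[i], ligand = lg, receptor = rc,
               sender = combos$sender, receiver = combos$receiver,
               group = group,
               score = (st$means[lg, combos$sender] +
                          st$means[rc, combos$receiver]) / 2,
               pct_ligand_sender = st$pct[lg, combos$sender],
               pct_receptor_receiver = st$pct[rc, combos$receiver],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$expressed <- out$pct_ligand_sender > min_pct &
    out$pct_receptor_receiver > min_pct
  out
}

#' Permutation test for ligand-receptor interactions
#'
#' The null is built by shuffling cell-type labels among the group's cells
#' (age-group labels stay fixed); `p = (1 + #[permuted score >= observed])
#' / (1 + n_perm)`. A record is significant iff `p <= p_max` and it passes
#' the strict expression filter.
#'
#' @inheritParams interaction_score
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @param p_max Significance threshold on p (default 0.05).
#' @return `InteractionRecord` data.frame: [interaction_score()] columns
#'   plus `p` and `significant`.
#' @export
permutation_test <- function(nm, meta, pairs, group, n_perm = 1000,
                             seed = 1L, min_pct = 0.1, p_max = 0.05) {
  if (n_perm < 100) {
    warning(sprintf("n_perm = %d gives p resolution of only %.3g", n_perm,
                    1 / (n_perm + 1)))
  }
  obs <- interaction_score(nm, meta, pairs, group, min_pct = min_pct)
  cells <- meta[meta$group == group, , drop = FALSE]
  types <- sort(unique(cells$cell_type))
  genes <- unique(c(obs$ligand, obs$receptor))
  E <- as.matrix(nm$values[genes, cells$cell_id, drop = FALSE])
  labels <- factor(cells$cell_type, levels = types)

  li <- match(obs$ligand, genes); ri <- match(obs$receptor, genes)
  si <- match(obs$sender, types); vi <- match(obs$receiver, types)
  set.seed(derive_seed(seed, paste0("crosstalk:", group)))
  hits <- integer(nrow(obs))
  for (b in seq_len(n_perm)) {
    perm <- labels[sample.int(length(labels))]
    M <- stats::model.matrix(~ 0 + perm)
    means <- (E %*% M) %*% diag(1 / colSums(M), length(types))
    sc <- (means[cbind(li, si)] + means[cbind(ri, vi)]) / 2
    hits <- hits + (sc >= obs$score)
  }
  obs$p <- (1 + hits) / (1 + n_perm)
  obs$significant <- obs$p <= p_max & obs$expressed
  obs
}

#' Young/aged differential interaction network
#'
#' Group-specific interactions (significant in one group and not the other,
#' per identical (pair, sender, receiver) record) aggregated to one edge
#' per (sender, receiver) with a signed weight.
#'
#' @param records_young,records_aged [permutation_test()] outputs computed
#'   on the same pair and cell-type universes.
#' @return List with `edges` (data.frame `sender`, `receiver`,
#'   `n_aged_specific`, `n_young_specific`, `n_shared`, `weight =
#'   n_aged_specific - n_young_specific`), `aged_specific` and
#'   `young_specific` (interaction tables).
#' @export
differential_network <- function(records_young, records_aged) {
  key <- function(x) paste(x$pair_id, x$sender, x$receiver, sep = "\r")
  ky <- key(records_young); ka <- key(records_aged)
  if (length(ky) != length(ka) || !setequal(ky, ka)) {
    stop("young and aged records cover different (pair, sender, receiver) universes")
  }
  a <- records_aged[match(ky, ka), , drop = FALSE]  # align to young order
  y <- records_young
  aged_spec <- a$significant & !y$significant
  young_spec <- y$significant & !a$significant
  shared <- a$significant & y$significant
  ek <- paste(y$sender, y$receiver, sep = "\r")
  agg <- function(flag) tapply(flag, ek, sum)
  ks <- sort(unique(ek))
  parts <- strsplit(ks, "\r", fixed = TRUE)
  edges <- data.frame(
    sender = vapply(parts, `[[`, "", 1L),
    receiver = vapply(parts, `[[`, "", 2L),
    n_aged_specific = as.integer(agg(aged_spec)[ks]),
    n_young_specific = as.integer(agg(young_spec)[ks]),
    n_shared = as.integer(agg(shared)[ks]),
    stringsAsFactors = FALSE, row.names = NULL)
  edges$weight <- edges$n_aged_specific - edges$n_young_specific
  list(edges = edges,
       aged_specific = a[aged_spec, , drop = FALSE],
       young_specific = y[young_spec, , drop = FALSE])
}
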