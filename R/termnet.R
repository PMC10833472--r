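# Cohen's-kappa similarity network over term gene sets, plus a
# hypergeometric over-representation helper for user-supplied annotations.

#' Cohen's kappa between two gene sets over a universe
#'
#' Chance-corrected agreement of the two binary membership vectors: with
#' a = |A n B|, b = |A \ B|, c = |B \ A|, d = |universe \ (A u B)| and
#' N = |universe|, `p_o = (a + d) / N`, `p_e = ((a+b)(a+c) +
#' (c+d)(b+d)) / N^2`, `kappa = (p_o - p_e) / (1 - p_e)`; kappa = 1 when
#' `p_e = 1` (both sets equal the full universe or both empty).
#'
#' @param a_set,b_set Character gene vectors (subsets of `universe`).
#' @param universe Character vector, the membership universe (|universe|
#'   >= 2).
#' @return kappa in [-1, 1].
#' @export
kappa_similarity <- function(a_set, b_set, universe) {
  universe <- unique(universe)
  if (length(universe) < 2) stop("universe must contain >= 2 genes")
  if (!all(a_set %in% universe) || !all(b_set %in% universe)) {
    stop("term gene sets must be subsets of the universe")
  }
  A <- universe %in% a_set
  B <- universe %in% b_set
  N <- length(universe)
  a <- sum(A & B); b <- sum(A & !B); c <- sum(!A & B); d <- sum(!A & !B)
  p_o <- (a + d) / N
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  if (p_e == 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Build a kappa term-similarity graph
#'
#' Undirected edge between two terms iff their kappa exceeds `threshold`
#' (strict). The default universe is the union of member genes over all
#' terms.
#'
#' @param terms Named list of character gene vectors (>= 2 terms, all
#'   non-empty).
#' @param threshold Kappa edge threshold, strict (default 0.3).
#' @param universe Optional explicit universe.
#' @param node_meta Optional data.frame of extra node annotations keyed by
#'   `term` (e.g. per-cell-type gene-hit proportions).
#' @return List with `nodes` (data.frame `term`, `size`, any `node_meta`
#'   columns), `edges` (data.frame `term_a`, `term_b`, `kappa`) and
#'   `graph` (an igraph object).
#' @export
build_term_graph <- function(terms, threshold = 0.3, universe = NULL,
                             node_meta = NULL) {
  if (length(terms) < 2) stop("need >= 2 terms")
  if (any(!lengths(terms))) stop("every term must have a non-empty gene set")
  if (is.null(names(terms)) || anyDuplicated(names(terms))) {
    stop("terms must be uniquely named")
  }
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  nms <- names(terms)
  combs <- utils::combn(length(nms), 2L)
  kap <- apply(combs, 2L, function(ij)
    kappa_similarity(terms[[ij[1L]]], terms[[ij[2L]]], universe))
  keep <- kap > threshold
  edges <- data.frame(term_a = nms[combs[1L, keep]],
                      term_b = nms[combs[2L, keep]],
                      kappa = kap[keep], stringsAsFactors = FALSE,
                      row.names = NULL)
  nodes <- data.frame(term = nms, size = lengths(terms),
                      stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(node_meta)) {
    nodes <- merge(nodes, node_meta, by = "term", all.x = TRUE, sort = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  list(nodes = nodes, edges = edges, graph = g)
}

#' Write a term graph as edge-list TSV and GraphML
#'
#' @param tg Result of [build_term_graph()].
#' @param edge_path Path for the TSV edge list.
#' @param graphml_path Optional path for GraphML output.
#' @return Invisibly, the paths written.
#' @export
write_term_graph <- function(tg, edge_path, graphml_path = NULL) {
  utils::write.table(tg$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(tg$graph, graphml_path, format = "graphml")
  }
  invisible(c(edge_path, graphml_path))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail p = P(X >= k) for the overlap k between the query and each
#' annotation term, with term size K, query size n and universe size N;
#' BH adjustment across terms. Terms with no gene in the universe are
#' skipped.
#'
#' @param query Character gene vector (must be a subset of `universe`).
#' @param annotation Named list of term gene vectors.
#' @param universe Character gene universe.
#' @return `EnrichmentRecord` data.frame: `term`, `k`, `K`, `n`, `N`,
#'   `p`, `p_adj`.
#' @export
hypergeom_enrich <- function(query, annotation, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(annotation[[term]], universe)
    K <- length(genes)
    if (K == 0) return(NULL)
    k <- length(intersect(query, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  }
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
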