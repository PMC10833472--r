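test_that("exact rank-sum matches enumeration and the reference test", {
  # 3 vs 3, complete separation: two-sided exact p = 2/20 = 0.1
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3))$p, 0.1)
  # parameterised comparison against stats::wilcox.test (exact, no ties)
  set.seed(1)
  for (i in 1:40) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    mine <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
})

test_that("normal-approximation branch matches the reference with ties", {
  set.seed(2)
  for (i in 1:20) {
    x <- sample(0:5, 30, replace = TRUE)
    y <- sample(0:5, 25, replace = TRUE)
    mine <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("bh_adjust implements step-up with monotonicity", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
})

test_that("avg_log2FC follows the pseudocount-on-averaged-expm1 form", {
  # aged mean(expm1) = 3, young mean(expm1) = 1 -> lfc = log2(4/2) = 1
  va <- matrix(log1p(3), 1, 6)
  vy <- matrix(log1p(1), 1, 6)
  v <- cbind(va, vy)
  rownames(v) <- "g1"
  # add a second varying gene so BH has >= 1 tested gene companion
  v <- rbind(v, g2 = c(rep(log1p(5), 6), rep(log1p(0.2), 6)))
  nm <- toy_nm(v)
  meta <- toy_meta(nm$cell_ids, rep(c("aged", "young"), each = 6))
  deg <- wilcoxon_deg(nm, meta, "T", min_pct = 0, lfc_prefilter = 0)
  expect_equal(deg$avg_log2FC[deg$gene == "g1"], 1)
  expect_equal(deg$direction[deg$gene == "g1"], "up")
})

test_that("identical groups yield zero fold changes and no DEGs", {
  set.seed(4)
  block <- matrix(rlnorm(20 * 8), 20, 8)
  v <- cbind(block, block)
  nm <- toy_nm(v)
  meta <- toy_meta(nm$cell_ids, rep(c("aged", "young"), each = 8))
  deg <- wilcoxon_deg(nm, meta, "T", min_pct = 0, lfc_prefilter = 0)
  expect_equal(deg$avg_log2FC, rep(0, nrow(deg)))
  expect_false(any(deg$significant))
})

test_that("swapping group labels negates fold changes and preserves p", {
  s <- quick_sim(41, n_genes = 200,
                 cell_types = list(sim_cell_type("Hep", 20, 20)),
                 deg_spec = data.frame(gene = sprintf("G%04d", 50:54),
                                       cell_type = "Hep", log2fc = 1))
  nm <- normalize_log1p_cp10k(s$counts)
  d1 <- wilcoxon_deg(nm, s$meta, "Hep")
  meta2 <- s$meta
  meta2$group <- ifelse(meta2$group == "young", "aged", "young")
  d2 <- wilcoxon_deg(nm, meta2, "Hep")
  d2 <- d2[match(d1$gene, d2$gene), ]
  expect_equal(d2$avg_log2FC, -d1$avg_log2FC)
  expect_equal(d2$p, d1$p)
})

test_that("wilcoxon_deg recovers injected effects on synthetic truth", {
  # inject into detectably expressed genes (baseline mu >= 0.3): an lfc of
  # -1 on a near-zero gene is invisible on the pseudocount scale by design
  mk <- function(seed, deg_spec = NULL)
    quick_sim(seed, n_genes = 600,
              cell_types = list(sim_cell_type("Hep", 200, 200,
                                              marker_genes = 0)),
              deg_spec = deg_spec)
  pool <- names(which(mk(42)$truth$gene_means >= 0.3))
  degs <- data.frame(gene = pool[1:30], cell_type = "Hep",
                     log2fc = rep(c(1, -1), 15))
  s <- mk(42, degs)
  nm <- normalize_log1p_cp10k(s$counts)
  out <- wilcoxon_deg(nm, s$meta, "Hep")
  hit <- out[out$significant, ]
  sens <- mean(degs$gene %in% hit$gene)
  fdr <- mean(!hit$gene %in% degs$gene)
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
  # direction agrees with the injected sign
  found <- hit[hit$gene %in% degs$gene, ]
  expect_true(all(found$direction ==
                    ifelse(degs$log2fc[match(found$gene, degs$gene)] > 0,
                           "up", "down")))
  expect_error(wilcoxon_deg(nm, s$meta, "Missing"), "Missing")
})

test_that("shared_degs counts per direction and matches set algebra", {
  tabs <- list(
    A = rbind(deg_row("g1", "A", 1), deg_row("g2", "A", 1),
              deg_row("g3", "A", -1)),
    B = rbind(deg_row("g1", "B", 2), deg_row("g2", "B", -1)),
    C = rbind(deg_row("g1", "C", 0.5), deg_row("g3", "C", -2)),
    D = rbind(deg_row("g3", "D", -1), deg_row("g2", "D", 1,
                                              significant = FALSE)))
  out <- shared_degs(tabs, k_min = 3)
  expect_equal(nrow(out), 2)
  expect_equal(out$k[out$gene == "g1"], 3)          # up in A, B, C
  expect_equal(out$direction[out$gene == "g3"], "down")  # down in A, C, D
  # g2: up in A, down in B, non-significant in D -> no record

  # randomized tables against a brute-force oracle
  set.seed(9)
  genes <- sprintf("g%02d", 1:30)
  types <- LETTERS[1:6]
  tabs2 <- lapply(types, function(ct) {
    g <- sample(genes, 12)
    do.call(rbind, lapply(g, function(x)
      deg_row(x, ct, sample(c(-1, 1), 1))))
  })
  names(tabs2) <- types
  out2 <- shared_degs(tabs2, k_min = 3)
  flat <- do.call(rbind, tabs2)
  oracle <- 0L
  for (g in genes) for (d in c("up", "down")) {
    k <- length(unique(flat$cell_type[flat$gene == g & flat$direction == d]))
    if (k >= 3) oracle <- oracle + 1L
  }
  expect_equal(nrow(out2), oracle)
})

test_that("overlap_modules covers exactly the 14 classes and flags discord", {
  # one gene per (direction, non-empty subset) pattern
  pats <- expand.grid(dir = c(1, -1),
                      pp = c(TRUE, FALSE), mz = c(TRUE, FALSE),
                      pc = c(TRUE, FALSE))
  pats <- pats[pats$pp | pats$mz | pats$pc, ]
  pats$gene <- sprintf("pat%02d", seq_len(nrow(pats)))
  mk <- function(sub) {
    rows <- pats[pats[[sub]], ]
    do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
      deg_row(rows$gene[i], sub, rows$dir[i])))
  }
  colnames(pats)[2:4] <- c("PP", "MZ", "PC")
  res <- overlap_modules(mk("PP"), mk("MZ"), mk("PC"))
  expect_equal(sort(unique(res$modules$module_id)), 1:14)
  expect_equal(nrow(res$modules), 14)
  expect_equal(nrow(res$discordant), 0)

  # single-subtype gene lands in its singleton module
  one <- overlap_modules(deg_row("gx", "PP", 1),
                         deg_row("zz", "MZ", 1)[0, ],
                         deg_row("zz", "PC", 1)[0, ])
  expect_equal(one$modules$subtypes, "PP")
  expect_equal(one$modules$direction, "up")

  # discordant direction is excluded and reported
  dis <- overlap_modules(deg_row("gd", "PP", 1),
                         deg_row("zz", "MZ", 1)[0, ],
                         deg_row("gd", "PC", -1))
  expect_equal(nrow(dis$modules), 0)
  expect_equal(dis$discordant$gene, "gd")

  # union of module genes + discordant = all genes significant anywhere
  both <- overlap_modules(rbind(deg_row("a", "PP", 1), deg_row("b", "PP", 1)),
                          deg_row("b", "MZ", -1),
                          deg_row("c", "PC", -1))
  expect_setequal(c(both$modules$gene, both$discordant$gene),
                  c("a", "b", "c"))
})

test_that("signed_external_overlap classifies by sign agreement", {
  deg <- rbind(deg_row("GA", "Hep", 1), deg_row("GB", "Hep", -1),
               deg_row("GC", "Hep", 1), deg_row("GD", "Hep", 1,
                                                significant = FALSE))
  ext <- data.frame(gene = c("ga", "gb", "gc", "ge"),
                    sign = c("+", "-", "-", "+"), stringsAsFactors = FALSE)
  out <- signed_external_overlap(deg, ext)
  expect_equal(out$co_up, "GA")
  expect_equal(out$co_down, "GB")
  expect_equal(out$discordant, "GC")
  # case-sensitive matching finds nothing here
  expect_warning(none <- signed_external_overlap(deg, ext,
                                                 case_insensitive = FALSE),
                 "no overlap")
  expect_length(none$co_up, 0)
})
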