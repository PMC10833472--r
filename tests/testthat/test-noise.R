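test_that("downsample_umi boundary cases and postconditions", {
  m <- matrix(c(5L, 3L, 2L), 3, 1)
  cm <- toy_cm(m)
  # target equal to the total: draw everything, unchanged
  same <- downsample_umi(cm, 10, seed = 1)
  expect_equal(as.numeric(same$counts[, 1]), c(5, 3, 2))
  # target below: sums to target, entrywise <= input
  ds <- downsample_umi(cm, 5, seed = 1)
  expect_equal(sum(ds$counts[, 1]), 5)
  expect_true(all(as.numeric(ds$counts[, 1]) <= c(5, 3, 2)))
  # cells below the target are dropped (with a warning if none remain)
  expect_warning(empty <- downsample_umi(cm, 11, seed = 1), "no cell")
  expect_equal(ncol(empty$counts), 0)
})

test_that("downsample_umi marginals match the multivariate hypergeometric", {
  # 10,000 independent draws from one (5, 3, 2) cell at target 5, in one
  # call (each column is an independent draw)
  n_draws <- 10000
  m <- matrix(rep(c(5L, 3L, 2L), n_draws), 3, n_draws)
  cm <- toy_cm(m, cell_ids = sprintf("d%05d", seq_len(n_draws)))
  ds <- downsample_umi(cm, 5, seed = 7)
  x1 <- as.numeric(ds$counts[1, ])
  # expectation n * K / N: (2.5, 1.5, 1.0)
  expect_equal(mean(x1), 2.5, tolerance = 0.03)
  expect_equal(mean(ds$counts[2, ]), 1.5, tolerance = 0.03)
  expect_equal(mean(ds$counts[3, ]), 1.0, tolerance = 0.03)
  expect_true(all(Matrix::colSums(ds$counts) == 5))
  # chi-square goodness of fit of the gene-1 marginal against
  # Hypergeometric(N = 10, K = 5, n = 5)
  probs <- stats::dhyper(0:5, 5, 5, 5)
  obs <- tabulate(x1 + 1L, nbins = 6L)
  keep <- probs > 0
  gof <- stats::chisq.test(obs[keep], p = probs[keep] / sum(probs[keep]))
  expect_gt(gof$p.value, 0.01)
})

test_that("downsampling is seeded and deterministic", {
  s <- quick_sim(31, n_genes = 200,
                 cell_types = list(sim_cell_type("Hep", 20, 20)))
  a <- downsample_umi(s$counts, 800, seed = 5)
  b <- downsample_umi(s$counts, 800, seed = 5)
  c <- downsample_umi(s$counts, 800, seed = 6)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_false(identical(as.matrix(a$counts), as.matrix(c$counts)))
  expect_true(all(as.matrix(a$counts) <= as.matrix(
    s$counts$counts[, a$cell_ids])))
})

test_that("balance_groups takes min(n_young, n_aged) per type", {
  meta <- rbind(toy_meta(sprintf("y%03d", 1:100), "young", "A"),
                toy_meta(sprintf("a%03d", 1:60), "aged", "A"),
                toy_meta(sprintf("ry%02d", 1:10), "young", "B"),
                toy_meta(sprintf("ra%02d", 1:50), "aged", "B"))
  expect_warning(sel <- balance_groups(meta, min_cells = 20, seed = 1), "B")
  got <- meta[meta$cell_id %in% sel, ]
  expect_equal(unname(table(got$group)), c(60L, 60L), ignore_attr = TRUE)
  expect_false(any(got$cell_type == "B"))
  # equal sizes: all cells selected regardless of seed
  meta2 <- rbind(toy_meta(sprintf("y%02d", 1:25), "young", "A"),
                 toy_meta(sprintf("a%02d", 1:25), "aged", "A"))
  expect_setequal(balance_groups(meta2, seed = 1), meta2$cell_id)
  expect_setequal(balance_groups(meta2, seed = 99), meta2$cell_id)
})

test_that("distance-to-centroid noise matches direct arithmetic", {
  # identical cells -> noise 0
  m <- matrix(rep(c(4L, 6L, 10L), 4), 3, 4)
  cm <- toy_cm(m)
  meta <- toy_meta(cm$cell_ids, c("young", "young", "aged", "aged"))
  nt <- transcriptional_noise(cm, meta, gene_min_pct = 0)
  expect_equal(nt$noise, rep(0, 4))

  # two cells: each at ||x1 - x2|| / 2 from the midpoint
  m2 <- cbind(c(8L, 2L, 10L), c(2L, 8L, 10L))
  cm2 <- toy_cm(m2)
  meta2 <- toy_meta(cm2$cell_ids, "young")
  nt2 <- transcriptional_noise(cm2, meta2, gene_min_pct = 0)
  v <- log1p(sweep(m2, 2, colSums(m2), "/") * 1e4)
  expect_equal(nt2$noise, rep(sqrt(sum((v[, 1] - v[, 2])^2)) / 2, 2))

  # three-cell group: hand-computed centroid distances on normalized values
  m3 <- cbind(c(0L, 0L, 20L), c(5L, 0L, 15L), c(0L, 5L, 15L))
  cm3 <- toy_cm(m3)
  nt3 <- transcriptional_noise(cm3, toy_meta(cm3$cell_ids, "aged"),
                               gene_min_pct = 0)
  v3 <- log1p(sweep(m3, 2, colSums(m3), "/") * 1e4)
  ctr <- rowMeans(v3)
  expect_equal(nt3$noise, sqrt(colSums((v3 - ctr)^2)), ignore_attr = TRUE)

  # a single-cell group is flagged degenerate with zero distance
  meta4 <- toy_meta(cm3$cell_ids, c("young", "young", "aged"))
  nt4 <- transcriptional_noise(cm3, meta4, gene_min_pct = 0)
  expect_true(nt4$degenerate[nt4$group == "aged"])
  expect_equal(nt4$noise[nt4$group == "aged"], 0)
})

test_that("noise_ratio medians, tests and NA reasons", {
  nt <- data.frame(cell_id = sprintf("c%02d", 1:12),
                   cell_type = "Hep",
                   group = rep(c("young", "aged"), each = 6),
                   noise = c(1:6, 2 * (1:6)), stringsAsFactors = FALSE)
  out <- noise_ratio(nt)
  expect_equal(out$log2_ratio, 1)  # aged = 2 x young elementwise
  nt$noise[7:12] <- nt$noise[1:6]
  expect_equal(noise_ratio(nt)$log2_ratio, 0)
  nt$noise[1:6] <- 0
  na_out <- noise_ratio(nt)
  expect_true(is.na(na_out$log2_ratio))
  expect_match(na_out$note, "young median")
})

test_that("noise_correlated_genes flags perfect trackers, strict threshold", {
  set.seed(5)
  n <- 40
  noise <- runif(n, 1, 3)
  v <- matrix(runif(6 * n), 6, n)
  v[1, ] <- noise + 1          # r = 1
  v[2, ] <- -noise + 4         # r = -1
  v[3, ] <- 2                  # constant: excluded, counted
  nm <- toy_nm(v)
  nt <- data.frame(cell_id = nm$cell_ids, cell_type = "Hep",
                   group = rep(c("young", "aged"), each = n / 2),
                   noise = noise, stringsAsFactors = FALSE)
  out <- noise_correlated_genes(nm, nt, "Hep", r_min = 0.6, fdr_max = 0.05)
  expect_equal(out$gene[out$direction == "up"][1], "g01")
  expect_true("g02" %in% out$gene[out$direction == "down"])
  expect_equal(out$pearson_r[out$gene == "g01"], 1)
  expect_equal(attr(out, "n_constant"), 1)
  # strict ">": setting r_min to an attained |r| excludes that gene
  r4 <- abs(stats::cor(noise, v[4, ]))
  out2 <- noise_correlated_genes(nm, nt, "Hep", r_min = r4, fdr_max = 1)
  expect_false("g04" %in% out2$gene)
})

test_that("null gene-noise correlations are calibrated", {
  set.seed(6)
  n <- 50
  noise <- runif(n)
  v <- matrix(rnorm(1000 * n), 1000, n)
  nm <- toy_nm(v, gene_ids = sprintf("g%04d", 1:1000))
  nt <- data.frame(cell_id = nm$cell_ids, cell_type = "Hep",
                   group = rep(c("young", "aged"), each = n / 2),
                   noise = noise, stringsAsFactors = FALSE)
  r <- as.numeric(stats::cor(noise, t(v)))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  # ~5% of raw p below 0.05 (binomial 3 SE)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  # and the reported selection at the default thresholds is empty
  out <- noise_correlated_genes(nm, nt, "Hep")
  expect_equal(nrow(out), 0)
})

test_that("bin_by_noise builds equal-frequency bins with a stable tie rule", {
  nt <- data.frame(cell_id = sprintf("c%02d", 1:40),
                   cell_type = "Hep",
                   group = rep(c("young", "aged"), each = 20),
                   noise = c(runif(20), rep(1, 20)),
                   stringsAsFactors = FALSE)
  b <- bin_by_noise(nt, n_bins = 4)
  expect_equal(unname(table(b$bin[b$group == "young"])), rep(5L, 4),
               ignore_attr = TRUE)
  # all-tied noises: bins assigned by cell_id order
  aged <- b[b$group == "aged", ]
  expect_equal(aged$bin[order(aged$cell_id)], rep(1:4, each = 5))
  # n_bins = cells per group: a permutation of ranks
  b2 <- bin_by_noise(nt[nt$group == "young", ], n_bins = 20)
  expect_setequal(b2$bin, 1:20)
  expect_error(bin_by_noise(nt, n_bins = 21), "exceed")
})

test_that("noise pipeline is invariant to cell order and gene relabeling", {
  s <- quick_sim(35, n_genes = 200,
                 cell_types = list(sim_cell_type("Hep", 25, 25)))
  cm <- s$counts; meta <- s$meta
  perm <- sample(ncol(cm$counts))
  cmp <- CountMatrix(cm$counts[, perm], gene_ids = cm$gene_ids,
                     cell_ids = cm$cell_ids[perm])
  nt1 <- transcriptional_noise(cm, meta)
  nt2 <- transcriptional_noise(cmp, meta)
  nt2 <- nt2[match(nt1$cell_id, nt2$cell_id), ]
  expect_equal(nt1$noise, nt2$noise)
  cmg <- CountMatrix(cm$counts, gene_ids = paste0("X", cm$gene_ids),
                     cell_ids = cm$cell_ids)
  nt3 <- transcriptional_noise(cmg, meta)
  expect_equal(nt1$noise, nt3$noise)
})
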