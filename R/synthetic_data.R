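# Synthetic snRNA-seq generator with known ground truth.
#
# Counts are negative binomial: count(g, c) ~ NB(mean = s_c * mu_g * e_{g,
# type(c), group(c)} * z_{g, t(c)}, size = theta_g / disp_mult(type, group)),
# where s_c is a log-normal library factor, mu_g a log-normal baseline mean,
# e the injected marker/DEG effect, z the hepatocyte zonation factor and the
# dispersion multiplier inflates variance (not means) in aged cells so the
# noise statistic isolates variance.

#' Declare a simulated cell type
#'
#' @param name Cell-type label.
#' @param n_young,n_aged Number of cells per age group.
#' @param marker_genes Number of type-specific marker genes.
#' @param marker_lfc log2 fold change of marker genes in this type.
#' @param aged_dispersion_multiplier Variance inflation for aged cells
#'   (theta -> theta / multiplier); must be >= 1.
#' @param zonated Logical; if TRUE cells of this type carry a continuous
#'   zonation position t in [0, 1] and respond to the zonation gradient.
#' @return A list describing the cell type.
#' @export
sim_cell_type <- function(name, n_young = 200, n_aged = 200,
                          marker_genes = 25, marker_lfc = 2,
                          aged_dispersion_multiplier = 1, zonated = FALSE) {
  stopifnot(n_young >= 0, n_aged >= 0, marker_genes >= 0,
            aged_dispersion_multiplier >= 1)
  list(name = name, n_young = n_young, n_aged = n_aged,
       marker_genes = marker_genes, marker_lfc = marker_lfc,
       aged_dispersion_multiplier = aged_dispersion_multiplier,
       zonated = zonated)
}

#' Build a simulation configuration
#'
#' Defaults describe a small liver-like dataset: a zonated hepatocyte
#' population plus two non-parenchymal types, 200 cells per group for the
#' hepatocytes, NB dispersion theta = 10, log-normal library sizes and a
#' Beta-distributed mitochondrial fraction with mean 2.5% (below the 5% QC
#' ceiling typical of nuclei).
#'
#' @param n_genes Number of non-mitochondrial genes.
#' @param cell_types List of [sim_cell_type()] entries.
#' @param baseline_log_mean,baseline_log_sd Parameters of the log-normal
#'   distribution of per-gene baseline means mu_g.
#' @param nb_dispersion NB size parameter theta (scalar, shared by genes).
#' @param library_size_log_mean,library_size_log_sd Log-normal parameters of
#'   the per-cell library factor s_c.
#' @param deg_spec data.frame with columns `gene`, `cell_type`, `log2fc`:
#'   aging effects applied to aged cells of the named type. `cell_type`
#'   may be `"*"` for all types.
#' @param zonation List: `enabled`, `n_gradient_genes` (extra genes with
#'   random signed amplitudes), `gradient_amplitude` (log2 amplitude `a`),
#'   `pp_marker_genes`, `pc_marker_genes` (counts).
#' @param lr_spec data.frame with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `log2fc`, `group` (`"young"`, `"aged"` or `"both"`):
#'   ligand is upregulated in sender cells and receptor in receiver cells of
#'   the stated group(s).
#' @param n_mito_genes Number of mitochondrial genes (ids prefixed
#'   `mito_gene_prefix`).
#' @param mito_fraction_beta_params Length-2 shape parameters of the Beta
#'   distribution of per-cell mitochondrial fractions.
#' @param mito_gene_prefix Prefix used for mitochondrial gene ids.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes = 1000,
                       cell_types = list(
                         sim_cell_type("Hep", 200, 200, zonated = TRUE),
                         sim_cell_type("EC", 100, 100),
                         sim_cell_type("Kupffer", 100, 100)),
                       baseline_log_mean = -1, baseline_log_sd = 1,
                       nb_dispersion = 10,
                       library_size_log_mean = 1.5, library_size_log_sd = 0.35,
                       deg_spec = NULL,
                       zonation = list(enabled = TRUE, n_gradient_genes = 30,
                                       gradient_amplitude = 2,
                                       pp_marker_genes = 10,
                                       pc_marker_genes = 10),
                       lr_spec = NULL,
                       n_mito_genes = 13,
                       mito_fraction_beta_params = c(2, 78),
                       mito_gene_prefix = "MT-",
                       seed = 1L) {
  stopifnot(n_genes > 0, nb_dispersion > 0, n_mito_genes >= 0,
            length(mito_fraction_beta_params) == 2,
            all(mito_fraction_beta_params > 0))
  if (!length(cell_types)) stop("at least one cell type required")
  cfg <- list(n_genes = n_genes, cell_types = cell_types,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              nb_dispersion = nb_dispersion,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              deg_spec = deg_spec, zonation = zonation, lr_spec = lr_spec,
              n_mito_genes = n_mito_genes,
              mito_fraction_beta_params = mito_fraction_beta_params,
              mito_gene_prefix = mito_gene_prefix,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' Zonation multiplier profile at position t
#'
#' Linear-in-log scheme: a gene with signed amplitude `a` gets multiplier
#' `2^(a * (2t - 1))`, so periportal (PP) markers (negative slope sign,
#' i.e. amplitude applied as `2^(a * (1 - 2t))`) decrease monotonically in
#' t, pericentral (PC) markers increase, and `t = 0.5` gives the geometric
#' mean of the two endpoints (multiplier 1).
#'
#' @param t Zonation position in [0, 1] (0 = periportal, 1 = pericentral).
#' @param amplitudes Named numeric vector of signed log2 amplitudes per
#'   gradient gene (positive = PC-biased, negative = PP-biased).
#' @return Named multiplier vector (one per gradient gene) if `t` is scalar,
#'   else a gene x cell matrix.
#' @export
simulate_zonation_profile <- function(t, amplitudes) {
  if (any(t < 0 | t > 1)) stop("zonation position t must lie in [0, 1]")
  out <- 2^(outer(amplitudes, 2 * t - 1))
  if (length(t) == 1L) out[, 1L] else out
}

#' Simulate a UMI count matrix with known ground truth
#'
#' @param config A [sim_config()] object.
#' @return A list with `counts` (a [CountMatrix()]), `meta` (cell metadata
#'   data.frame) and `truth` (a `GroundTruth` list: `deg` effects table,
#'   `gene_means` (baseline mu_g), `markers` per type,
#'   `zonation_t` per hepatocyte-like cell,
#'   `zonation_amplitudes`, `pp_markers`, `pc_markers`,
#'   `noise_multiplier` per (type, group), `lr` effect table, `mito_genes`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, "simulate"))
  ng <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(ng))
  mito_ids <- if (config$n_mito_genes > 0)
    paste0(config$mito_gene_prefix, seq_len(config$n_mito_genes)) else character()
  types <- config$cell_types
  type_names <- vapply(types, `[[`, "", "name")
  if (anyDuplicated(type_names)) stop("duplicate cell type names in config")

  mu <- stats::rlnorm(ng, config$baseline_log_mean, config$baseline_log_sd)
  names(mu) <- gene_ids

  # assign marker genes: disjoint blocks from the top of the gene list
  markers <- list()
  cursor <- 0L
  for (ct in types) {
    if (ct$marker_genes > 0) {
      idx <- cursor + seq_len(ct$marker_genes)
      if (max(idx) > ng) stop("not enough genes for requested marker blocks")
      markers[[ct$name]] <- gene_ids[idx]
      cursor <- cursor + ct$marker_genes
    } else markers[[ct$name]] <- character()
  }

  # zonation gradient genes drawn after the marker blocks
  zon <- config$zonation
  zon_amp <- numeric(0)
  pp_markers <- pc_markers <- character()
  if (isTRUE(zon$enabled)) {
    need <- zon$pp_marker_genes + zon$pc_marker_genes + zon$n_gradient_genes
    if (cursor + need > ng) stop("not enough genes for zonation blocks")
    pp_markers <- gene_ids[cursor + seq_len(zon$pp_marker_genes)]
    cursor <- cursor + zon$pp_marker_genes
    pc_markers <- gene_ids[cursor + seq_len(zon$pc_marker_genes)]
    cursor <- cursor + zon$pc_marker_genes
    grad_extra <- gene_ids[cursor + seq_len(zon$n_gradient_genes)]
    cursor <- cursor + zon$n_gradient_genes
    a <- zon$gradient_amplitude
    zon_amp <- c(stats::setNames(rep(-a, length(pp_markers)), pp_markers),
                 stats::setNames(rep(a, length(pc_markers)), pc_markers),
                 stats::setNames(stats::runif(length(grad_extra), -a, a),
                                 grad_extra))
  }

  deg <- config$deg_spec
  if (!is.null(deg)) {
    bad <- setdiff(deg$gene, gene_ids)
    if (length(bad)) stop(sprintf("deg_spec names unknown genes: %s",
                                  paste(utils::head(bad, 5), collapse = ", ")))
    bad_ct <- setdiff(setdiff(deg$cell_type, "*"), type_names)
    if (length(bad_ct)) stop(sprintf("deg_spec names unknown cell types: %s",
                                     paste(bad_ct, collapse = ", ")))
  }
  lr <- config$lr_spec
  if (!is.null(lr)) {
    bad <- setdiff(c(lr$ligand, lr$receptor), gene_ids)
    if (length(bad)) stop(sprintf("lr_spec names unknown genes: %s",
                                  paste(bad, collapse = ", ")))
    if (is.null(lr$group)) lr$group <- "both"
    if (is.null(lr$log2fc)) lr$log2fc <- 2
  }

  all_ids <- c(gene_ids, mito_ids)
  n_cells <- sum(vapply(types, function(ct) ct$n_young + ct$n_aged, 0))
  counts <- matrix(0L, length(all_ids), n_cells,
                   dimnames = list(all_ids, NULL))
  cell_id <- character(n_cells)
  cell_type <- character(n_cells)
  group <- character(n_cells)
  zonation_t <- rep(NA_real_, n_cells)

  theta0 <- config$nb_dispersion
  beta_par <- config$mito_fraction_beta_params
  col <- 0L
  for (ct in types) {
    for (grp in c("young", "aged")) {
      n_grp <- if (grp == "young") ct$n_young else ct$n_aged
      if (n_grp == 0) next
      idx <- col + seq_len(n_grp)
      col <- col + n_grp
      cell_id[idx] <- sprintf("%s_%s_%03d", ct$name, grp, seq_len(n_grp))
      cell_type[idx] <- ct$name
      group[idx] <- grp

      base <- mu  # per-gene mean for this (type, group)
      mk <- markers[[ct$name]]
      if (length(mk)) base[mk] <- base[mk] * 2^ct$marker_lfc
      if (!is.null(deg) && grp == "aged") {
        hit <- deg$cell_type == ct$name | deg$cell_type == "*"
        if (any(hit)) {
          g <- deg$gene[hit]
          base[g] <- base[g] * 2^deg$log2fc[hit]
        }
      }
      if (!is.null(lr)) {
        hit <- (lr$group == "both" | lr$group == grp)
        for (k in which(hit)) {
          if (lr$sender[k] == ct$name)
            base[lr$ligand[k]] <- base[lr$ligand[k]] * 2^lr$log2fc[k]
          if (lr$receiver[k] == ct$name)
            base[lr$receptor[k]] <- base[lr$receptor[k]] * 2^lr$log2fc[k]
        }
      }

      mean_mat <- matrix(base, ng, n_grp, dimnames = list(gene_ids, NULL))
      if (ct$zonated && length(zon_amp)) {
        tt <- stats::runif(n_grp)
        zonation_t[idx] <- tt
        zmult <- simulate_zonation_profile(tt, zon_amp)
        mean_mat[names(zon_amp), ] <- mean_mat[names(zon_amp), , drop = FALSE] *
          zmult
      }
      s <- stats::rlnorm(n_grp, config$library_size_log_mean,
                         config$library_size_log_sd)
      mean_mat <- sweep(mean_mat, 2L, s, `*`)

      if (length(mito_ids)) {
        f <- stats::rbeta(n_grp, beta_par[1L], beta_par[2L])
        # mito mass chosen so E[mito]/E[total] = f per cell
        mito_tot <- f / (1 - f) * colSums(mean_mat)
        w <- rep(1 / length(mito_ids), length(mito_ids))
        mito_mat <- outer(w, mito_tot)
        mean_mat <- rbind(mean_mat, mito_mat)
      }
      theta <- theta0
      if (grp == "aged") theta <- theta0 / ct$aged_dispersion_multiplier
      counts[, idx] <- matrix(
        stats::rnbinom(length(mean_mat), size = theta, mu = mean_mat),
        nrow(mean_mat), n_grp)
    }
  }

  cm <- CountMatrix(counts, gene_ids = all_ids, cell_ids = cell_id)
  meta <- make_cell_meta(cm, sample_id = paste0("sim_", group), group = group,
                         cell_type = cell_type,
                         mito_gene_prefix = config$mito_gene_prefix)

  truth_deg <- if (is.null(deg)) {
    data.frame(gene = character(), cell_type = character(),
               log2fc = numeric(), stringsAsFactors = FALSE)
  } else as.data.frame(deg, stringsAsFactors = FALSE)
  mult <- do.call(rbind, lapply(types, function(ct)
    data.frame(cell_type = ct$name, group = c("young", "aged"),
               multiplier = c(1, ct$aged_dispersion_multiplier),
               stringsAsFactors = FALSE)))
  truth <- structure(list(
    deg = truth_deg,
    gene_means = mu,
    markers = markers,
    zonation_t = stats::setNames(zonation_t, cell_id),
    zonation_amplitudes = zon_amp,
    pp_markers = pp_markers, pc_markers = pc_markers,
    noise_multiplier = mult,
    lr = if (is.null(lr)) NULL else as.data.frame(lr, stringsAsFactors = FALSE),
    mito_genes = mito_ids), class = "GroundTruth")
  list(counts = cm, meta = meta, truth = truth)
}

#' Write a simulated dataset in the standard exchange formats
#'
#' Writes `matrix.mtx` / `genes.tsv` / `barcodes.tsv`, `cell_meta.tsv` and
#' plain-text ground-truth tables under `out_dir`.
#'
#' @param sim Result of [simulate_counts()].
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, out_dir)
  write_cell_meta(sim$meta, file.path(out_dir, "cell_meta.tsv"))
  tr <- sim$truth
  utils::write.table(tr$deg, file.path(out_dir, "ground_truth_deg.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  zt <- tr$zonation_t[!is.na(tr$zonation_t)]
  utils::write.table(data.frame(cell_id = names(zt), t = as.numeric(zt)),
                     file.path(out_dir, "ground_truth_zonation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tr$noise_multiplier,
                     file.path(out_dir, "ground_truth_noise.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mk <- data.frame(
    cell_type = rep(names(tr$markers), lengths(tr$markers)),
    gene = unlist(tr$markers, use.names = FALSE))
  utils::write.table(mk, file.path(out_dir, "ground_truth_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tr$lr)) {
    utils::write.table(tr$lr, file.path(out_dir, "ground_truth_lr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
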