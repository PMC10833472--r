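# End-to-end orchestration: qc -> normalize -> scoring/zonation -> noise ->
# deg -> overlap modules -> crosstalk -> termnet, with one global seed,
# per-stage substreams and a provenance manifest.

#' Build a pipeline configuration
#'
#' @param counts_dir Directory holding `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` and `cell_meta.tsv` (as written by
#'   [write_simulation()]).
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param seed Global seed; stages derive independent substreams from it.
#' @param lr_pairs Optional path to a ligand-receptor TSV; crosstalk is
#'   skipped (with a logged notice) when NULL.
#' @param zonation_gmt Optional GMT with sets named `PP` and `PC`
#'   (zonation marker genes); zonation stages are skipped when NULL.
#' @param hepatocyte_type Cell-type label treated as hepatocytes for the
#'   zonation stages (default "Hep").
#' @param terms_gmt Optional GMT of annotation terms for enrichment and the
#'   kappa network.
#' @param signature Optional path to an external signed signature TSV.
#' @param params Named list overriding stage parameters: `qc` (min_genes,
#'   max_pct_mito, mito_gene_prefix), `score` (top_n, lfc_min, padj_max,
#'   n_bins, n_ctrl), `noise` (target_umi, gene_min_pct, min_cells),
#'   `deg` (min_pct, lfc_prefilter, padj_max, lfc_sig), `crosstalk`
#'   (n_perm, min_pct, p_max), `termnet` (kappa_threshold).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(counts_dir, out_dir, seed = 1L, lr_pairs = NULL,
                            zonation_gmt = NULL, hepatocyte_type = "Hep",
                            terms_gmt = NULL, signature = NULL,
                            params = list()) {
  defaults <- list(
    qc = list(min_genes = 200, max_pct_mito = 0.05, mito_gene_prefix = "MT-"),
    score = list(top_n = 50, lfc_min = 0.5, padj_max = 0.05, n_bins = 24,
                 n_ctrl = 100),
    noise = list(target_umi = NULL, gene_min_pct = 0.1, min_cells = 20),
    deg = list(min_pct = 0.1, lfc_prefilter = 0.25, padj_max = 0.05,
               lfc_sig = 0.25),
    crosstalk = list(n_perm = 1000, min_pct = 0.1, p_max = 0.05),
    termnet = list(kappa_threshold = 0.3))
  for (st in names(params)) {
    defaults[[st]][names(params[[st]])] <- params[[st]]
  }
  structure(list(counts_dir = counts_dir, out_dir = out_dir,
                 seed = as.integer(seed), lr_pairs = lr_pairs,
                 zonation_gmt = zonation_gmt,
                 hepatocyte_type = hepatocyte_type, terms_gmt = terms_gmt,
                 signature = signature, params = defaults),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from JSON
#' @param path JSON file with the [pipeline_config()] fields.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' @keywords internal
.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; each optional stage (crosstalk,
#' zonation, termnet, external signature) is skipped with a logged notice
#' when its input is not configured. Rerunning with the same config and
#' inputs reproduces bit-identical TSVs.
#'
#' @param config A `PipelineConfig` (or path to its JSON form).
#' @param log Function receiving log lines (default writes to stderr).
#' @return Invisibly, the output directory. Side effects: stage TSVs and
#'   `manifest.json` under `config$out_dir`.
#' @export
run_pipeline <- function(config, log = function(msg) message(msg)) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  prm <- config$params
  written <- character()
  skipped <- character()
  add <- function(x, name) {
    written <<- c(written, .write_tsv(x, file.path(out, name)))
  }
  inputs <- c(file.path(config$counts_dir,
                        c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                          "cell_meta.tsv")),
              config$lr_pairs, config$zonation_gmt, config$terms_gmt,
              config$signature)
  for (p in inputs) if (!file.exists(p)) stop(sprintf("missing input: %s", p))

  log("[qc] reading counts")
  cm <- read_counts(file.path(config$counts_dir, "matrix.mtx"),
                    file.path(config$counts_dir, "genes.tsv"),
                    file.path(config$counts_dir, "barcodes.tsv"))
  meta <- read_cell_meta(file.path(config$counts_dir, "cell_meta.tsv"))
  qc <- qc_filter(cm, meta, min_genes = prm$qc$min_genes,
                  max_pct_mito = prm$qc$max_pct_mito,
                  mito_gene_prefix = prm$qc$mito_gene_prefix)
  log(sprintf("[qc] %d/%d cells pass", qc$report$n_pass_cells,
              qc$report$n_input_cells))
  add(qc$meta, "cell_meta_qc.tsv")
  nm <- normalize_log1p_cp10k(qc$counts)
  meta <- qc$meta

  log("[score] young identity sets + drift")
  sets <- young_identity_sets(nm, meta, top_n = prm$score$top_n,
                              lfc_min = prm$score$lfc_min,
                              padj_max = prm$score$padj_max)
  write_gmt(sets, file.path(out, "identity_sets.gmt"))
  written <- c(written, file.path(out, "identity_sets.gmt"))
  drift <- identity_drift(nm, meta, sets, n_bins = prm$score$n_bins,
                          n_ctrl = prm$score$n_ctrl,
                          seed = derive_seed(seed, "score"))
  add(drift, "identity_drift.tsv")

  zonation <- NULL
  if (!is.null(config$zonation_gmt)) {
    log("[zonation] marker-score assignment")
    zsets <- read_gmt(config$zonation_gmt)
    hep <- meta$cell_id[meta$cell_type == config$hepatocyte_type]
    zonation <- zonation_assign(nm, hep, zsets$PP, zsets$PC,
                                n_bins = prm$score$n_bins,
                                n_ctrl = prm$score$n_ctrl,
                                seed = derive_seed(seed, "zonation"))
    add(zonation, "zonation.tsv")
  } else skipped <- c(skipped, "zonation")

  log("[noise] balance + downsample + distance-to-centroid")
  sel <- balance_groups(meta, min_cells = prm$noise$min_cells,
                        seed = derive_seed(seed, "balance"))
  cmb <- CountMatrix(qc$counts$counts[, sel, drop = FALSE],
                     gene_ids = qc$counts$gene_ids, cell_ids = sel)
  target <- prm$noise$target_umi %||% default_target_umi(cmb)
  cmd <- downsample_umi(cmb, target, seed = derive_seed(seed, "downsample"))
  nt <- transcriptional_noise(cmd, meta, gene_min_pct = prm$noise$gene_min_pct)
  add(nt, "noise_table.tsv")
  add(noise_ratio(nt), "noise_summary.tsv")
  nmd <- normalize_log1p_cp10k(cmd)
  ngenes <- do.call(rbind, lapply(sort(unique(nt$cell_type)), function(ct) {
    g <- noise_correlated_genes(nmd, nt, ct)
    if (nrow(g)) cbind(cell_type = ct, g) else NULL
  }))
  if (is.null(ngenes)) {
    ngenes <- data.frame(cell_type = character(), gene = character(),
                         pearson_r = numeric(), p = numeric(),
                         fdr = numeric(), direction = character())
  }
  add(ngenes, "noise_genes.tsv")

  log("[deg] aging DEGs per cell type")
  deg_tabs <- list()
  for (ct in sort(unique(meta$cell_type))) {
    sub <- meta[meta$cell_type == ct, ]
    if (min(sum(sub$group == "young"), sum(sub$group == "aged")) < 3) next
    deg_tabs[[ct]] <- wilcoxon_deg(nm, meta, ct,
                                   min_pct = prm$deg$min_pct,
                                   lfc_prefilter = prm$deg$lfc_prefilter,
                                   padj_max = prm$deg$padj_max,
                                   lfc_sig = prm$deg$lfc_sig)
    add(deg_tabs[[ct]], sprintf("deg_%s.tsv", ct))
  }
  if (length(deg_tabs) >= 3) {
    add(shared_degs(deg_tabs, k_min = 3), "shared_degs.tsv")
  } else skipped <- c(skipped, "shared_degs")

  if (!is.null(zonation)) {
    log("[modules] zonation overlap modules")
    zmeta <- meta[meta$cell_id %in% zonation$cell_id, , drop = FALSE]
    zmeta$cell_type <- zonation$zone[match(zmeta$cell_id, zonation$cell_id)]
    ztabs <- lapply(c(PP = "PP", MZ = "MZ", PC = "PC"), function(z)
      wilcoxon_deg(nm, zmeta, z, min_pct = prm$deg$min_pct,
                   lfc_prefilter = prm$deg$lfc_prefilter,
                   padj_max = prm$deg$padj_max, lfc_sig = prm$deg$lfc_sig))
    mods <- overlap_modules(ztabs$PP, ztabs$MZ, ztabs$PC)
    add(mods$modules, "zonation_modules.tsv")
    add(mods$discordant, "zonation_discordant.tsv")
  } else skipped <- c(skipped, "modules")

  if (!is.null(config$signature) && length(deg_tabs)) {
    ext <- read_signature(config$signature)
    ov <- lapply(deg_tabs, signed_external_overlap, external = ext)
    tab <- do.call(rbind, lapply(names(ov), function(ct) {
      o <- ov[[ct]]
      genes <- c(o$co_up, o$co_down, o$discordant)
      data.frame(cell_type = rep(ct, length(genes)),
                 class = rep(c("co_up", "co_down", "discordant"),
                             c(length(o$co_up), length(o$co_down),
                               length(o$discordant))),
                 gene = genes, stringsAsFactors = FALSE)
    }))
    add(tab, "signed_overlap.tsv")
  } else skipped <- c(skipped, "signed_overlap")

  if (!is.null(config$lr_pairs)) {
    log("[crosstalk] permutation test per group")
    pairs <- read_lr_pairs(config$lr_pairs)
    recs <- lapply(c(young = "young", aged = "aged"), function(g)
      permutation_test(nm, meta, pairs, g, n_perm = prm$crosstalk$n_perm,
                       seed = derive_seed(seed, "crosstalk"),
                       min_pct = prm$crosstalk$min_pct,
                       p_max = prm$crosstalk$p_max))
    add(recs$young, "interactions_young.tsv")
    add(recs$aged, "interactions_aged.tsv")
    dn <- differential_network(recs$young, recs$aged)
    add(dn$edges, "diff_edges.tsv")
  } else {
    log("[crosstalk] no LR pairs configured; stage skipped")
    skipped <- c(skipped, "crosstalk")
  }

  if (!is.null(config$terms_gmt) && length(deg_tabs)) {
    log("[termnet] enrichment + kappa graph")
    terms <- read_gmt(config$terms_gmt)
    universe <- nm$gene_ids
    degs <- unique(unlist(lapply(deg_tabs, function(t)
      t$gene[t$significant])))
    terms <- lapply(terms, intersect, y = universe)
    terms <- terms[lengths(terms) > 0]
    enr <- hypergeom_enrich(intersect(degs, universe), terms, universe)
    add(enr, "term_enrichment.tsv")
    sel_terms <- terms[enr$term[enr$p <= 0.05]]
    if (length(sel_terms) >= 2) {
      tg <- build_term_graph(sel_terms,
                             threshold = prm$termnet$kappa_threshold)
      write_term_graph(tg, file.path(out, "term_edges.tsv"),
                       file.path(out, "term_graph.graphml"))
      written <- c(written, file.path(out, "term_edges.tsv"))
    } else skipped <- c(skipped, "term_graph")
  } else skipped <- c(skipped, "termnet")

  manifest <- list(
    package = "livage",
    version = as.character(utils::packageVersion("livage")),
    seed = seed, parameters = prm,
    skipped_stages = skipped,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log(sprintf("[done] %d outputs in %s", length(written), out))
  invisible(out)
}

#' Summarize a completed pipeline run
#'
#' Deterministic aggregation of the stage TSVs into compact summary tables
#' mirroring the headline figures: per-type noise ratios, DEG counts,
#' overlap-module counts and differential-edge counts.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @return List of data.frames: `noise`, `deg_counts`, `module_counts`,
#'   `diff_edges` (NULL where the stage was skipped).
#' @export
make_report <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.json"))) {
    stop(sprintf("incomplete run: no manifest.json in %s", run_dir))
  }
  rd <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) return(NULL)
    utils::read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  }
  noise <- rd("noise_summary.tsv")
  deg_files <- list.files(run_dir, pattern = "^deg_.*\\.tsv$",
                          full.names = TRUE)
  deg_counts <- do.call(rbind, lapply(deg_files, function(f) {
    t <- utils::read.table(f, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    data.frame(cell_type = sub("^deg_(.*)\\.tsv$", "\\1", basename(f)),
               n_up = sum(t$significant & t$direction == "up"),
               n_down = sum(t$significant & t$direction == "down"),
               stringsAsFactors = FALSE)
  }))
  mods <- rd("zonation_modules.tsv")
  module_counts <- NULL
  if (!is.null(mods)) {
    tab <- as.data.frame(table(module_id = mods$module_id),
                         stringsAsFactors = FALSE)
    tab$module_id <- as.integer(tab$module_id)
    module_counts <- merge(module_classes(), tab, by = "module_id",
                           all.x = TRUE)
    module_counts$Freq[is.na(module_counts$Freq)] <- 0L
    names(module_counts)[names(module_counts) == "Freq"] <- "n_genes"
    module_counts$module_id <- as.integer(module_counts$module_id)
    module_counts <- module_counts[order(module_counts$module_id), ]
    row.names(module_counts) <- NULL
  }
  list(noise = noise, deg_counts = deg_counts,
       module_counts = module_counts, diff_edges = rd("diff_edges.tsv"))
}
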