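# Pipeline orchestration: simulate -> differential expression -> gene-set
# scoring -> lot consistency -> report, with a run manifest. Files are the
# contract between stages; every stage is also callable on its own.

#' Pipeline configuration
#'
#' All analysis thresholds in one place. Defaults: DE at q <= 0.1, module
#' activation at z >= 2, 10,000 permutation draws, SD summary thresholds 0.5
#' and 1.0, top-10 gene tables, >= 3 measured members per scored set, a
#' +/- 0.6 neutral display band for heat-map exports, and the high dose vs
#' control contrast.
#'
#' @param q_max FDR threshold for DE calls.
#' @param z_activation Module activation threshold on the permutation z.
#' @param n_perm Permutation draws per set score (>= 100).
#' @param seed Master seed for every random stage.
#' @param sd_thresholds Thresholds for SD "fraction below" summaries.
#' @param top_k Rows per top-gene table.
#' @param min_genes Minimum measured members to score a set.
#' @param heatmap_clip Half-width of the neutral display band.
#' @param treated,control Contrast conditions.
#' @return Object of class `PipelineConfig` (a named list).
#' @export
pipeline_config <- function(q_max = 0.1, z_activation = 2.0, n_perm = 10000,
                            seed = 1L, sd_thresholds = c(0.5, 1.0),
                            top_k = 10, min_genes = 3, heatmap_clip = 0.6,
                            treated = "high", control = "control") {
  if (q_max <= 0 || z_activation <= 0 || top_k < 1 || min_genes < 1 ||
      heatmap_clip <= 0 || any(sd_thresholds <= 0))
    stop("all thresholds must be positive")
  if (n_perm < 100) stop("n_perm must be >= 100")
  structure(list(q_max = q_max, z_activation = z_activation,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 sd_thresholds = sd_thresholds, top_k = as.integer(top_k),
                 min_genes = as.integer(min_genes),
                 heatmap_clip = heatmap_clip, treated = treated,
                 control = control),
            class = c("PipelineConfig", "list"))
}

stage_stop <- function(stage, e) {
  stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Reads an expression study and gene sets, computes per-lot fold-change
#' tables, scores injury modules (AAFC) and pathways (AFC) with permutation
#' nulls, computes feature-set toxicity scores, assembles the lot-consistency
#' report, and writes every result table plus a JSON run manifest to
#' `out_dir`. Deterministic given config + seed.
#'
#' @param config A [pipeline_config()].
#' @param matrix_path,samples_path Expression matrix and sample sheet TSVs.
#' @param gmt_paths Named character vector of GMT paths; names give each
#'   file's category (`injury_module`, `pathway`, `feature_set`). May be
#'   empty.
#' @param out_dir Output directory.
#' @param panel_genes Optional gene panel for the panel table.
#' @return Invisibly, a list with the in-memory results (`fc_tables`,
#'   `module_scores`, `pathway_scores`, `feature_scores`, `consistency`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, matrix_path, samples_path,
                         gmt_paths = character(0), out_dir,
                         panel_genes = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  for (p in c(matrix_path, samples_path, unname(gmt_paths)))
    if (!file.exists(p)) stop("[stage: input] missing input file: ", p,
                              call. = FALSE)

  study <- tryCatch(read_expression_study(matrix_path, samples_path),
                    error = function(e) stage_stop("input", e))
  collections <- tryCatch(
    Map(read_gene_sets, gmt_paths, names(gmt_paths)),
    error = function(e) stage_stop("input", e))

  fc_tables <- tryCatch(
    fold_change_tables(study, treated = config$treated,
                       control = config$control, q_max = config$q_max),
    error = function(e) stage_stop("diffexpr", e))
  for (lot in names(fc_tables))
    write_table(as.data.frame(fc_tables[[lot]]),
                file.path(out_dir, paste0("de_", lot, ".tsv")), digits = 6)

  score_one <- function(coll, method) {
    tryCatch(
      score_collection(fc_tables, coll, method, n_perm = config$n_perm,
                       seed = config$seed, z_activation = config$z_activation,
                       min_genes = config$min_genes),
      error = function(e) stage_stop("geneset_scoring", e))
  }
  pick <- function(cat) {
    hits <- collections[names(collections) == cat]
    if (length(hits)) merge_collections(hits) else NULL
  }
  module_scores <- pathway_scores <- feature_scores <- NULL
  modules <- pick("injury_module")
  if (!is.null(modules)) {
    module_scores <- score_one(modules, "AAFC")
    write_table(module_scores$scores,
                file.path(out_dir, "module_scores.tsv"), digits = 6)
    write_matrix(module_scores$z_matrix,
                 file.path(out_dir, "module_z_matrix.tsv"))
  }
  pathways <- pick("pathway")
  if (!is.null(pathways)) {
    pathway_scores <- score_one(pathways, "AFC")
    write_table(pathway_scores$scores,
                file.path(out_dir, "pathway_scores.tsv"), digits = 6)
    write_matrix(pathway_scores$z_matrix,
                 file.path(out_dir, "pathway_z_matrix.tsv"))
  }
  features <- pick("feature_set")
  if (!is.null(features)) {
    feature_scores <- tryCatch(
      feature_set_scores(fc_tables, features, config$min_genes),
      error = function(e) stage_stop("geneset_scoring", e))
    write_table(feature_scores$per_lot,
                file.path(out_dir, "feature_scores.tsv"), digits = 6)
    write_table(feature_scores$summary,
                file.path(out_dir, "feature_summary.tsv"), digits = 6)
  }

  consistency <- tryCatch(
    consistency_report(fc_tables, q_max = config$q_max,
                       sd_thresholds = config$sd_thresholds,
                       top_k = config$top_k, panel_genes = panel_genes),
    error = function(e) stage_stop("lot_consistency", e))
  write_consistency(consistency, out_dir, config)

  manifest <- list(
    config = unclass(config),
    inputs = c(list(matrix = unname(tools::md5sum(matrix_path)),
                    samples = unname(tools::md5sum(samples_path))),
               lapply(stats::setNames(unname(gmt_paths), names(gmt_paths)),
                      function(p) unname(tools::md5sum(p)))),
    n_genes = length(study$genes), n_samples = length(study$samples),
    lots = sort(unique(study$annotations$lot)),
    de_counts = as.list(vapply(fc_tables,
                               function(t) sum(t$significant), numeric(1))),
    n_common_genes = length(consistency$common_genes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("pipeline complete: ", out_dir)
  invisible(list(fc_tables = fc_tables, module_scores = module_scores,
                 pathway_scores = pathway_scores,
                 feature_scores = feature_scores,
                 consistency = consistency, manifest = manifest))
}

merge_collections <- function(colls) {
  sets <- do.call(c, lapply(unname(colls), function(x) x$sets))
  if (anyDuplicated(names(sets)))
    stop("duplicate set_id across GMT files of one category")
  structure(list(sets = sets), class = "GeneSetCollection")
}

write_matrix <- function(m, path, digits = 6) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path, digits = digits)
}

write_consistency <- function(rep, out_dir, config) {
  write_matrix(rep$overlap, file.path(out_dir, "overlap.tsv"), digits = 0)
  writeLines(rep$common_genes, file.path(out_dir, "common_genes.txt"))
  write_table(data.frame(gene = names(rep$merged_fc),
                         merged_fc = unname(rep$merged_fc),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "merged_fc.tsv"), digits = 6)
  if (!is.null(rep$correlation_all))
    write_matrix(rep$correlation_all,
                 file.path(out_dir, "correlations_all.tsv"))
  if (!is.null(rep$correlation_common))
    write_matrix(rep$correlation_common,
                 file.path(out_dir, "correlations_common.tsv"))
  if (!is.null(rep$sd_all))
    write_table(data.frame(gene = names(rep$sd_all$sd),
                           sd = unname(rep$sd_all$sd),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "sd_profile.tsv"), digits = 6)
  if (!is.null(rep$top_genes)) {
    up <- rep$top_genes$up; up$direction <- "up"
    dn <- rep$top_genes$down; dn$direction <- "down"
    write_table(rbind(up, dn), file.path(out_dir, "top_genes.tsv"),
                digits = 6)
  }
  if (!is.null(rep$panel))
    write_table(rep$panel, file.path(out_dir, "panel.tsv"), digits = 6)
  invisible(NULL)
}

#' Export a matrix with heat-map display metadata
#'
#' Writes the raw values unchanged plus a parallel class annotation: cells
#' with |value| <= `clip` fall in the neutral band; values above/below are
#' classed `up` / `down`. Mirrors the display convention of showing fold
#' changes within +/- 0.6 as neutral.
#'
#' @param m Numeric matrix with row and column names.
#' @param clip Half-width of the neutral band (default 0.6).
#' @param path Output TSV path for the raw values; a sibling
#'   `<path>.classes.tsv` gets the band classes.
#' @return Invisibly, the character matrix of band classes.
#' @export
export_heatmap_matrix <- function(m, clip = 0.6, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  classes <- matrix(ifelse(abs(m) <= clip, "neutral",
                           ifelse(m > 0, "up", "down")),
                    nrow = nrow(m), dimnames = dimnames(m))
  write_matrix(m, path, digits = 6)
  write_matrix_chr(classes, paste0(path, ".classes.tsv"))
  invisible(classes)
}

write_matrix_chr <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
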