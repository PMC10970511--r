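# Lot-to-lot consistency analytics: DE overlap matrix, common genes, merged
# fold changes, correlation matrices, SD profiles, cross-lot summary stats,
# top-k gene tables, and sign-consistency flags for gene panels.

#' Pairwise overlap matrix of per-lot DE gene sets
#'
#' Entry (i, j) is the number of genes called differentially expressed in
#' both lot i and lot j; the diagonal carries the per-lot DE counts.
#'
#' @param de_sets Named list of character vectors (one DE gene set per lot).
#' @return Symmetric integer matrix, lots x lots.
#' @export
overlap_matrix <- function(de_sets) {
  stopifnot(length(de_sets) >= 1)
  de_sets <- lapply(de_sets, unique)
  lots <- names(de_sets)
  m <- matrix(0L, length(lots), length(lots), dimnames = list(lots, lots))
  for (i in seq_along(lots))
    for (j in i:length(lots)) {
      m[i, j] <- m[j, i] <- length(intersect(de_sets[[i]], de_sets[[j]]))
    }
  m
}

#' Genes differentially expressed in every lot
#'
#' @param de_sets Named list of character vectors (>= 2 lots).
#' @return Character vector: the intersection across all lots.
#' @export
common_genes <- function(de_sets) {
  stopifnot(length(de_sets) >= 2)
  Reduce(intersect, de_sets)
}

#' Merged (cross-lot average) fold change per gene
#'
#' The merged lot is the unweighted arithmetic mean of the per-lot log2 fold
#' changes, gene by gene, over the genes measured in every lot. Genes missing
#' from any lot are dropped with a warning.
#'
#' @param fc_tables Named list of `FoldChangeTable`s or named FC vectors.
#' @return Named numeric vector of merged fold changes.
#' @export
merged_fold_change <- function(fc_tables) {
  maps <- lapply(fc_tables, fc_map)
  shared <- Reduce(intersect, lapply(maps, names))
  if (!length(shared)) stop("no gene measured in every lot")
  n_union <- length(unique(unlist(lapply(maps, names))))
  if (n_union > length(shared))
    warning(n_union - length(shared),
            " gene(s) missing from at least one lot were dropped")
  mat <- matrix(unlist(lapply(maps, function(m) m[shared])),
                nrow = length(shared), dimnames = list(shared, names(maps)))
  rowMeans(mat)
}

#' Pearson correlation matrix of per-lot (and merged) fold-change vectors
#'
#' Correlates the per-lot FC vectors, plus the merged average as an extra
#' column, restricted to an optional gene subset (e.g. the common-gene set).
#' The merged column includes each lot's own contribution, mirroring the
#' usual lot-vs-consensus display. Zero-variance vectors give NA cells.
#'
#' @inheritParams merged_fold_change
#' @param merged Optional precomputed merged FC vector; computed if NULL.
#' @param gene_subset Optional character vector restricting the evaluation
#'   universe (default: genes shared by all lots).
#' @return Symmetric numeric matrix (lots + merged) squared, unit diagonal.
#' @export
correlation_matrix <- function(fc_tables, merged = NULL, gene_subset = NULL) {
  maps <- lapply(fc_tables, fc_map)
  if (is.null(merged)) merged <- suppressWarnings(merged_fold_change(fc_tables))
  maps$merged <- merged
  shared <- Reduce(intersect, lapply(maps, names))
  if (!is.null(gene_subset)) shared <- intersect(shared, gene_subset)
  if (length(shared) < 2)
    stop("fewer than 2 shared genes in the evaluation subset")
  mat <- vapply(maps, function(m) m[shared], numeric(length(shared)))
  r <- suppressWarnings(stats::cor(mat, method = "pearson"))
  diag(r) <- ifelse(apply(mat, 2, stats::sd) > 0, 1, NA_real_)
  r
}

#' Cross-lot SD profile with threshold fractions
#'
#' Sample standard deviation (n-1 denominator) of the per-lot fold changes
#' (or per-set z-scores) for each gene/set, plus the fraction of genes
#' strictly below each threshold.
#'
#' @inheritParams merged_fold_change
#' @param thresholds Numeric thresholds for the "fraction below" summary
#'   (default `c(0.5, 1)`).
#' @param gene_subset Optional restriction of the gene universe.
#' @return List with `sd` (named numeric vector) and `fraction_below`
#'   (named numeric vector, one entry per threshold).
#' @export
sd_profile <- function(fc_tables, thresholds = c(0.5, 1),
                       gene_subset = NULL) {
  stopifnot(length(fc_tables) >= 2)
  maps <- lapply(fc_tables, fc_map)
  shared <- Reduce(intersect, lapply(maps, names))
  if (!is.null(gene_subset)) shared <- intersect(shared, gene_subset)
  mat <- matrix(unlist(lapply(maps, function(m) m[shared])),
                nrow = length(shared), dimnames = list(shared, names(maps)))
  sds <- apply(mat, 1, stats::sd)
  names(sds) <- shared
  frac <- vapply(thresholds, function(th) mean(sds < th), numeric(1))
  names(frac) <- as.character(thresholds)
  list(sd = sds, fraction_below = frac)
}

#' Cross-lot mean and sample SD
#'
#' The summary pair printed in per-gene/per-set report tables: arithmetic
#' mean and sample standard deviation (n-1 denominator) of per-lot values.
#'
#' @param values Numeric vector, one value per lot (>= 2).
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
cross_lot_stats <- function(values) {
  if (length(values) < 2) stop("need at least 2 per-lot values")
  c(mean = mean(values), sd = stats::sd(values))
}

#' Top up- and down-regulated genes by merged fold change
#'
#' Ranks genes (typically restricted to the common-gene set) by merged FC:
#' the up table holds the k largest, the down table the k smallest. Ties are
#' broken by gene symbol ascending. Each row carries the merged FC and the
#' cross-lot SD.
#'
#' @param merged_fc Named numeric vector of merged fold changes (already
#'   restricted to the universe of interest).
#' @param k Number of genes per table (default 10); truncated with a warning
#'   if it exceeds the available genes.
#' @param sd_values Named numeric vector of cross-lot SDs (e.g.
#'   `sd_profile(...)$sd`).
#' @return List of two data frames `up` and `down`, columns `gene`,
#'   `merged_fc`, `sd`.
#' @export
top_k_genes <- function(merged_fc, k = 10, sd_values = NULL) {
  stopifnot(k >= 1)
  if (k > length(merged_fc)) {
    warning("k = ", k, " exceeds available genes (", length(merged_fc),
            "); truncated")
    k <- length(merged_fc)
  }
  genes <- names(merged_fc)
  take <- function(decreasing) {
    ord <- order(merged_fc, genes,
                 decreasing = c(decreasing, FALSE), method = "radix")
    sel <- genes[ord][seq_len(k)]
    data.frame(gene = sel, merged_fc = unname(merged_fc[sel]),
               sd = if (is.null(sd_values)) NA_real_
                    else unname(sd_values[sel]),
               stringsAsFactors = FALSE)
  }
  list(up = take(TRUE), down = take(FALSE))
}

#' Sign consistency of per-lot fold changes
#'
#' `consistent_up` if every lot's FC is strictly positive, `consistent_down`
#' if strictly negative, otherwise `mixed` (an exact zero breaks
#' consistency). Used for the star annotation of panel genes that are
#' nowhere significant yet move the same way in every lot.
#'
#' @param per_lot_fc Numeric vector of per-lot fold changes (>= 2).
#' @return One of `"consistent_up"`, `"consistent_down"`, `"mixed"`.
#' @export
sign_consistency <- function(per_lot_fc) {
  stopifnot(length(per_lot_fc) >= 2)
  if (all(per_lot_fc > 0)) "consistent_up"
  else if (all(per_lot_fc < 0)) "consistent_down"
  else "mixed"
}

#' Gene-panel report table
#'
#' For a user-specified panel of genes (e.g. hepatocyte transporters or
#' cytochrome P450 enzymes), reports each lot's fold change, the cross-lot
#' mean and sample SD, the sign-consistency flag, and whether the gene is
#' significant in any lot. The `starred` column marks the panel convention:
#' consistent direction in every lot while significant in none.
#'
#' @inheritParams merged_fold_change
#' @param panel_genes Character vector of gene symbols.
#' @return Data frame: `gene`, one `fc_<lot>` column per lot, `mean`, `sd`,
#'   `consistency`, `any_significant`, `starred`. Panel genes measured in no
#'   lot are dropped with a warning.
#' @export
panel_table <- function(fc_tables, panel_genes) {
  lots <- names(fc_tables)
  maps <- lapply(fc_tables, fc_map)
  shared <- Reduce(intersect, lapply(maps, names))
  missing <- setdiff(panel_genes, shared)
  if (length(missing))
    warning("panel gene(s) not measured in every lot, dropped: ",
            paste(missing, collapse = ", "))
  panel_genes <- intersect(panel_genes, shared)
  sig <- lapply(fc_tables, function(t) {
    if (is.data.frame(t)) t$gene[t$significant] else character(0)
  })
  rows <- lapply(panel_genes, function(g) {
    v <- vapply(maps, function(m) m[[g]], numeric(1))
    st <- cross_lot_stats(v)
    any_sig <- any(vapply(sig, function(s) g %in% s, logical(1)))
    flag <- sign_consistency(v)
    row <- c(list(gene = g), as.list(stats::setNames(v, paste0("fc_", lots))),
             list(mean = st[["mean"]], sd = st[["sd"]], consistency = flag,
                  any_significant = any_sig,
                  starred = flag != "mixed" && !any_sig))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full lot-consistency report
#'
#' Convenience wrapper assembling the consistency analytics from per-lot
#' fold-change tables: DE overlap matrix, common genes, merged FC,
#' correlation matrices on the all-gene and common-gene universes, SD
#' profiles, top-k tables, and an optional gene-panel table.
#'
#' @inheritParams merged_fold_change
#' @param q_max FDR threshold for DE calls (default 0.1).
#' @param sd_thresholds Thresholds for the SD "fraction below" summaries.
#' @param top_k Rows per top-gene table.
#' @param panel_genes Optional gene panel for [panel_table()].
#' @return Object of class `ConsistencyReport` (a named list).
#' @export
consistency_report <- function(fc_tables, q_max = 0.1,
                               sd_thresholds = c(0.5, 1), top_k = 10,
                               panel_genes = NULL) {
  lots <- names(fc_tables)
  de_sets <- lapply(fc_tables, call_significant, q_max = q_max)
  single_lot <- length(fc_tables) < 2
  merged <- suppressWarnings(merged_fold_change(fc_tables))
  common <- if (single_lot) de_sets[[1]] else common_genes(de_sets)
  sd_all <- if (single_lot) NULL else sd_profile(fc_tables, sd_thresholds)
  sd_common <- if (single_lot || !length(common)) NULL
               else sd_profile(fc_tables, sd_thresholds, gene_subset = common)
  cor_all <- if (single_lot) NULL else correlation_matrix(fc_tables, merged)
  cor_common <- if (single_lot || length(common) < 2) NULL
                else correlation_matrix(fc_tables, merged, gene_subset = common)
  top <- if (length(common))
    top_k_genes(merged[intersect(names(merged), common)], top_k,
                sd_values = sd_common$sd)
  else NULL
  panel <- if (!is.null(panel_genes) && !single_lot)
    panel_table(fc_tables, panel_genes) else NULL
  structure(
    list(lots = lots, overlap = overlap_matrix(de_sets),
         common_genes = common, merged_fc = merged,
         correlation_all = cor_all, correlation_common = cor_common,
         sd_all = sd_all, sd_common = sd_common,
         top_genes = top, panel = panel),
    class = "ConsistencyReport"
  )
}

#' @export
print.ConsistencyReport <- function(x, ...) {
  cat("ConsistencyReport over", length(x$lots), "lot(s)\n")
  cat("  per-lot DE counts:",
      paste(diag(x$overlap), collapse = ", "), "\n")
  cat("  common genes:", length(x$common_genes), "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Table-style rounding (2.5 -> 3, -2.5 -> -3) used for display columns in
#' report tables; raw full-precision values are always emitted alongside.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
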