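# Per-lot differential expression: log2 fold change (difference of mean log2
# expression, treated minus control), Welch t-test p-values, BH q-values.

check_arm <- function(study, lot, condition) {
  if (!lot %in% study$annotations$lot)
    stop("unknown lot: ", lot)
  if (!condition %in% CONDITION_LEVELS)
    stop("unknown condition: ", condition)
  ids <- arm_samples(study, lot, condition)
  if (length(ids) < 2)
    stop("lot ", lot, ", condition ", condition, ": fewer than 2 replicates")
  ids
}

#' Per-gene log2 fold change for one lot
#'
#' Fold change is the difference of mean log2 expression, treated arm minus
#' control arm, computed per gene within one lot.
#'
#' @param study An `ExpressionStudy`.
#' @param lot Lot id.
#' @param treated,control Condition labels of the two arms
#'   (defaults: high dose vs control).
#' @return Named numeric vector, one log2 FC per gene.
#' @export
compute_fold_changes <- function(study, lot, treated = "high",
                                 control = "control") {
  t_ids <- check_arm(study, lot, treated)
  c_ids <- check_arm(study, lot, control)
  rowMeans(study$values[, t_ids, drop = FALSE]) -
    rowMeans(study$values[, c_ids, drop = FALSE])
}

#' Per-gene Welch t-test for one lot
#'
#' Two-sided unequal-variance t-test of treated vs control log2 expression,
#' with Welch--Satterthwaite degrees of freedom, vectorised over genes.
#' A gene with zero variance in both arms and equal means gets p = 1; zero
#' variance with unequal means gets p = 0 (infinite t).
#'
#' @inheritParams compute_fold_changes
#' @return Named numeric vector of two-sided p-values.
#' @export
welch_test <- function(study, lot, treated = "high", control = "control") {
  t_ids <- check_arm(study, lot, treated)
  c_ids <- check_arm(study, lot, control)
  x <- study$values[, t_ids, drop = FALSE]
  y <- study$values[, c_ids, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate genes: no variance in either arm
  degen <- se2 == 0
  if (any(degen)) p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  names(p) <- study$genes
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort p ascending, q_(i) = min over j >= i of
#' p_(j) * n / j, capped at 1. Delegates to [stats::p.adjust()]; names are
#' preserved.
#'
#' @param p_values Named numeric vector of p-values in \[0, 1\].
#' @return Named vector of q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Full per-lot fold-change table
#'
#' Combines [compute_fold_changes()], [welch_test()] and [bh_adjust()] into
#' the per-lot differential-expression table, with the significance call at
#' q <= `q_max` (boundary inclusive).
#'
#' @inheritParams compute_fold_changes
#' @param q_max FDR threshold for the `significant` flag (default 0.1).
#' @return Object of class `FoldChangeTable`: a data frame with columns
#'   `gene`, `log2_fc`, `p_raw`, `q_value`, `significant`, and attributes
#'   `lot`, `treated`, `control`, `q_max`.
#' @export
fold_change_table <- function(study, lot, treated = "high",
                              control = "control", q_max = 0.1) {
  fc <- compute_fold_changes(study, lot, treated, control)
  p <- welch_test(study, lot, treated, control)
  q <- bh_adjust(p)
  tab <- data.frame(gene = study$genes, log2_fc = unname(fc),
                    p_raw = unname(p), q_value = unname(q),
                    significant = unname(q <= q_max),
                    stringsAsFactors = FALSE)
  attr(tab, "lot") <- lot
  attr(tab, "treated") <- treated
  attr(tab, "control") <- control
  attr(tab, "q_max") <- q_max
  class(tab) <- c("FoldChangeTable", "data.frame")
  tab
}

#' Significant genes of a fold-change table
#'
#' @param fc_table A `FoldChangeTable` (or any data frame with `gene` and
#'   `q_value` columns).
#' @param q_max FDR threshold; genes with q <= `q_max` are returned.
#' @return Character vector of gene symbols.
#' @export
call_significant <- function(fc_table, q_max = 0.1) {
  fc_table$gene[fc_table$q_value <= q_max]
}

#' Fold-change tables for every lot
#'
#' @inheritParams fold_change_table
#' @param lots Lots to process (default: all lots in the study, sorted).
#' @return Named list of `FoldChangeTable`s, one per lot.
#' @export
fold_change_tables <- function(study, lots = NULL, treated = "high",
                               control = "control", q_max = 0.1) {
  if (is.null(lots)) lots <- sort(unique(study$annotations$lot))
  stats::setNames(
    lapply(lots, fold_change_table, study = study, treated = treated,
           control = control, q_max = q_max),
    lots
  )
}

# named FC vector from a FoldChangeTable (or pass a named vector through)
fc_map <- function(x) {
  if (is.data.frame(x)) stats::setNames(x$log2_fc, x$gene) else x
}
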