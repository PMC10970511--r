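# Gene-set scoring: aggregated absolute fold change (AAFC) and aggregated
# fold change (AFC), permutation nulls over random same-sized gene subsets,
# z-scores and empirical p-values, activation calls, toxicity feature-set
# scores, and a generic hypergeometric over-representation test.

SCORE_METHODS <- c("AAFC", "AFC")

set_score_raw <- function(fc_values, method) {
  if (method == "AAFC") mean(abs(fc_values)) else mean(fc_values)
}

#' Aggregated absolute fold change of a gene set
#'
#' Mean of |log2 FC| over the set's members that are present in the
#' fold-change map; unmeasured members are ignored but counted. This is the
#' direction-blind injury-module score.
#'
#' @param fc Named numeric vector of per-gene log2 fold changes (or a
#'   `FoldChangeTable`).
#' @param members Character vector of member gene symbols.
#' @param min_genes Minimum measured members required to score (default 3).
#' @return List with `score` and `n_measured`.
#' @export
aafc_score <- function(fc, members, min_genes = 3) {
  fc <- fc_map(fc)
  present <- unique(members)[unique(members) %in% names(fc)]
  if (length(present) < min_genes)
    stop("only ", length(present), " measured member(s); min_genes = ",
         min_genes)
  list(score = mean(abs(fc[present])), n_measured = length(present))
}

#' Aggregated (signed) fold change of a gene set
#'
#' Mean of signed log2 FC over measured members; carries the up/down
#' direction of the set, used for pathway display.
#'
#' @inheritParams aafc_score
#' @return List with `score` and `n_measured`.
#' @export
afc_score <- function(fc, members, min_genes = 3) {
  fc <- fc_map(fc)
  present <- unique(members)[unique(members) %in% names(fc)]
  if (length(present) < min_genes)
    stop("only ", length(present), " measured member(s); min_genes = ",
         min_genes)
  list(score = mean(fc[present]), n_measured = length(present))
}

#' Permutation null distribution for a set score
#'
#' Draws `n_perm` random gene subsets of the given size, uniformly without
#' replacement from the measured-gene universe of `fc`, and scores each with
#' the chosen method. The null mean and SD feed the z-score; the null scores
#' feed the empirical p-value.
#'
#' @inheritParams aafc_score
#' @param set_size Number of genes per random draw.
#' @param method `"AAFC"` or `"AFC"`.
#' @param n_perm Number of random draws (default 10000).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return Object of class `PermutationNull`: list with `set_size`, `n_perm`,
#'   `seed`, `null_scores`, `null_mean`, `null_sd`, `degenerate`.
#' @export
permutation_null <- function(fc, set_size, method = c("AAFC", "AFC"),
                             n_perm = 10000, seed = 1L) {
  fc <- fc_map(fc)
  method <- match.arg(method)
  n <- length(fc)
  if (set_size > n)
    stop("set_size (", set_size, ") exceeds measured universe (", n, ")")
  vals <- if (method == "AAFC") abs(unname(fc)) else unname(fc)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n, set_size),
                integer(set_size))
  null_scores <- colMeans(matrix(vals[idx], nrow = set_size))
  null_sd <- stats::sd(null_scores)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  structure(
    list(set_size = set_size, n_perm = n_perm, seed = seed,
         method = method, null_scores = null_scores,
         null_mean = mean(null_scores), null_sd = null_sd,
         degenerate = degenerate),
    class = "PermutationNull"
  )
}

# save/restore the global RNG state so scoring does not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Score one gene set against its permutation null
#'
#' Computes the raw AAFC/AFC score, the permutation z-score
#' `z = (raw - null_mean) / null_sd`, the add-one empirical p-value
#' `p = (1 + #\{null >= raw\}) / (n_perm + 1)`, and the activation call
#' `z >= z_activation`. A degenerate null (zero SD) yields z = 0 with a
#' warning. For AFC a signed display z (`z_signed`) is also reported: the
#' z-magnitude of |raw| against the null of |scores|, carrying the sign of
#' the raw score.
#'
#' @inheritParams permutation_null
#' @param members Character vector of member gene symbols.
#' @param z_activation Activation threshold on the z-score (default 2).
#' @param min_genes Minimum measured members (default 3).
#' @param set_id Optional set identifier carried into the result row.
#' @return Object of class `ModuleScore`: one-row data frame with columns
#'   `set_id`, `method`, `n_measured`, `raw_score`, `z_score`, `z_signed`,
#'   `p_perm`, `activated`.
#' @export
score_set <- function(fc, members, method = c("AAFC", "AFC"),
                      n_perm = 10000, seed = 1L, z_activation = 2,
                      min_genes = 3, set_id = NA_character_) {
  fc <- fc_map(fc)
  method <- match.arg(method)
  raw <- if (method == "AAFC") aafc_score(fc, members, min_genes)
         else afc_score(fc, members, min_genes)
  null <- permutation_null(fc, raw$n_measured, method, n_perm, seed)
  p_perm <- (1 + sum(null$null_scores >= raw$score)) / (n_perm + 1)
  if (null$degenerate) {
    warning("degenerate permutation null (zero SD); z set to 0")
    z <- 0
  } else {
    z <- (raw$score - null$null_mean) / null$null_sd
  }
  z_signed <- z
  if (method == "AFC" && !null$degenerate) {
    abs_null <- abs(null$null_scores)
    s <- stats::sd(abs_null)
    mag <- if (s > 0) (abs(raw$score) - mean(abs_null)) / s else 0
    z_signed <- sign(raw$score) * mag
  }
  structure(
    data.frame(set_id = set_id, method = method,
               n_measured = raw$n_measured, raw_score = raw$score,
               z_score = z, z_signed = z_signed, p_perm = p_perm,
               activated = z >= z_activation,
               stringsAsFactors = FALSE),
    class = c("ModuleScore", "data.frame")
  )
}

#' Score a gene-set collection across all lots
#'
#' Scores every (set, lot) pair with the chosen method and appends a merged
#' column per set: the unweighted mean of the per-lot z-scores (the consensus
#' display used in module/pathway heat maps). Sets with fewer than
#' `min_genes` measured members are reported with NA scores rather than
#' dropped.
#'
#' @param fc_tables Named list (one element per lot) of `FoldChangeTable`s or
#'   named FC vectors.
#' @param sets A `GeneSetCollection`.
#' @inheritParams score_set
#' @return List with `scores` (long data frame: set_id, category, lot,
#'   method, n_measured, raw_score, z_score, z_signed, p_perm, activated) and
#'   `z_matrix` (sets x lots+merged matrix of z-scores).
#' @export
score_collection <- function(fc_tables, sets, method = c("AAFC", "AFC"),
                             n_perm = 10000, seed = 1L, z_activation = 2,
                             min_genes = 3) {
  stopifnot(inherits(sets, "GeneSetCollection"), length(fc_tables) >= 1)
  method <- match.arg(method)
  lots <- names(fc_tables)
  set_ids <- names(sets$sets)
  rows <- list()
  zmat <- matrix(NA_real_, nrow = length(set_ids), ncol = length(lots) + 1,
                 dimnames = list(set_ids, c(lots, "merged")))
  for (li in seq_along(lots)) {
    fc <- fc_map(fc_tables[[li]])
    # one sub-seed per lot so lots are independent but reproducible
    lot_seed <- derive_seed(seed, li)
    for (si in seq_along(set_ids)) {
      s <- sets$sets[[si]]
      measured <- sum(unique(s$members) %in% names(fc))
      if (measured < min_genes) {
        rows[[length(rows) + 1]] <- data.frame(
          set_id = set_ids[si], category = s$category, lot = lots[li],
          method = method, n_measured = measured, raw_score = NA_real_,
          z_score = NA_real_, z_signed = NA_real_, p_perm = NA_real_,
          activated = NA, stringsAsFactors = FALSE)
        next
      }
      ms <- score_set(fc, s$members, method, n_perm,
                      seed = derive_seed(lot_seed, si),
                      z_activation = z_activation, min_genes = min_genes,
                      set_id = set_ids[si])
      zmat[si, li] <- ms$z_score
      rows[[length(rows) + 1]] <- data.frame(
        set_id = ms$set_id, category = s$category, lot = lots[li],
        method = method, n_measured = ms$n_measured,
        raw_score = ms$raw_score, z_score = ms$z_score,
        z_signed = ms$z_signed, p_perm = ms$p_perm,
        activated = ms$activated, stringsAsFactors = FALSE)
    }
  }
  zmat[, "merged"] <- rowMeans(zmat[, lots, drop = FALSE])
  list(scores = do.call(rbind, rows), z_matrix = zmat)
}

#' Toxicity feature-set scores (mean |FC| per lot, with cross-lot summary)
#'
#' For each feature set (e.g. the published liver-toxicity sets PTGS (all),
#' PTGS (core), TMG) and each lot, the score is the mean absolute log2 fold
#' change over the set's measured members — the [aafc_score()] on that lot's
#' full FC map. A summary per set gives the cross-lot mean and sample SD.
#'
#' @inheritParams score_collection
#' @param feature_sets A `GeneSetCollection` of feature sets.
#' @return List with `per_lot` (data frame set_id x lot score) and `summary`
#'   (data frame set_id, mean, sd).
#' @export
feature_set_scores <- function(fc_tables, feature_sets, min_genes = 3) {
  stopifnot(inherits(feature_sets, "GeneSetCollection"))
  lots <- names(fc_tables)
  ids <- names(feature_sets$sets)
  per_lot <- expand.grid(set_id = ids, lot = lots, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  per_lot$score <- NA_real_
  per_lot$n_measured <- NA_integer_
  for (i in seq_len(nrow(per_lot))) {
    s <- feature_sets$sets[[per_lot$set_id[i]]]
    res <- aafc_score(fc_map(fc_tables[[per_lot$lot[i]]]), s$members,
                      min_genes)
    per_lot$score[i] <- res$score
    per_lot$n_measured[i] <- res$n_measured
  }
  summary <- do.call(rbind, lapply(ids, function(id) {
    v <- per_lot$score[per_lot$set_id == id]
    st <- cross_lot_stats(v)
    data.frame(set_id = id, mean = st[["mean"]], sd = st[["sd"]],
               stringsAsFactors = FALSE)
  }))
  list(per_lot = per_lot, summary = summary)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail P(X >= overlap) of each set's overlap with
#' the differentially expressed genes, relative to the measured universe,
#' with BH adjustment across sets. Generic enrichment plumbing; set
#' annotations are user-supplied.
#'
#' @param de_genes Character vector of DE gene symbols (must be contained in
#'   `universe`).
#' @param universe Character vector of all measured gene symbols.
#' @param sets A `GeneSetCollection`.
#' @return Data frame: `set_id`, `n_set` (measured members), `n_overlap`,
#'   `p_value`, `q_value`.
#' @export
ora_enrichment <- function(de_genes, universe, sets) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  outside <- setdiff(de_genes, universe)
  if (length(outside))
    stop("de_genes not contained in universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe); K <- length(de_genes)
  res <- do.call(rbind, lapply(names(sets$sets), function(id) {
    m <- intersect(unique(sets$sets[[id]]$members), universe)
    ov <- length(intersect(m, de_genes))
    # P(X >= ov) with X ~ Hypergeom(N, |set|, K)
    p <- stats::phyper(ov - 1, length(m), N - length(m), K,
                       lower.tail = FALSE)
    data.frame(set_id = id, n_set = length(m), n_overlap = ov,
               p_value = min(p, 1), stringsAsFactors = FALSE)
  }))
  res$q_value <- bh_adjust(res$p_value)
  res
}

# deterministic 32-bit sub-seed derivation (keeps seeds < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 10007) %% 2147483647)
}
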