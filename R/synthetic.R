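# Synthetic multi-lot expression studies with known ground truth. The
# generator emulates the pooled-hepatocyte study design: 5 lots x 3
# treatment conditions (control / low / high dose) x 5 replicates on ~15,000
# genes, with a shared core of true DE genes whose effects are jittered per
# lot, disjoint lot-specific DE genes, and signal injected into designated
# gene sets. Simulation is on the log2 scale with Gaussian replicate noise.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the emulated study design: 5 lots, 5 replicates per
#' condition, 15,000 genes. Effects are signed log2 fold changes: shared
#' core effects have magnitude ~ N(`effect_mean`, `effect_sd`) floored at
#' `effect_min` with random sign, are multiplied per lot by a
#' N(1, `lot_effect_sd`) jitter, and are complemented by per-lot-specific
#' effects from the same magnitude distribution. Low-dose effects are the
#' high-dose effects scaled by `low_dose_factor`.
#'
#' @param n_lots Number of hepatocyte lots (default 5; labelled A, B, ...).
#' @param n_replicates Replicates per lot x condition (default 5).
#' @param n_genes Number of measured genes (default 15000).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression
#'   distribution (defaults 6.0, 2.0).
#' @param residual_sd Replicate noise SD on the log2 scale (default 0.25).
#' @param n_core_de Number of shared core DE genes (default 800).
#' @param effect_mean,effect_sd,effect_min Magnitude distribution of true
#'   |log2 FC| (defaults 1.0, 0.5, floor 0.2).
#' @param n_lot_specific_de DE genes private to each lot (default 1500).
#' @param lot_effect_sd SD of the multiplicative per-lot jitter on shared
#'   effects (default 0.3).
#' @param low_dose_factor Scaling of effects in the low-dose condition
#'   (default 0.15).
#' @param injected_sets Named numeric vector: set id -> mean |effect| of the
#'   signal injected into that set's members.
#' @param n_null_sets Number of uninjected random gene sets emitted alongside
#'   (default 8).
#' @param set_size Members per generated gene set (default 30).
#' @param seed Integer master seed; every phase derives its own sub-seed.
#' @return Object of class `SyntheticConfig` (a named list).
#' @export
synthetic_config <- function(n_lots = 5, n_replicates = 5, n_genes = 15000,
                             baseline_mean = 6.0, baseline_sd = 2.0,
                             residual_sd = 0.25,
                             n_core_de = 800, effect_mean = 1.0,
                             effect_sd = 0.5, effect_min = 0.2,
                             n_lot_specific_de = 1500, lot_effect_sd = 0.3,
                             low_dose_factor = 0.15,
                             injected_sets = c(bile_duct_proliferation = 1.0,
                                               hepatocellular_necrosis = 0.8,
                                               periportal_fibrosis = 0.5),
                             n_null_sets = 8, set_size = 30, seed = 1L) {
  cfg <- list(n_lots = n_lots, n_replicates = n_replicates,
              n_genes = n_genes, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, residual_sd = residual_sd,
              n_core_de = n_core_de, effect_mean = effect_mean,
              effect_sd = effect_sd, effect_min = effect_min,
              n_lot_specific_de = n_lot_specific_de,
              lot_effect_sd = lot_effect_sd,
              low_dose_factor = low_dose_factor,
              injected_sets = injected_sets, n_null_sets = n_null_sets,
              set_size = set_size, seed = as.integer(seed))
  with(cfg, {
    if (n_lots < 1 || n_replicates < 2 || n_genes < 1)
      stop("n_lots, n_replicates (>= 2) and n_genes must be positive")
    if (residual_sd <= 0) stop("residual_sd must be > 0")
    if (n_core_de < 0 || n_lot_specific_de < 0 || n_null_sets < 0)
      stop("counts must be non-negative")
    if (n_core_de + n_lot_specific_de > n_genes)
      stop("n_core_de + n_lot_specific_de exceeds n_genes")
    n_set_genes <- length(injected_sets) * set_size
    if (n_core_de + n_lots * n_lot_specific_de + n_set_genes > n_genes)
      stop("gene budget exceeded: core + lot-specific (all lots) + injected ",
           "set members must fit in n_genes")
  })
  structure(cfg, class = c("SyntheticConfig", "list"))
}

rand_effects <- function(n, mean, sd, minimum) {
  mag <- pmax(stats::rnorm(n, mean, sd), minimum)
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate a synthetic multi-lot expression study with ground truth
#'
#' Control replicates are drawn around per-gene baselines; treated
#' replicates are shifted by the lot's true log2 FC (shared core effect x
#' per-lot jitter, plus lot-specific effects, plus injected-set effects);
#' the low-dose arm uses effects scaled by `low_dose_factor`. Identical
#' seeds give identical output.
#'
#' @param config A [synthetic_config()].
#' @param sets Optional `GeneSetCollection` supplying the gene sets to
#'   inject into; ids named in `config$injected_sets` must exist in it
#'   (unknown ids are an error). If NULL, the generator creates the injected
#'   and null sets itself.
#' @return List with `study` (an `ExpressionStudy`), `truth` (class
#'   `GroundTruth`: `true_fc` genes x lots matrix for the high dose, `core`
#'   logical per gene, `lot_specific` list of per-lot gene vectors, `sets`
#'   data frame of set_id / injected / true_effect), and `sets` (the
#'   `GeneSetCollection`).
#' @export
generate_study <- function(config, sets = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)

  genes <- sprintf("g%05d", seq_len(config$n_genes))
  lots <- make_lot_ids(config$n_lots)

  # phase 1: baselines
  set.seed(derive_seed(config$seed, 1))
  baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                           config$baseline_sd)

  # phase 2: DE architecture (core + lot-specific, disjoint pools)
  set.seed(derive_seed(config$seed, 2))
  pool <- sample.int(config$n_genes)  # random gene order, then carve up
  core_idx <- sort(pool[seq_len(config$n_core_de)])
  used <- config$n_core_de
  lot_specific <- list()
  for (l in lots) {
    lot_specific[[l]] <- sort(pool[used + seq_len(config$n_lot_specific_de)])
    used <- used + config$n_lot_specific_de
  }
  core_effect <- numeric(config$n_genes)
  core_effect[core_idx] <- rand_effects(length(core_idx), config$effect_mean,
                                        config$effect_sd, config$effect_min)

  # phase 3: gene sets and injected effects
  set.seed(derive_seed(config$seed, 3))
  inj_ids <- names(config$injected_sets)
  if (!is.null(sets)) {
    stopifnot(inherits(sets, "GeneSetCollection"))
    unknown <- setdiff(inj_ids, names(sets$sets))
    if (length(unknown))
      stop("injected set(s) not in the collection: ",
           paste(unknown, collapse = ", "))
    collection <- sets
  } else {
    set_defs <- list()
    for (id in inj_ids) {
      members_idx <- pool[used + seq_len(config$set_size)]
      used <- used + config$set_size
      set_defs[[id]] <- list(description = "synthetic injected set",
                             members = genes[sort(members_idx)])
    }
    for (k in seq_len(config$n_null_sets)) {
      id <- sprintf("null_set_%02d", k)
      set_defs[[id]] <- list(description = "synthetic null set",
                             members = genes[sort(sample.int(config$n_genes,
                                                             config$set_size))])
    }
    collection <- gene_set_collection(set_defs, "injury_module")
  }
  injected_effect <- numeric(config$n_genes)
  for (id in inj_ids) {
    members <- collection$sets[[id]]$members
    idx <- match(members, genes)
    idx <- idx[!is.na(idx)]
    injected_effect[idx] <- injected_effect[idx] +
      rand_effects(length(idx), config$injected_sets[[id]],
                   0.2 * config$injected_sets[[id]], 0.05)
  }

  # phase 4: per-lot true fold changes
  set.seed(derive_seed(config$seed, 4))
  true_fc <- matrix(0, config$n_genes, config$n_lots,
                    dimnames = list(genes, lots))
  for (l in lots) {
    jitter <- stats::rnorm(config$n_genes, 1, config$lot_effect_sd)
    fc <- (core_effect + injected_effect) * jitter
    ls_idx <- lot_specific[[l]]
    fc[ls_idx] <- fc[ls_idx] + rand_effects(length(ls_idx),
                                            config$effect_mean,
                                            config$effect_sd,
                                            config$effect_min)
    true_fc[, l] <- fc
  }
  # genes with no assigned effect stay exactly zero in every lot
  null_gene <- core_effect == 0 & injected_effect == 0
  for (l in lots) {
    mask <- null_gene
    mask[lot_specific[[l]]] <- FALSE
    true_fc[mask, l] <- 0
  }

  # phase 5: replicate noise and sample assembly
  set.seed(derive_seed(config$seed, 5))
  dose_scale <- c(control = 0, low = config$low_dose_factor, high = 1)
  n_samp <- config$n_lots * 3 * config$n_replicates
  values <- matrix(NA_real_, config$n_genes, n_samp)
  ids <- character(n_samp)
  ann <- vector("list", n_samp)
  k <- 0
  for (l in lots) for (cond in CONDITION_LEVELS) for (r in seq_len(config$n_replicates)) {
    k <- k + 1
    ids[k] <- paste(l, cond, r, sep = "_")
    shift <- dose_scale[[cond]] * true_fc[, l]
    values[, k] <- baseline + shift +
      stats::rnorm(config$n_genes, 0, config$residual_sd)
    ann[[k]] <- data.frame(sample_id = ids[k], lot = l, condition = cond,
                           replicate = r, stringsAsFactors = FALSE)
  }
  dimnames(values) <- list(genes, ids)
  study <- expression_study(values, do.call(rbind, ann))

  set_truth <- data.frame(
    set_id = names(collection$sets),
    injected = names(collection$sets) %in% inj_ids,
    true_effect = ifelse(names(collection$sets) %in% inj_ids,
                         config$injected_sets[names(collection$sets)], 0),
    stringsAsFactors = FALSE)
  rownames(set_truth) <- NULL
  truth <- structure(
    list(true_fc = true_fc,
         core = stats::setNames(seq_along(genes) %in% core_idx, genes),
         lot_specific = lapply(lot_specific, function(i) genes[i]),
         sets = set_truth),
    class = "GroundTruth")
  list(study = study, truth = truth, sets = collection)
}

make_lot_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("L%03d", seq_len(n))
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits `expression.tsv`, `samples.tsv`, `sets.gmt` (injected + null sets),
#' `truth.tsv` (per-gene core flag and per-lot true FC), and `config.yaml`
#' (an echo of the generator inputs) — all readable by the package's own
#' readers.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the [generate_study()] result.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  gen <- generate_study(config)
  write_expression_study(gen$study, file.path(out_dir, "expression.tsv"),
                         file.path(out_dir, "samples.tsv"))
  write_gene_sets(gen$sets, file.path(out_dir, "sets.gmt"))
  truth_df <- data.frame(gene = rownames(gen$truth$true_fc),
                         core = unname(gen$truth$core),
                         gen$truth$true_fc,
                         check.names = FALSE, stringsAsFactors = FALSE)
  names(truth_df)[-(1:2)] <- paste0("true_fc_", colnames(gen$truth$true_fc))
  write_table(truth_df, file.path(out_dir, "truth.tsv"), digits = 6)
  cfg <- unclass(config)
  cfg$injected_sets <- as.list(cfg$injected_sets)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  invisible(gen)
}
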