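# Fixtures built in code: tiny hand-assembled studies and independent
# re-implementations used as oracles against the package's vectorised paths.

# study with one lot and explicit replicate values per gene:
# `control`/`treated` are genes x replicates matrices (or vectors for 1 gene)
arm_study <- function(control, treated, lot = "A", genes = NULL) {
  if (is.vector(control)) control <- matrix(control, nrow = 1)
  if (is.vector(treated)) treated <- matrix(treated, nrow = 1)
  stopifnot(nrow(control) == nrow(treated))
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(control)))
  nc <- ncol(control); nt <- ncol(treated)
  values <- cbind(control, treated)
  rownames(values) <- genes
  colnames(values) <- c(paste0(lot, "_control_", seq_len(nc)),
                        paste0(lot, "_high_", seq_len(nt)))
  ann <- data.frame(
    sample_id = colnames(values), lot = lot,
    condition = rep(c("control", "high"), c(nc, nt)),
    replicate = c(seq_len(nc), seq_len(nt)), stringsAsFactors = FALSE)
  expression_study(values, ann)
}

# random multi-gene single-lot study under the null (same distribution in
# both arms)
null_arm_study <- function(n_genes, n_rep = 5, seed = 1, lot = "A") {
  set.seed(seed)
  arm_study(matrix(rnorm(n_genes * n_rep), n_genes),
            matrix(rnorm(n_genes * n_rep), n_genes), lot = lot)
}

arm_study_cols <- function(study, condition, lot = "A") {
  study$annotations$sample_id[study$annotations$lot == lot &
                                study$annotations$condition == condition]
}

# independent BH step-up: sort ascending, q_(i) = min_{j>=i} p_(j)*n/j
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n))
    q_sorted[i] <- min(1, min(p[ord][i:n] * n / (i:n)))
  q <- numeric(n)
  q[ord] <- q_sorted
  names(q) <- names(p)
  q
}

# exhaustive permutation-null probability: P(mean score of a random subset
# of size k >= observed), enumerating all subsets of the universe
exact_perm_p <- function(values, k, observed, method = "AAFC") {
  v <- if (method == "AAFC") abs(values) else values
  combos <- utils::combn(length(v), k)
  scores <- apply(combos, 2, function(idx) mean(v[idx]))
  mean(scores >= observed)
}

# hypergeometric upper tail by explicit pmf summation
hyper_tail_brute <- function(overlap, n_set, n_universe, n_de) {
  ks <- overlap:min(n_set, n_de)
  sum(choose(n_set, ks) * choose(n_universe - n_set, n_de - ks)) /
    choose(n_universe, n_de)
}

# small synthetic config used across tests (kept light for runtime)
small_config <- function(seed = 1, ...) {
  defaults <- list(n_lots = 5, n_replicates = 5, n_genes = 2000,
                   n_core_de = 100, n_lot_specific_de = 150,
                   injected_sets = c(bile_duct_proliferation = 1.0,
                                     hepatocellular_necrosis = 0.8),
                   n_null_sets = 5, set_size = 30, seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# zero-effect (global null) version of the small config
null_config <- function(seed = 1, ...) {
  small_config(seed = seed, n_core_de = 0, n_lot_specific_de = 0,
               injected_sets = stats::setNames(numeric(0), character(0)),
               ...)
}
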