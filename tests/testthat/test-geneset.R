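test_that("AAFC and AFC aggregate member fold changes as specified", {
  fc <- c(g1 = 1.0, g2 = -1.0)
  expect_equal(aafc_score(fc, c("g1", "g2"), min_genes = 2)$score, 1.0)
  expect_equal(afc_score(fc, c("g1", "g2"), min_genes = 2)$score, 0.0)

  # unmeasured members are ignored but counted out
  res <- aafc_score(c(g1 = -0.5), c("g1", "gX"), min_genes = 1)
  expect_equal(res$score, 0.5)
  expect_equal(res$n_measured, 1)
  expect_error(aafc_score(c(g1 = 1), c("g1", "gX"), min_genes = 2),
               "min_genes")

  # all-positive members: signed and absolute scores coincide
  fc_pos <- c(a = 0.3, b = 1.2, c = 0.7)
  expect_equal(afc_score(fc_pos, names(fc_pos))$score,
               aafc_score(fc_pos, names(fc_pos))$score)
})

test_that("set scores match brute-force recomputation and are order/dup invariant", {
  set.seed(23)
  fc <- setNames(rnorm(200), sprintf("G%03d", 1:200))
  members <- sample(names(fc), 20)
  expect_equal(aafc_score(fc, members)$score, mean(abs(fc[members])),
               tolerance = 1e-12)
  expect_equal(afc_score(fc, members)$score, mean(fc[members]),
               tolerance = 1e-12)
  shuffled <- c(sample(members), members[1])  # reordered, one duplicate
  expect_equal(aafc_score(fc, shuffled)$score, aafc_score(fc, members)$score)
  expect_equal(aafc_score(fc, shuffled)$n_measured, 20)
})

test_that("AAFC dominates |AFC| on random instances", {
  set.seed(31)
  for (i in 1:50) {
    fc <- setNames(rnorm(100, sd = runif(1, 0.1, 3)), paste0("g", 1:100))
    members <- sample(names(fc), sample(3:40, 1))
    expect_gte(aafc_score(fc, members)$score,
               abs(afc_score(fc, members)$score))
  }
})

test_that("permutation null matches exhaustive enumeration on a 4-gene universe", {
  fc <- c(a = 0.1, b = -0.2, c = 0.3, d = -0.4)
  # unordered pairs of |FC| have means {.15,.2,.25,.25,.3,.35}; P(>= .35)=1/6
  exact <- exact_perm_p(fc, 2, 0.35, "AAFC")
  expect_equal(exact, 1 / 6)

  null <- permutation_null(fc, 2, "AAFC", n_perm = 10000, seed = 9)
  expect_length(null$null_scores, 10000)
  mc <- mean(null$null_scores >= 0.35)
  tol <- 3 * sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc - exact), tol)
})

test_that("permutation null is deterministic under a seed and flags degeneracy", {
  set.seed(2)
  fc <- setNames(rnorm(50), paste0("g", 1:50))
  a <- permutation_null(fc, 5, "AAFC", n_perm = 500, seed = 77)
  b <- permutation_null(fc, 5, "AAFC", n_perm = 500, seed = 77)
  expect_identical(a$null_scores, b$null_scores)

  const <- setNames(rep(c(1, -1), 10), paste0("g", 1:20))
  n <- permutation_null(const, 4, "AAFC", n_perm = 200, seed = 1)
  expect_true(n$degenerate)
  expect_equal(n$null_sd, 0)

  expect_error(permutation_null(fc, 51, n_perm = 10), "exceeds")
})

test_that("score_set combines raw score, z, add-one p, and activation", {
  fc <- c(a = 0.1, b = -0.2, c = 0.3, d = -0.4)
  ms <- score_set(fc, c("c", "d"), "AAFC", n_perm = 10000, seed = 5,
                  min_genes = 2)
  expect_equal(ms$raw_score, 0.35)
  expect_equal(ms$p_perm, 1 / 6, tolerance = 3 * sqrt((1/6) * (5/6) / 1e4) / (1/6))
  expect_gt(ms$p_perm, 0)   # add-one rule forbids p = 0
  expect_lte(ms$p_perm, 1)

  # set = whole universe: every draw reproduces the set itself, so the
  # null collapses onto the raw score (degenerate), z = 0 and p ~ 1
  expect_warning(
    whole <- score_set(fc, names(fc), "AAFC", n_perm = 2000, seed = 5,
                       min_genes = 4),
    "degenerate")
  expect_equal(whole$z_score, 0, tolerance = 1e-9)
  expect_gt(whole$p_perm, 0.99)

  const <- setNames(rep(2, 10), paste0("g", 1:10))
  expect_warning(msd <- score_set(const, c("g1", "g2", "g3"), "AAFC",
                                  n_perm = 200, seed = 1),
                 "degenerate")
  expect_equal(msd$z_score, 0)
})

test_that("AFC scoring reports a signed display z", {
  set.seed(41)
  fc <- setNames(c(rnorm(90), rnorm(10, mean = -2)), paste0("g", 1:100))
  down <- paste0("g", 91:100)
  ms <- score_set(fc, down, "AFC", n_perm = 2000, seed = 3)
  expect_lt(ms$raw_score, 0)
  expect_lt(ms$z_score, 0)     # plain z is negative for a down set
  expect_lt(ms$z_signed, 0)    # signed display z carries the direction
  expect_gt(abs(ms$z_signed), 2)
})

test_that("score_collection scores every set x lot and averages z into merged", {
  set.seed(13)
  fc_tables <- list(
    A = setNames(rnorm(300), sprintf("G%03d", 1:300)),
    B = setNames(rnorm(300), sprintf("G%03d", 1:300)))
  sets <- gene_set_collection(
    list(s1 = list(description = "", members = sprintf("G%03d", 1:15)),
         s2 = list(description = "", members = sprintf("G%03d", 16:40)),
         tiny = list(description = "", members = c("G001", "ZZZ"))),
    "pathway")
  res <- score_collection(fc_tables, sets, "AFC", n_perm = 300, seed = 4)
  expect_equal(nrow(res$scores), 6)
  expect_equal(dim(res$z_matrix), c(3, 3))
  expect_equal(res$z_matrix[, "merged"],
               rowMeans(res$z_matrix[, c("A", "B")]))
  # under-measured set is NA, not dropped
  expect_true(all(is.na(res$z_matrix["tiny", ])))
  expect_true(all(res$scores$n_measured[res$scores$set_id == "tiny"] == 1))

  one <- score_collection(fc_tables["A"], sets, "AFC", n_perm = 300, seed = 4)
  expect_equal(one$z_matrix[, "merged"], one$z_matrix[, "A"])
})

test_that("feature-set scores reproduce the published cross-lot summaries", {
  # per-lot mean-|FC| scores as printed for the three liver-toxicity sets
  ptgs_all <- c(0.75, 0.80, 0.94, 0.88, 0.85)
  ptgs_core <- c(0.71, 0.78, 0.89, 0.80, 0.81)
  tmg <- c(0.68, 0.70, 0.83, 0.79, 0.74)
  for (case in list(list(ptgs_all, 0.84, 0.07),
                    list(ptgs_core, 0.80, 0.06),
                    list(tmg, 0.75, 0.06))) {
    st <- cross_lot_stats(case[[1]])
    expect_equal(round_half_away(st[["mean"]]), case[[2]])
    expect_equal(round_half_away(st[["sd"]]), case[[3]])
  }
  expect_equal(cross_lot_stats(rep(0.8, 5))[["sd"]], 0)
})

test_that("feature_set_scores applies mean-|FC| per lot with a summary row", {
  fc_tables <- list(A = c(g1 = 1, g2 = -1, g3 = 2),
                    B = c(g1 = 0.5, g2 = 0.5, g3 = 0.5))
  fs <- gene_set_collection(
    list(panel = list(description = "", members = c("g1", "g2", "g3"))),
    "feature_set")
  res <- feature_set_scores(fc_tables, fs)
  expect_equal(res$per_lot$score, c(mean(c(1, 1, 2)), 0.5))
  expect_equal(res$summary$mean, mean(c(4 / 3, 0.5)))
  expect_equal(res$summary$sd, sd(c(4 / 3, 0.5)))
})

test_that("hypergeometric ORA matches combinatorial enumeration", {
  universe <- paste0("g", 1:10)
  sets <- gene_set_collection(
    list(s = list(description = "", members = paste0("g", 1:5))), "pathway")
  res <- ora_enrichment(paste0("g", 1:5), universe, sets)
  expect_equal(res$p_value, 1 / choose(10, 5))   # = 1/252

  # zero overlap never exceeds 1
  res0 <- ora_enrichment(paste0("g", 6:10), universe, sets)
  expect_equal(res0$n_overlap, 0)
  expect_lte(res0$p_value, 1)

  set.seed(19)
  for (i in 1:20) {
    uni <- paste0("g", 1:30)
    de <- sample(uni, sample(3:15, 1))
    mem <- sample(uni, sample(3:15, 1))
    s <- gene_set_collection(list(s = list(description = "", members = mem)),
                             "pathway")
    got <- ora_enrichment(de, uni, s)
    want <- hyper_tail_brute(got$n_overlap, length(mem), 30, length(de))
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }

  expect_error(ora_enrichment(c("g1", "zz"), universe, sets),
               "not contained")
})
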