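test_that("overlap matrix counts pairwise DE intersections", {
  sets <- list(A = paste0("g", 1:7), B = paste0("g", 1:7))
  expect_true(all(overlap_matrix(sets) == 7))

  disjoint <- list(A = c("a", "b"), B = c("c", "d"), C = c("e"))
  m <- overlap_matrix(disjoint)
  expect_equal(diag(m), c(A = 2, B = 2, C = 1))
  expect_true(all(m[upper.tri(m)] == 0))

  set.seed(29)
  rand <- lapply(1:5, function(i) sample(paste0("g", 1:1000), 300))
  names(rand) <- LETTERS[1:5]
  m <- overlap_matrix(rand)
  for (i in 1:5) for (j in 1:5)
    expect_equal(m[i, j], length(intersect(rand[[i]], rand[[j]])))
  expect_identical(m, t(m))
  # off-diagonals bounded by the diagonals; 5-way intersection bounded too
  for (i in 1:5) for (j in 1:5)
    expect_lte(m[i, j], min(m[i, i], m[j, j]))
  expect_lte(length(common_genes(rand)), min(diag(m)))
  expect_equal(sort(common_genes(rand)), sort(Reduce(intersect, rand)))
})

test_that("common_genes handles empty and nested inputs", {
  expect_equal(common_genes(list(A = character(0), B = c("g1"))),
               character(0))
  nested <- list(A = paste0("g", 1:10), B = paste0("g", 1:5),
                 C = paste0("g", 1:3))
  expect_equal(common_genes(nested), paste0("g", 1:3))
})

test_that("merged fold change is the unweighted per-gene lot average", {
  expect_equal(merged_fold_change(list(A = c(g = 1.0), B = c(g = 3.0))),
               c(g = 2.0))
  single <- c(g1 = 0.5, g2 = -1)
  expect_equal(merged_fold_change(list(A = single)), single)

  set.seed(37)
  tabs <- lapply(1:5, function(i) setNames(rnorm(80), paste0("g", 1:80)))
  names(tabs) <- LETTERS[1:5]
  merged <- merged_fold_change(tabs)
  manual <- rowMeans(sapply(tabs, function(x) x[names(merged)]))
  expect_equal(merged, manual, tolerance = 1e-12)
  # permutation-invariant in lot order
  expect_equal(merged_fold_change(rev(tabs))[names(merged)], merged)

  expect_warning(merged_fold_change(list(A = c(g1 = 1, g2 = 2),
                                         B = c(g1 = 3))), "dropped")
  expect_error(merged_fold_change(list(A = c(g1 = 1), B = c(g2 = 1))),
               "no gene")
})

test_that("correlation matrix is symmetric with unit diagonal and matches cor", {
  set.seed(43)
  tabs <- list(A = setNames(rnorm(60), paste0("g", 1:60)),
               B = setNames(rnorm(60), paste0("g", 1:60)))
  tabs$C <- -tabs$A  # perfect anticorrelation with A
  r <- correlation_matrix(tabs)
  expect_identical(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["A", "C"], -1)
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  # textbook Pearson on a pair, computed independently
  g <- names(tabs$A)
  x <- tabs$A[g]; y <- tabs$B[g]
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["A", "B"], manual, tolerance = 1e-12)

  # zero-variance vector yields NA cells, not an error
  tabs$D <- setNames(rep(0.2, 60), g)
  r2 <- correlation_matrix(tabs)
  expect_true(is.na(r2["A", "D"]))

  expect_error(correlation_matrix(tabs, gene_subset = "g001"),
               "fewer than 2")
})

test_that("sd_profile uses the sample SD and strict-below fractions", {
  tabs <- list(A = c(g1 = 1, g2 = -2.98), B = c(g1 = 1, g2 = -5.48),
               C = c(g1 = 1, g2 = -4.07), D = c(g1 = 1, g2 = -3.10),
               E = c(g1 = 1, g2 = -6.86))
  prof <- sd_profile(tabs, thresholds = c(0.5, 1.7))
  expect_equal(unname(prof$sd["g1"]), 0)
  # printed per-lot values of a published CYP row reproduce SD 1.66 at 2 dp
  expect_equal(round_half_away(unname(prof$sd["g2"])), 1.66)
  expect_equal(unname(prof$fraction_below), c(0.5, 1.0))  # strict <

  set.seed(47)
  tabs <- lapply(1:4, function(i) setNames(rnorm(30), paste0("g", 1:30)))
  names(tabs) <- LETTERS[1:4]
  prof <- sd_profile(tabs)
  mat <- sapply(tabs, identity)
  manual <- apply(mat, 1, function(v) sqrt(sum((v - mean(v))^2) / 3))
  expect_equal(unname(prof$sd), unname(manual[names(prof$sd)]),
               tolerance = 1e-12)
})

test_that("cross_lot_stats reproduces printed panel-table rows at 2 dp", {
  rows <- list(
    list(c(1.05, 0.87, 0.87, 0.91, 0.90), 0.92, 0.07),   # CYP3A5
    list(c(2.56, -1.88, -3.97, -1.59, 4.25), -0.13, 3.40),  # OAT2
    list(c(0.20, -0.63, 0.90, 0.14, 5.27), 1.18, 2.35),  # ABCB1
    list(c(0.44, 0.78, 0.93, 1.08, 0.52), 0.75, 0.27))   # SLC16A13
  for (r in rows) {
    st <- cross_lot_stats(r[[1]])
    expect_equal(round_half_away(st[["mean"]]), r[[2]])
    expect_equal(round_half_away(st[["sd"]]), r[[3]])
  }
  expect_equal(cross_lot_stats(c(3, 3, 3))[["sd"]], 0)
  expect_error(cross_lot_stats(1), "at least 2")
})

test_that("top_k_genes ranks by merged FC with alphabetical tie-breaks", {
  merged <- c(a = 2, b = -1, c = 0)
  res <- top_k_genes(merged, k = 1)
  expect_equal(res$up$gene, "a")
  expect_equal(res$down$gene, "b")

  ties <- c(zed = 1, ant = 1, mid = 1)
  res <- top_k_genes(ties, k = 2)
  expect_equal(res$up$gene, c("ant", "mid"))
  expect_equal(res$down$gene, c("ant", "mid"))

  expect_warning(res <- top_k_genes(merged, k = 10), "truncated")
  expect_equal(nrow(res$up), 3)
})

test_that("sign consistency requires a strict shared direction", {
  expect_equal(sign_consistency(c(0.24, 0.37, 0.25, 0.32, 0.30)),
               "consistent_up")       # published MRP2 pattern
  expect_equal(sign_consistency(c(-0.22, -0.36, -0.55, -0.49, -0.16)),
               "consistent_down")     # published FIC1/ATP8B1 pattern
  expect_equal(sign_consistency(c(0.2, -0.1, 0.3)), "mixed")
  expect_equal(sign_consistency(c(0, 0.5)), "mixed")  # exact zero breaks it
})

test_that("panel_table assembles per-lot FC, summaries, and star flags", {
  tabs <- list(
    A = data.frame(gene = c("T1", "T2"), log2_fc = c(0.3, 1.5),
                   q_value = c(0.5, 0.01), significant = c(FALSE, TRUE)),
    B = data.frame(gene = c("T1", "T2"), log2_fc = c(0.2, -0.5),
                   q_value = c(0.6, 0.5), significant = c(FALSE, FALSE)))
  expect_warning(pt <- panel_table(tabs, c("T1", "T2", "T9")),
                 "not measured")
  expect_equal(pt$gene, c("T1", "T2"))
  expect_equal(pt$fc_A, c(0.3, 1.5))
  expect_equal(pt$consistency, c("consistent_up", "mixed"))
  # starred = consistent everywhere yet significant nowhere
  expect_equal(pt$starred, c(TRUE, FALSE))
  expect_warning(panel_table(tabs, "T9"), "not measured")
})

test_that("consistency_report assembles all components coherently", {
  gen <- generate_study(small_config(seed = 8, n_lots = 3,
                                     n_genes = 500, n_core_de = 50,
                                     n_lot_specific_de = 40))
  tabs <- fold_change_tables(gen$study)
  rep <- consistency_report(tabs, top_k = 5,
                            panel_genes = gen$study$genes[1:4])
  expect_s3_class(rep, "ConsistencyReport")
  expect_equal(dim(rep$overlap), c(3, 3))
  expect_true(all(rep$common_genes %in%
                    Reduce(intersect, lapply(tabs, call_significant))))
  expect_equal(dim(rep$correlation_all), c(4, 4))
  expect_equal(nrow(rep$top_genes$up), 5)
  expect_equal(nrow(rep$panel), 4)

  # a single lot degrades gracefully: no cross-lot analytics, no error
  one <- consistency_report(tabs[1])
  expect_null(one$correlation_all)
  expect_null(one$sd_all)
  expect_equal(unname(one$merged_fc), tabs[[1]]$log2_fc)
})
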