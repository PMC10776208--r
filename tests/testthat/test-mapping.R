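test_that("the 90% fold threshold is inclusive at the boundary", {
  p <- 10L; n <- 121L
  fm <- matrix(FALSE, p, n)
  fm[1, 1:109] <- TRUE                 # 109/121 = 0.9008 -> included
  fm[2, 1:108] <- TRUE                 # 108/121 = 0.8926 -> excluded
  fm[3, ] <- TRUE
  map <- validated_edges(fake_cv(fm, permutation_p = 0.01))
  expect_true(map$cv_passed)
  expect_identical(which(map$mask), c(1L, 3L))
  expect_equal(map$fold_fraction[3], 1.0)
})

test_that("models failing the permutation test yield empty maps", {
  fm <- matrix(TRUE, 5, 50)
  map <- validated_edges(fake_cv(fm, permutation_p = 0.11))
  expect_false(map$cv_passed)
  expect_false(any(map$mask))
  # boundary: p exactly at model_alpha is not passed
  map2 <- validated_edges(fake_cv(fm, permutation_p = 0.05))
  expect_false(map2$cv_passed)
  expect_error(validated_edges(structure(list(fold_masks = NULL,
                                              permutation_p = 0.01),
                                         class = "cpm_cv")),
               "fold masks")
})

test_that("node degrees match hand enumeration and conserve edge counts", {
  parc <- toy_parcellation(5L)
  eu <- edge_universe(5L)
  mask <- rep(FALSE, eu$unique_edge_count)
  mask[edge_index(5L, c(1, 1, 1, 2), c(2, 3, 4, 3))] <- TRUE
  nd <- node_degrees(fake_map(mask), parc)
  expect_equal(nd$degree$degree, c(3L, 2L, 2L, 1L, 0L))
  expect_equal(sum(nd$degree$degree), 2 * sum(mask))
  # thresholds: nonzero degrees {3,2,2,1}: mean 2, sd 0.8165
  expect_equal(nd$mean_nonzero, 2)
  expect_equal(nd$threshold_critical, floor(2 + sd(c(3, 2, 2, 1))))
  expect_equal(nd$threshold_highly_critical,
               floor(2 + 2 * sd(c(3, 2, 2, 1))))
  expect_identical(nd$critical$node_id, c(1L, 2L, 3L))
  expect_identical(nd$highly_critical$node_id, 1L)
  # highly critical is always a subset of critical
  expect_true(all(nd$highly_critical$node_id %in% nd$critical$node_id))
})

test_that("equal nonzero degrees make every incident node critical", {
  parc <- toy_parcellation(6L)
  mask <- rep(FALSE, edge_universe(6L)$unique_edge_count)
  mask[edge_index(6L, c(1, 3, 5), c(2, 4, 6))] <- TRUE   # disjoint pairs
  nd <- node_degrees(fake_map(mask), parc)
  expect_equal(nd$sd_nonzero, 0)
  expect_equal(nd$threshold_critical, 1)
  expect_equal(nrow(nd$critical), 6L)
  expect_equal(nrow(nd$highly_critical), 6L)
})

test_that("edge classification matches a brute-force label loop", {
  parc <- synthetic_parcellation()
  eu <- edge_universe(100L)
  set.seed(14)
  for (rep in 1:5) {
    mask <- rep(FALSE, eu$unique_edge_count)
    mask[sample.int(eu$unique_edge_count, 20L)] <- TRUE
    cls <- classify_edges(fake_map(mask), parc)
    intra_loop <- 0L
    for (k in which(mask)) {
      ni <- parc$network[eu$pairs[k, "i"]]
      nj <- parc$network[eu$pairs[k, "j"]]
      if (ni == nj) intra_loop <- intra_loop + 1L
    }
    expect_equal(cls$intra, 2L * intra_loop)
    expect_equal(cls$intra + cls$inter, cls$total)
    expect_equal(cls$total, 2L * sum(mask))
    # conservation against node degrees
    nd <- node_degrees(fake_map(mask), parc)
    expect_equal(sum(nd$degree$degree), cls$total)
  }
})

test_that("edges within one network are never inter-network", {
  parc <- synthetic_parcellation()
  vis <- which(parc$network == "visual")
  mask <- rep(FALSE, edge_universe(100L)$unique_edge_count)
  mask[edge_index(100L, vis[1], vis[2:5])] <- TRUE
  cls <- classify_edges(fake_map(mask), parc)
  expect_equal(cls$inter, 0L)
  expect_equal(cls$intra, cls$total)
})

test_that("raising thresholds never adds edges or nodes", {
  coh <- small_cohort()
  cv <- loocv_predict(coh, "word_list_immediate", n_perm = 30, seed = 5)
  m1 <- validated_edges(cv, fold_threshold = 0.80)
  m2 <- validated_edges(cv, fold_threshold = 0.95)
  expect_true(all(which(m2$mask) %in% which(m1$mask)))
  nd1 <- node_degrees(m1, coh$parcellation, multipliers = c(1, 2))
  nd2 <- node_degrees(m1, coh$parcellation, multipliers = c(2, 3))
  expect_true(all(nd2$critical$node_id %in% nd1$critical$node_id))
})

test_that("degree heatmap sums degrees by hemisphere and network", {
  parc <- toy_parcellation(5L)
  mask <- rep(FALSE, edge_universe(5L)$unique_edge_count)
  mask[edge_index(5L, c(1, 1), c(2, 3))] <- TRUE
  nd <- node_degrees(fake_map(mask, "t1"), parc)
  heat <- degree_table(list(nd))
  # node 1 (L, visual) has degree 2; node 3 (L, control) degree 1
  got <- heat$t1[heat$hemisphere == "L" & heat$network == "visual"]
  expect_equal(got, 2L)
  expect_equal(heat$t1[heat$hemisphere == "L" &
                         heat$network == "control"], 1L)
  expect_equal(sum(heat$t1), sum(nd$degree$degree))
})
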