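test_that("block averaging collapses an O/E matrix to the node graph", {
  set.seed(2)
  v <- rand_sym_counts(8, lambda = 5, zero_frac = 0)
  oe <- as_oe(v)
  g0 <- block_graph(oe, change_point_state(n = 8, positions = integer(0)))
  expect_equal(dim(g0$weights), c(1L, 1L))
  expect_equal(g0$weights[1, 1], mean(v))

  # block-constant input reproduces the block constants exactly
  bc <- matrix(2, 6, 6); bc[1:2, 3:6] <- 0.5; bc[3:6, 1:2] <- 0.5
  gbc <- block_graph(as_oe(bc), change_point_state(n = 6, positions = 2L))
  expect_equal(gbc$weights, matrix(c(2, 0.5, 0.5, 2), 2))
  expect_equal(gbc$node_sizes, c(2L, 4L))
  expect_equal(gbc$degrees, rowSums(gbc$weights))
  expect_equal(gbc$total_weight_m, sum(gbc$weights) / 2)

  # random case against loop-computed block means
  v12 <- rand_sym_counts(12, zero_frac = 0.2)
  pos <- c(3, 6, 9)
  g <- block_graph(as_oe(v12), change_point_state(n = 12, positions = pos))
  grp <- findInterval(0:11, pos) + 1
  for (k in 1:4) for (l in 1:4) {
    expect_equal(g$weights[k, l], mean(v12[grp == k, grp == l]))
  }
})

test_that("spectral normalized cut matches closed forms and the exact optimum", {
  # two disconnected 3-cliques: lambda2 = 1, F = 0, sides are the cliques
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
  diag(W) <- 0
  p <- spectral_ncut(weighted_graph(W))
  expect_equal(p$lambda2, 1, tolerance = 1e-12)
  expect_equal(p$F, 0, tolerance = 1e-12)
  expect_length(unique(p$side[1:3]), 1)
  expect_length(unique(p$side[4:6]), 1)
  expect_false(p$side[1] == p$side[4])
  expect_equal(p$cut_R, 0)
  expect_equal(p$kappa1 + p$kappa2, 2 * weighted_graph(W)$total_weight_m)

  # complete graph K4, unit weights: lambda2 = -1/3, m = 6, F = 1/9
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  p4 <- spectral_ncut(weighted_graph(K4))
  expect_equal(p4$lambda2, -1 / 3, tolerance = 1e-12)
  expect_equal(p4$F, 1 / 9, tolerance = 1e-12)

  # nu2 is unit length with deterministic sign
  expect_equal(sum(p4$nu2^2), 1, tolerance = 1e-12)
  expect_gt(p4$nu2[which(abs(p4$nu2) > 1e-12)[1]], 0)

  expect_error(spectral_ncut(weighted_graph(matrix(c(0, 0, 0, 1), 2))),
               "zero-degree")
})

test_that("sign rounding recovers the exact minimum cut on planted graphs", {
  set.seed(17)
  hits <- 0
  for (rep in 1:50) {
    g <- planted_graph(sample(6:10, 1), ratio = 4)
    sp <- spectral_ncut(g)
    bf <- brute_force_ncut(g)
    if (isTRUE(all.equal(sp$objective, bf$objective, tolerance = 1e-9))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 50, 0.9)
})

test_that("brute-force normalized cut is exact", {
  two <- weighted_graph(matrix(c(0.2, 1, 1, 0.2), 2))
  b2 <- brute_force_ncut(two)
  expect_equal(b2$side, c(1L, 2L))
  expect_equal(b2$cut_R, 1)

  disc <- matrix(0, 4, 4)
  disc[1:2, 1:2] <- 1; disc[3:4, 3:4] <- 1; diag(disc) <- 0.5
  bd <- brute_force_ncut(weighted_graph(disc))
  expect_equal(bd$cut_R, 0)
  expect_equal(bd$objective, 0)

  set.seed(23)
  for (rep in 1:20) {
    W <- matrix(runif(36, 0.05, 1), 6)
    W <- (W + t(W)) / 2
    g <- weighted_graph(W)
    expect_equal(brute_force_ncut(g)$objective, naive_min_ncut(W),
                 tolerance = 1e-12)
  }
  expect_error(brute_force_ncut(weighted_graph(diag(21) * 0 + 1)), "20 nodes")
})

test_that("CpG orientation anchors A to CpG-rich bins", {
  set.seed(31)
  v <- matrix(1, 10, 10)
  v[1:5, 1:5] <- 8; v[6:10, 6:10] <- 8
  st <- change_point_state(n = 10, positions = 5L)
  part <- spectral_ncut(block_graph(as_oe(v), st))

  cpg_pos <- cpg_track(c(rep(1, 5), rep(0, 5)) + rnorm(10, 0, 0.01))
  prof <- assign_ab(part, st, cpg_pos)
  expect_true(all(prof$labels[1:5] == "A"))
  expect_true(all(prof$labels[6:10] == "B"))
  expect_gte(prof$cpg_corr, 0)

  # negating the CpG track flips every label
  cpg_neg <- cpg_track(-cpg_pos$values)
  prof2 <- assign_ab(part, st, cpg_neg)
  expect_equal(prof2$labels, ifelse(prof$labels == "A", "B", "A"))

  # global negation of nu2 yields an identical oriented profile
  part_neg <- part
  part_neg$nu2 <- -part$nu2
  prof3 <- assign_ab(part_neg, st, cpg_pos)
  expect_equal(prof3$labels, prof$labels)
  expect_equal(prof3$ncut_values, prof$ncut_values, tolerance = 1e-12)

  # oriented correlation is always non-negative on random instances
  for (rep in 1:10) {
    g <- planted_graph(6, ratio = 3)
    sp <- spectral_ncut(g)
    st6 <- change_point_state(n = 12, positions = c(2, 4, 6, 8, 10))
    cpg <- cpg_track(rnorm(12))
    pr <- assign_ab(sp, st6, cpg, n = 12)
    expect_gte(pr$cpg_corr, 0)
  }

  # zero-variance CpG leaves the profile unoriented but flagged
  expect_warning(pr0 <- assign_ab(part, st, cpg_track(rep(1, 10))),
                 "undefined")
  expect_true(pr0$weak_flag)
})

test_that("compartmental strength is -log2(F) averaged over repeats", {
  mk <- function(F) structure(list(F = F), class = "PartitionResult")
  expect_equal(compartment_strength(mk(0.25)), 2)
  expect_equal(compartment_strength(list(mk(0.5), mk(0.125))), 2)
  expect_equal(compartment_strength(mk(0)), Inf)
  expect_equal(compartment_strength(list(mk(0), mk(0.5))), Inf)
  expect_error(compartment_strength(mk(-0.1)), "negative F")
  expect_error(compartment_strength(list()), "no results")
})
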