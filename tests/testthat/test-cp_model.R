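test_that("loci_groups splits bins at the occupied gaps", {
  st <- change_point_state(gaps = c(0, 1, 0, 0))
  expect_equal(loci_groups(st), data.frame(start = c(0L, 2L), end = c(2L, 5L)))
  st0 <- change_point_state(n = 6, positions = integer(0))
  expect_equal(loci_groups(st0), data.frame(start = 0L, end = 6L))
  st3 <- change_point_state(gaps = c(1, 1, 1))
  expect_equal(loci_groups(st3),
               data.frame(start = 0:3, end = 1:4))
})

test_that("block statistics match the definitions on simple and random input", {
  const <- contact_matrix(matrix(5, 4, 4))
  bs <- block_stats(const, change_point_state(n = 4, positions = integer(0)))
  expect_equal(bs$N[1, 1], 16)
  expect_equal(bs$S[1, 1], 16)
  expect_equal(bs$mu_hat[1, 1], 5)
  expect_equal(bs$V[1, 1], 0)
  expect_equal(bs$r_hat[1, 1], 1)

  zero <- contact_matrix(matrix(0, 4, 4))
  bz <- block_stats(zero, change_point_state(n = 4, positions = integer(0)))
  expect_equal(bz$S[1, 1], 0)
  expect_equal(bz$r_hat[1, 1], 0)
  expect_equal(bz$V[1, 1], 0)

  set.seed(21)
  for (rep in 1:5) {
    Y <- rand_sym_counts(8)
    pos <- sort(sample(7, 2))
    m <- contact_matrix(Y)
    st <- change_point_state(n = 8, positions = pos)
    got <- block_stats(m, st)
    ref <- naive_block_tallies(Y, pos)
    expect_equal(got$N, ref$N)
    expect_equal(got$S, ref$S)
    expect_equal(got$mu_hat, ref$mu)
    expect_equal(got$V, ref$V, tolerance = 1e-12)
    expect_true(isSymmetric(got$N) && isSymmetric(got$S))
    expect_equal(got$r_hat, ref$S / pmax(ref$N, 1))
  }

  # masked bins are excluded from every tally
  mask <- c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  Y <- rand_sym_counts(8)
  m <- contact_matrix(Y, mask = mask)
  st <- change_point_state(n = 8, positions = c(3, 5))
  got <- block_stats(m, st)
  ref <- naive_block_tallies(Y, c(3, 5), mask)
  expect_equal(got$N, ref$N)
  expect_equal(got$V, ref$V, tolerance = 1e-12)
})

test_that("log-posterior matches an independent transcription of the model", {
  # fully observed constant matrix: r_hat = 1, V = 0 -> log-posterior 0
  const <- contact_matrix(matrix(7, 5, 5))
  expect_warning(
    lp <- log_posterior(const, change_point_state(n = 5, positions = 2L)),
    "Gaussian term")
  expect_equal(lp, 0)

  # two-block matrix: the true CP dominates every other single-CP state
  v <- matrix(1, 6, 6)
  v[1:3, 1:3] <- 10
  v[4:6, 4:6] <- 10
  v <- v + diag(0.5, 6)  # break exact constancy so sigma2 > 0
  m2 <- contact_matrix(v)
  lps <- vapply(1:5, function(p) {
    log_posterior(m2, change_point_state(n = 6, positions = p))
  }, numeric(1))
  expect_equal(which.max(lps), 3L)

  set.seed(33)
  for (rep in 1:20) {
    n <- sample(6:10, 1)
    Y <- rand_sym_counts(n)
    K <- sample(0:3, 1)
    pos <- if (K > 0) sort(sample(n - 1, K)) else integer(0)
    m <- contact_matrix(Y)
    st <- change_point_state(n = n, positions = pos)
    expect_equal(log_posterior(m, st), naive_log_posterior(Y, pos),
                 tolerance = 1e-10)
  }
})

test_that("MH chains are reproducible, hold exactly K change points, and find the planted boundary", {
  set.seed(1)
  m <- contact_matrix(rand_sym_counts(15, lambda = 4))
  c1 <- mh_sample(m, K = 3, n_iter = 300, seed = 99)
  c2 <- mh_sample(m, K = 3, n_iter = 300, seed = 99)
  expect_identical(c1$states, c2$states)
  expect_identical(c1$log_posts, c2$log_posts)

  expect_true(all(apply(c1$states, 1, function(p) {
    length(unique(p)) == 3 && all(p >= 1) && all(p <= 14)
  })))

  c0 <- mh_sample(m, K = 2, n_iter = 1, seed = 5)
  expect_equal(nrow(c0$states), 1L)
  expect_error(mh_sample(m, K = 14, seed = 1), "K must satisfy")

  # planted strong two-block structure: MH MAP equals exhaustive enumeration
  tr <- make_truth(30, 1, mu_within = 10, mu_between = 2, dropout_within = 0,
                   dropout_between = 0, seed = 12)
  mm <- sample_matrix(tr, seed = 12)
  chain <- mh_sample(mm, K = 1, n_iter = 2000, seed = 7)
  expect_equal(map_changepoints(chain)$positions,
               exhaustive_map(mm, 1)$positions)
})

test_that("MAP extraction takes the earliest maximum", {
  fake <- structure(list(states = matrix(c(2L, 5L, 5L), ncol = 1),
                         log_posts = c(-5, -2, -2),
                         accepted = c(NA, TRUE, FALSE),
                         K = 1L, n = 8L, seed = 1L, n_iter = 3L),
                    class = "CPChain")
  expect_equal(map_changepoints(fake)$positions, 5L)

  single <- structure(list(states = matrix(3L, ncol = 1), log_posts = -1,
                           accepted = NA, K = 1L, n = 6L, seed = 1L,
                           n_iter = 1L),
                      class = "CPChain")
  expect_equal(map_changepoints(single)$positions, 3L)

  set.seed(44)
  for (rep in 1:50) {
    lp <- rnorm(20)
    states <- matrix(sample(7, 20, replace = TRUE), ncol = 1)
    ch <- structure(list(states = states, log_posts = lp,
                         accepted = c(NA, rep(TRUE, 19)), K = 1L, n = 8L,
                         seed = 1L, n_iter = 20L),
                    class = "CPChain")
    expect_equal(map_changepoints(ch)$positions, states[which.max(lp), 1])
  }
})

test_that("exhaustive enumeration is a true upper bound for sampled MAPs", {
  expect_equal(exhaustive_map(contact_matrix(rand_sym_counts(4)), 0)$K, 0L)

  set.seed(55)
  for (rep in 1:5) {
    m <- contact_matrix(rand_sym_counts(12))
    ex <- exhaustive_map(m, 2)
    ch <- mh_sample(m, 2, n_iter = 200, seed = rep)
    expect_gte(log_posterior(m, ex),
               log_posterior(m, map_changepoints(ch)) - 1e-12)
  }
})
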