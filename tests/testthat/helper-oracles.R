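# Independent oracles and small fixture builders, all plain R loops and kept
# deliberately separate from the package's code paths.

# random symmetric non-negative integer matrix
rand_sym_counts <- function(n, lambda = 3, zero_frac = 0.3) {
  v <- matrix(0, n, n)
  ut <- which(upper.tri(v, diag = TRUE), arr.ind = TRUE)
  cnt <- stats::rpois(nrow(ut), lambda)
  cnt[stats::runif(nrow(ut)) < zero_frac] <- 0
  v[ut] <- cnt
  v[ut[, c(2, 1)]] <- cnt
  v
}

# literal double-loop transcription of the block-model log-posterior:
# sum_kl [ S log r + (N - S) log(1 - r) ] - (1/(2 sigma2)) sum_kl S * V
naive_log_posterior <- function(Y, positions, mask = rep(TRUE, nrow(Y))) {
  n <- nrow(Y)
  grp <- function(b) sum(positions <= b - 1) + 1  # 1-based group of bin b (1-based)
  nz_all <- c()
  for (i in 1:n) for (j in 1:n) {
    if (mask[i] && mask[j] && Y[i, j] != 0) nz_all <- c(nz_all, Y[i, j])
  }
  sigma2 <- if (length(nz_all)) mean((nz_all - mean(nz_all))^2) else 0
  Kp1 <- length(positions) + 1
  bern <- 0; gauss <- 0
  for (k in 1:Kp1) for (l in 1:Kp1) {
    vals <- c()
    for (i in 1:n) for (j in 1:n) {
      if (mask[i] && mask[j] && grp(i) == k && grp(j) == l) {
        vals <- c(vals, Y[i, j])
      }
    }
    N <- length(vals)
    if (N == 0) next
    nz <- vals[vals != 0]
    S <- length(nz)
    r <- S / N
    if (S > 0) bern <- bern + S * log(r)
    if (N - S > 0) bern <- bern + (N - S) * log(1 - r)
    V <- if (S > 1) mean((nz - mean(nz))^2) else 0
    gauss <- gauss + S * V
  }
  if (sigma2 > 0) bern - gauss / (2 * sigma2) else bern
}

# loop-computed block tallies for block_stats checks
naive_block_tallies <- function(Y, positions, mask = rep(TRUE, nrow(Y))) {
  n <- nrow(Y)
  grp <- function(b) sum(positions <= b - 1) + 1
  Kp1 <- length(positions) + 1
  N <- S <- MU <- V <- matrix(0, Kp1, Kp1)
  for (k in 1:Kp1) for (l in 1:Kp1) {
    vals <- c()
    for (i in 1:n) for (j in 1:n) {
      if (mask[i] && mask[j] && grp(i) == k && grp(j) == l) {
        vals <- c(vals, Y[i, j])
      }
    }
    N[k, l] <- length(vals)
    nz <- vals[vals != 0]
    S[k, l] <- length(nz)
    if (length(nz) > 0) MU[k, l] <- mean(nz)
    if (length(nz) > 1) V[k, l] <- mean((nz - mean(nz))^2)
  }
  list(N = N, S = S, mu = MU, V = V)
}

# independent exhaustive normalized-cut minimizer (subset enumeration coded
# differently from the package's bit-mask version)
naive_min_ncut <- function(W) {
  V <- nrow(W)
  d <- rowSums(W)
  best <- Inf
  for (size in 1:(V - 1)) {
    combos <- utils::combn(V, size)
    for (ci in seq_len(ncol(combos))) {
      s1 <- combos[, ci]
      if (!(1 %in% s1)) next  # canonical: node 1 on side 1
      s2 <- setdiff(1:V, s1)
      R <- sum(W[s1, s2, drop = FALSE])
      obj <- R / (sum(d[s1]) * sum(d[s2]))
      if (obj < best) best <- obj
    }
  }
  best
}

# planted two-community weighted graph (within/between weight ratio `ratio`)
planted_graph <- function(V, ratio = 4, noise = 0.2) {
  side <- rep(1:2, length.out = V)
  W <- matrix(0, V, V)
  for (i in 1:V) for (j in i:V) {
    base <- if (side[i] == side[j]) ratio else 1
    w <- max(base + stats::runif(1, -noise, noise), 0.05)
    W[i, j] <- w; W[j, i] <- w
  }
  weighted_graph(W)
}

# O/E-flagged matrix with the given values (identity expected profile)
as_oe <- function(values, mask = rep(TRUE, nrow(values))) {
  raw <- contact_matrix(values, mask = mask)
  oe_normalize(raw, structure(list(band_means = rep(1, nrow(values)),
                                   source_n_cells = 1L),
                              class = "ExpectedProfile"))
}

# strength of one matrix through the single-repeat pipeline
pipeline_strength <- function(m, K, seed) {
  masked <- mask_bins(m, 1)
  oe <- oe_normalize(masked, expected_profile(masked))
  chain <- mh_sample(masked, K, seed = seed)
  st <- map_changepoints(chain)
  compartment_strength(spectral_ncut(block_graph(oe, st)))
}
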