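#' Plant a ground-truth compartment structure
#'
#' Draws `K_true` change-point positions uniformly at random (without
#' collisions), labels the resulting loci groups alternately A/B (or with
#' user-supplied labels), and fills the per-block mean and observation
#' matrices from two-level parameters: within-compartment blocks (same label
#' on both axes) get `mu_within` and dropout `dropout_within`,
#' between-compartment blocks get `mu_between` / `dropout_between`. The
#' planted structure requires `mu_within >= mu_between`.
#'
#' The defaults encode the simulation regime used throughout the package's
#' tests: a checkerboard with a 5:1 contrast between within- and
#' between-compartment means, 70% dropout, unit Gaussian noise and no
#' distance decay.
#'
#' @param n Number of bins.
#' @param K_true Number of planted change points (`<= n - 2`).
#' @param mu_within,mu_between Within/between-compartment block means.
#' @param dropout_within,dropout_between Dropout rates in `[0, 1]`; the
#'   stored observation probability is one minus the dropout rate.
#' @param noise_sd Gaussian noise standard deviation of the true signal.
#' @param decay_rate Exponential distance-decay constant (0 = none); the
#'   expected signal at bin distance d is scaled by `exp(-decay_rate * d)`.
#' @param seed Integer seed; the truth is a pure function of its arguments.
#' @param node_labels Optional explicit per-group labels in `{"A","B"}`
#'   (length `K_true + 1`) replacing the alternating pattern.
#' @param positions Optional explicit change-point positions (1-based gap
#'   indices) replacing the uniform draw; length must equal `K_true`.
#' @return A `GroundTruth`: `n`, `cp_state`, `node_labels`, `mu`, `r`
#'   (observation probabilities), `noise_sd`, `decay_rate`, `seed`.
#' @export
make_truth <- function(n, K_true, mu_within = 10, mu_between = 2,
                       dropout_within = 0.7, dropout_between = 0.7,
                       noise_sd = 1, decay_rate = 0, seed = 1L,
                       node_labels = NULL, positions = NULL) {
  stopifnot(n >= 2, K_true >= 0, K_true <= n - 2)
  if (mu_within < 0 || mu_between < 0) stop("make_truth: means must be >= 0")
  if (mu_within < mu_between) {
    stop("make_truth: planted structure needs mu_within >= mu_between")
  }
  for (dr in c(dropout_within, dropout_between)) {
    if (dr < 0 || dr > 1) stop("make_truth: dropout rates must be in [0, 1]")
  }
  stopifnot(noise_sd >= 0, decay_rate >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(positions)) {
    positions <- if (K_true > 0) sort(sample.int(n - 1L, K_true)) else integer(0)
  } else {
    positions <- sort(as.integer(positions))
    if (length(positions) != K_true || anyDuplicated(positions) ||
        (K_true > 0 && (min(positions) < 1L || max(positions) > n - 1L))) {
      stop("make_truth: positions must be K_true distinct gaps in 1..n-1")
    }
  }
  st <- change_point_state(n = n, positions = positions)
  if (is.null(node_labels)) {
    node_labels <- rep(c("A", "B"), length.out = K_true + 1L)
  }
  stopifnot(length(node_labels) == K_true + 1L, all(node_labels %in% c("A", "B")))
  same <- outer(node_labels, node_labels, `==`)
  mu <- ifelse(same, mu_within, mu_between)
  r <- ifelse(same, 1 - dropout_within, 1 - dropout_between)
  structure(list(n = n, cp_state = st, node_labels = node_labels, mu = mu,
                 r = r, noise_sd = noise_sd, decay_rate = decay_rate,
                 seed = as.integer(seed)),
            class = "GroundTruth")
}

#' Per-bin ground-truth compartment labels
#'
#' @param truth A `GroundTruth` from [make_truth()].
#' @return Character vector of length `n` in `{"A","B"}`.
#' @export
truth_labels <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  truth$node_labels[group_ids(truth$cp_state) + 1L]
}

#' CpG density track matching a planted truth
#'
#' A convenience generator for end-to-end tests: CpG density 1 in planted A
#' bins, 0 in B bins, plus Gaussian noise, so orientation by CpG recovers the
#' planted A/B polarity.
#'
#' @param truth A `GroundTruth`.
#' @param noise_sd Noise standard deviation (default 0.1).
#' @param seed Integer seed.
#' @param chrom,resolution Track metadata.
#' @return A `CpGTrack` of length `n`.
#' @export
cpg_from_truth <- function(truth, noise_sd = 0.1, seed = 1L,
                           chrom = "chr1", resolution = 100000L) {
  stopifnot(inherits(truth, "GroundTruth"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  base <- as.numeric(truth_labels(truth) == "A")
  cpg_track(base + stats::rnorm(truth$n, 0, noise_sd),
            chrom = chrom, resolution = resolution)
}

#' Sample a single-cell contact matrix from a planted truth
#'
#' For each unordered bin pair (i, j), the true signal
#' `X ~ Normal(mu_block * exp(-decay_rate * |i - j|), noise_sd^2)` is
#' truncated at 0 and rounded to an integer count; an independent Bernoulli
#' observation indicator `R ~ Bern(r_block)` models dropout; the measured
#' count is `Y = R * X`. Sampling once per unordered pair makes the matrix
#' symmetric by construction.
#'
#' @param truth A `GroundTruth`.
#' @param seed Integer seed.
#' @param chrom,resolution Matrix metadata.
#' @return A raw `ContactMatrix`.
#' @export
sample_matrix <- function(truth, seed = 1L, chrom = "chr1",
                          resolution = 100000L) {
  stopifnot(inherits(truth, "GroundTruth"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- truth$n
  g <- group_ids(truth$cp_state) + 1L
  ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  mu <- truth$mu[cbind(g[ut[, 1L]], g[ut[, 2L]])] *
    exp(-truth$decay_rate * abs(ut[, 1L] - ut[, 2L]))
  x <- round(pmax(0, stats::rnorm(nrow(ut), mu, truth$noise_sd)))
  r <- stats::rbinom(nrow(ut), 1L, truth$r[cbind(g[ut[, 1L]], g[ut[, 2L]])])
  y <- r * x
  vals <- matrix(0, n, n)
  vals[ut] <- y
  vals[ut[, c(2L, 1L)]] <- y
  contact_matrix(vals, chrom = chrom, resolution = resolution)
}

#' Downsample a contact matrix
#'
#' Two protocols: `rate` thins each unordered-pair count
#' `Binomial(count, rate)` (emulating sequencing-depth reduction at rates
#' such as 1/400 to 1/3200); `target_contacts` draws exactly that many
#' contacts without replacement from the multiset of all contacts
#' (multivariate hypergeometric; emulating fixed-contact-number single
#' cells, e.g. 250 to 10000 contacts). Exactly one of the two must be given.
#'
#' @param m A raw integer-count `ContactMatrix`.
#' @param rate Thinning probability in `(0, 1]`.
#' @param target_contacts Exact number of contacts to keep (upper triangle
#'   plus diagonal).
#' @param seed Integer seed.
#' @return A raw `ContactMatrix` of the same shape.
#' @export
downsample <- function(m, rate = NULL, target_contacts = NULL, seed = 1L) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (m$normalized != "raw") stop("downsample expects a raw matrix")
  if (is.null(rate) == is.null(target_contacts)) {
    stop("downsample: give exactly one of rate or target_contacts")
  }
  vals <- m$values
  if (any(vals != round(vals))) stop("downsample: counts must be integers")
  n <- nrow(vals)
  ut <- which(upper.tri(vals, diag = TRUE), arr.ind = TRUE)
  cnt <- as.integer(round(vals[ut]))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (!is.null(rate)) {
    stopifnot(rate > 0, rate <= 1)
    keep <- stats::rbinom(length(cnt), cnt, rate)
  } else {
    total <- sum(cnt)
    if (target_contacts > total) {
      stop("downsample: target_contacts (", target_contacts,
           ") exceeds total contacts (", total, ")")
    }
    keep <- integer(length(cnt))
    remaining <- as.integer(target_contacts)
    left <- total
    for (k in seq_along(cnt)) {
      if (remaining == 0L) break
      if (cnt[k] > 0L) {
        keep[k] <- stats::rhyper(1L, cnt[k], left - cnt[k], remaining)
        remaining <- remaining - keep[k]
      }
      left <- left - cnt[k]
    }
  }
  out <- matrix(0, n, n)
  out[ut] <- keep
  out[ut[, c(2L, 1L)]] <- keep
  contact_matrix(out, chrom = m$chrom, resolution = m$resolution,
                 bin_start = m$bin_start, mask = m$mask)
}

#' Degrade compartmental structure by shuffle mixing
#'
#' Builds a shuffled copy of the matrix by permuting the upper-triangle
#' entries uniformly at random within each genomic-distance band (so the
#' distance-decay marginal is preserved and only the compartment pattern is
#' destroyed), then blends: `round((1 - fraction) * m + fraction * shuffled)`.
#' Fraction 0 returns the input unchanged; fraction 1 is a full per-band
#' permutation.
#'
#' @param m A raw `ContactMatrix`.
#' @param fraction Mixing fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A raw `ContactMatrix`.
#' @export
shuffle_mix <- function(m, fraction, seed = 1L) {
  stopifnot(inherits(m, "ContactMatrix"), fraction >= 0, fraction <= 1)
  if (m$normalized != "raw") stop("shuffle_mix expects a raw matrix")
  vals <- m$values
  n <- nrow(vals)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuf <- vals
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    idx <- cbind(i, i + d)
    if (nrow(idx) > 1L) shuf[idx] <- vals[idx][sample.int(nrow(idx))]
  }
  shuf[lower.tri(shuf)] <- t(shuf)[lower.tri(shuf)]
  out <- round((1 - fraction) * vals + fraction * shuf)
  contact_matrix(out, chrom = m$chrom, resolution = m$resolution,
                 bin_start = m$bin_start, mask = m$mask)
}
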