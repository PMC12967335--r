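#' Construct a change-point state
#'
#' A change-point (CP) state is a binary vector over the `n - 1` inter-bin
#' gaps with exactly `K` ones; the CPs partition the bins into `K + 1`
#' contiguous loci groups. Gap `p` (1-based) separates bins `p - 1` and `p`
#' (0-based).
#'
#' @param gaps Binary (0/1 or logical) vector of length `n - 1`, or `NULL` to
#'   build from `positions`.
#' @param n Number of bins (required with `positions`).
#' @param positions Integer vector of occupied gap indices (1-based),
#'   alternative to `gaps`.
#' @return A `ChangePointState` with elements `gaps`, `positions` (sorted) and
#'   `K`.
#' @export
change_point_state <- function(gaps = NULL, n = NULL, positions = NULL) {
  if (is.null(gaps)) {
    stopifnot(!is.null(n), n >= 2)
    positions <- sort(unique(as.integer(positions)))
    if (length(positions) &&
        (min(positions) < 1L || max(positions) > n - 1L)) {
      stop("change-point positions must lie in 1..n-1")
    }
    gaps <- integer(n - 1L)
    gaps[positions] <- 1L
  } else {
    gaps <- as.integer(gaps)
    if (!all(gaps %in% c(0L, 1L))) stop("gaps must be binary")
    n <- length(gaps) + 1L
    positions <- which(gaps == 1L)
  }
  structure(list(gaps = gaps, positions = positions,
                 K = length(positions), n = n),
            class = "ChangePointState")
}

#' @export
print.ChangePointState <- function(x, ...) {
  cat(sprintf("ChangePointState: %d bins, K = %d CPs at gaps {%s}\n",
              x$n, x$K, paste(x$positions, collapse = ", ")))
  invisible(x)
}

#' Loci groups induced by a change-point state
#'
#' @param state A `ChangePointState`.
#' @param n Number of bins; defaults to the state's own.
#' @return A data frame with 0-based half-open ranges (`start`, `end`), one
#'   row per loci group, covering bins `0..n-1`.
#' @export
loci_groups <- function(state, n = state$n) {
  stopifnot(inherits(state, "ChangePointState"), n == state$n)
  bounds <- c(0L, state$positions, n)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

# 0-based group id per bin; masked bins get -1 (the C++ kernels' convention)
group_ids <- function(state, mask = rep(TRUE, state$n)) {
  g <- integer(state$n)
  if (state$K > 0L) {
    g <- findInterval(seq_len(state$n) - 1L, state$positions)
  }
  g[!mask] <- -1L
  g
}

# population variance of the nonzero unmasked entries of the full symmetric
# matrix; fixed per matrix, shared by all states
pooled_sigma2 <- function(m) {
  keep <- m$mask
  vals <- m$values[keep, keep, drop = FALSE]
  nz <- vals[vals != 0]
  if (length(nz) == 0L) return(0)
  mean((nz - mean(nz))^2)
}

#' Per-block statistics of a contact matrix under a change-point state
#'
#' Tallies run over the full symmetric matrix (both triangles, diagonal
#' included) with masked bins excluded. For each block (k, l): `N` is the
#' number of contributing bin pairs, `S` the number with a nonzero count,
#' `mu_hat`/`V` the sample mean/population variance of the nonzero entries
#' (V = 0 when S <= 1), and `r_hat = S/N` the plug-in observation
#' probability. `sigma2_hat` is the pooled population variance of all nonzero
#' unmasked entries of the matrix, computed once and independent of the
#' state.
#'
#' @param m A raw `ContactMatrix` (change-point detection runs on raw counts).
#' @param state A `ChangePointState` for the same bin count.
#' @return A `BlockStats` list with matrices `N`, `S`, `mu_hat`, `V`, `r_hat`
#'   and scalar `sigma2_hat`.
#' @export
block_stats <- function(m, state) {
  stopifnot(inherits(m, "ContactMatrix"), inherits(state, "ChangePointState"))
  n <- n_bins(m)
  if (state$n != n) stop("block_stats: state is for ", state$n,
                         " bins, matrix has ", n)
  Kp1 <- state$K + 1L
  t <- cpp_block_tallies(m$values, group_ids(state, m$mask), Kp1)
  mu_hat <- ifelse(t$S > 0, t$sum / pmax(t$S, 1), 0)
  V <- ifelse(t$S > 1, t$sum2 / pmax(t$S, 1) - mu_hat^2, 0)
  V <- pmax(V, 0)  # guard tiny negative rounding
  r_hat <- ifelse(t$N > 0, t$S / pmax(t$N, 1), 0)
  structure(list(N = t$N, S = t$S, mu_hat = mu_hat, V = V, r_hat = r_hat,
                 sigma2_hat = pooled_sigma2(m)),
            class = "BlockStats")
}

#' Log-posterior of a change-point state
#'
#' Evaluates, up to an additive constant shared by all states with the same
#' number of CPs (the prior over states is uniform), the dropout-aware block
#' model log-posterior
#' \deqn{\sum_{k,l} [ S_{kl}\log\hat r_{kl} + (N_{kl}-S_{kl})\log(1-\hat r_{kl}) ]
#'       - \frac{1}{2\hat\sigma^2}\sum_{k,l} S_{kl} V_{kl},}
#' with the convention \eqn{0 \log 0 = 0} and the pooled
#' \eqn{\hat\sigma^2} of [block_stats()]. If \eqn{\hat\sigma^2 = 0} (all
#' nonzero entries identical) the Gaussian term is defined as 0, with a
#' warning.
#'
#' @inheritParams block_stats
#' @return A single numeric log-density value.
#' @export
log_posterior <- function(m, state) {
  stopifnot(inherits(m, "ContactMatrix"), inherits(state, "ChangePointState"))
  n <- n_bins(m)
  if (state$n != n) stop("log_posterior: state/matrix size mismatch")
  sigma2 <- pooled_sigma2(m)
  if (sigma2 == 0 && any(m$values[m$mask, m$mask] != 0)) {
    warning("log_posterior: pooled variance is 0; Gaussian term set to 0")
  }
  cpp_log_posterior(m$values, group_ids(state, m$mask), state$K + 1L, sigma2)
}

#' Metropolis-Hastings sampling of change-point configurations
#'
#' Samples the posterior over CP states with exactly `K` change points by a
#' symmetric move kernel: one occupied gap and one unoccupied gap are chosen
#' uniformly at random and swapped, so the acceptance probability is
#' `min(1, exp(delta log-posterior))`. Proposals that would leave a loci
#' group containing only masked bins are rejected in place. The chain starts
#' from `K` evenly spaced CPs and is exactly reproducible given
#' `(m, K, n_iter, seed)`.
#'
#' @param m A raw `ContactMatrix`.
#' @param K Number of change points, `1 <= K <= n - 2`.
#' @param n_iter Chain length (the initial state is iteration 1). Default
#'   `20 * (n - 1)`.
#' @param seed Integer seed.
#' @return A `CPChain`: `states` (n_iter x K matrix of sorted gap positions),
#'   `log_posts`, `accepted` (NA for the initial state), `K`, `n`, `seed`,
#'   `n_iter`.
#' @export
mh_sample <- function(m, K, n_iter = NULL, seed = 1L) {
  stopifnot(inherits(m, "ContactMatrix"))
  n <- n_bins(m)
  K <- as.integer(K)
  if (K < 1L || K > n - 2L) {
    stop("mh_sample: K must satisfy 1 <= K <= n - 2 (K = ", K, ", n = ", n, ")")
  }
  if (is.null(n_iter)) n_iter <- 20L * (n - 1L)
  n_iter <- as.integer(n_iter)
  stopifnot(n_iter >= 1L)
  init <- even_positions(n, K)
  sigma2 <- pooled_sigma2(m)
  res <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    cpp_mh_sample(m$values, m$mask, init, n_iter, sigma2)
  })
  structure(list(states = res$states, log_posts = res$log_posts,
                 accepted = res$accepted, K = K, n = n,
                 seed = as.integer(seed), n_iter = n_iter),
            class = "CPChain")
}

# K evenly spaced gap positions in 1..n-1
even_positions <- function(n, K) {
  pos <- unique(round(seq_len(K) * (n - 1) / (K + 1)))
  pos <- pmin(pmax(pos, 1L), n - 1L)
  pos <- unique(pos)
  # with K close to n-2 rounding can collide; fill from free gaps
  if (length(pos) < K) {
    free <- setdiff(seq_len(n - 1L), pos)
    pos <- sort(c(pos, free[seq_len(K - length(pos))]))
  }
  as.integer(sort(pos))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.CPChain <- function(x, ...) {
  acc <- mean(x$accepted[-1L])
  cat(sprintf(
    "CPChain: n = %d, K = %d, %d iterations (seed %d)\n  MAP log-posterior %.4f, acceptance rate %.3f\n",
    x$n, x$K, x$n_iter, x$seed, max(x$log_posts), acc))
  invisible(x)
}

#' Maximum-a-posteriori change points of a chain
#'
#' Returns the visited state with the largest log-posterior; ties are broken
#' by earliest visit.
#'
#' @param chain A `CPChain` from [mh_sample()].
#' @return A `ChangePointState`.
#' @export
map_changepoints <- function(chain) {
  stopifnot(inherits(chain, "CPChain"))
  if (length(chain$log_posts) == 0L) stop("map_changepoints: empty chain")
  best <- which.max(chain$log_posts)  # first maximum
  change_point_state(n = chain$n, positions = chain$states[best, ])
}

#' Exact MAP change points by exhaustive enumeration
#'
#' Evaluates the log-posterior of every one of the `choose(n - 1, K)` CP
#' states and returns the global maximizer (the prior is uniform, so the
#' posterior ranking equals the likelihood ranking). Intended as a
#' small-instance oracle; guarded at one million states.
#'
#' @inheritParams mh_sample
#' @return The maximizing `ChangePointState` (ties: first in
#'   [utils::combn()] order).
#' @export
exhaustive_map <- function(m, K) {
  stopifnot(inherits(m, "ContactMatrix"))
  n <- n_bins(m)
  K <- as.integer(K)
  if (K == 0L) return(change_point_state(n = n, positions = integer(0)))
  if (K > n - 2L) stop("exhaustive_map: K must leave non-empty groups")
  if (choose(n - 1, K) > 1e6) {
    stop("exhaustive_map: more than 1e6 states; use mh_sample()")
  }
  sigma2 <- pooled_sigma2(m)
  combos <- utils::combn(n - 1L, K)
  best_lp <- -Inf
  best <- NULL
  for (ci in seq_len(ncol(combos))) {
    pos <- combos[, ci]
    st <- change_point_state(n = n, positions = pos)
    g <- group_ids(st, m$mask)
    if (any(tabulate(g + 1L, nbins = K + 1L) == 0L)) next  # fully masked group
    lp <- cpp_log_posterior(m$values, g, K + 1L, sigma2)
    if (lp > best_lp) {
      best_lp <- lp
      best <- st
    }
  }
  if (is.null(best)) stop("exhaustive_map: no valid state (masking too severe)")
  best
}
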