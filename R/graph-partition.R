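#' Construct a weighted graph
#'
#' Builds the node-level graph representation used by the normalized-cut
#' solver directly from a symmetric non-negative adjacency matrix (self-loops
#' on the diagonal are allowed and counted once in the total weight).
#' [block_graph()] builds this from a contact matrix and a change-point
#' state.
#'
#' @param weights Symmetric non-negative adjacency matrix.
#' @param node_sizes Bin count per node (default 1 each).
#' @return A `WeightedGraph` with `degrees` (row sums) and `total_weight_m`
#'   (half the grand sum).
#' @export
weighted_graph <- function(weights, node_sizes = rep(1L, nrow(weights))) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weighted_graph: adjacency must be square")
  if (any(weights < 0) || anyNA(weights) || any(!is.finite(weights))) {
    stop("weighted_graph: weights must be finite and non-negative")
  }
  if (!isTRUE(all.equal(weights, t(weights), check.attributes = FALSE))) {
    stop("weighted_graph: adjacency must be symmetric")
  }
  stopifnot(length(node_sizes) == nrow(weights))
  structure(list(weights = weights, node_sizes = as.integer(node_sizes),
                 degrees = rowSums(weights), total_weight_m = sum(weights) / 2),
            class = "WeightedGraph")
}

#' Collapse an O/E matrix to a weighted block graph
#'
#' Each loci group becomes a node; the edge weight between nodes k and l is
#' the mean O/E value over all unmasked bin pairs of the (k, l) block.
#' Diagonal blocks become self-loop weights. Blocks with no unmasked pair get
#' weight 0.
#'
#' @param oe An O/E-normalized `ContactMatrix` (see [oe_normalize()]).
#' @param state A `ChangePointState` for the same bin count.
#' @return A `WeightedGraph`: `weights` ((K+1) x (K+1) adjacency with
#'   self-loops), `node_sizes` (unmasked bins per node), `degrees` (row sums)
#'   and `total_weight_m` (half the grand sum).
#' @export
block_graph <- function(oe, state) {
  stopifnot(inherits(oe, "ContactMatrix"), inherits(state, "ChangePointState"))
  if (oe$normalized != "oe") {
    stop("block_graph: partitioning runs on O/E-normalized data; call oe_normalize() first")
  }
  n <- n_bins(oe)
  if (state$n != n) stop("block_graph: state/matrix size mismatch")
  Kp1 <- state$K + 1L
  g <- group_ids(state, oe$mask)
  sizes <- tabulate(g + 1L, nbins = Kp1)
  if (any(sizes == 0L)) {
    stop("block_graph: a loci group contains only masked bins")
  }
  t <- cpp_block_tallies(oe$values, g, Kp1)
  # block mean over all unmasked pairs (zeros included: they are real O/E 0s)
  W <- ifelse(t$N > 0, t$sum / pmax(t$N, 1), 0)
  W <- (W + t(W)) / 2  # exact symmetry against rounding
  structure(list(weights = W, node_sizes = sizes, degrees = rowSums(W),
                 total_weight_m = sum(W) / 2),
            class = "WeightedGraph")
}

#' Spectral normalized-cut bipartition of a weighted graph
#'
#' Solves the relaxed normalized cut \eqn{\min R/(\kappa_1 \kappa_2)}: the
#' second-largest eigenpair \eqn{(\lambda_2, \nu_2)} of
#' \eqn{D^{-1/2} A D^{-1/2}} is extracted (the trivial top eigenvector
#' \eqn{D^{1/2}\mathbf{1}} is deflated out, which also resolves the
#' degenerate disconnected case), nodes are assigned to the two sides by the
#' sign of \eqn{\nu_2} (threshold 0), and the discrete cut quantities are
#' computed from that bipartition. \eqn{\nu_2} is unit length with its first
#' nonzero entry positive.
#'
#' @param g A `WeightedGraph` with at least 2 nodes and all degrees positive.
#' @return A `PartitionResult`: `nu2`, `lambda2`, `side` (1 where
#'   `nu2 >= 0`, else 2), `cut_R`, `kappa1`, `kappa2`,
#'   `F = (1 - lambda2) / (2m)`, and `objective = cut_R / (kappa1 * kappa2)`
#'   (NA with a warning if the sign rounding puts every node on one side).
#' @export
spectral_ncut <- function(g) {
  stopifnot(inherits(g, "WeightedGraph"))
  A <- g$weights
  V <- nrow(A)
  if (V < 2L) stop("spectral_ncut: need at least 2 nodes")
  d <- g$degrees
  if (any(d <= 0)) stop("spectral_ncut: zero-degree node")
  is <- 1 / sqrt(d)
  B <- A * (is %o% is)
  u <- sqrt(d) / sqrt(sum(d))          # top eigenvector of B, eigenvalue 1
  B2 <- B - 4 * (u %o% u)              # deflate: its top eigenpair is (lambda2, nu2)
  eig <- eigen(B2, symmetric = TRUE)
  lambda2 <- eig$values[1L]
  nu2 <- eig$vectors[, 1L]
  nz <- which(abs(nu2) > 1e-12)
  if (length(nz) && nu2[nz[1L]] < 0) nu2 <- -nu2
  side <- ifelse(nu2 >= 0, 1L, 2L)
  m <- g$total_weight_m
  Fval <- (1 - lambda2) / (2 * m)
  cross <- outer(side, side, `!=`)
  cut_R <- sum(A[cross]) / 2
  kappa1 <- sum(d[side == 1L])
  kappa2 <- sum(d[side == 2L])
  if (kappa1 == 0 || kappa2 == 0) {
    warning("spectral_ncut: sign rounding put all nodes on one side; objective undefined")
    objective <- NA_real_
  } else {
    objective <- cut_R / (kappa1 * kappa2)
  }
  structure(list(nu2 = nu2, lambda2 = lambda2, side = side, cut_R = cut_R,
                 kappa1 = kappa1, kappa2 = kappa2, F = Fval,
                 objective = objective),
            class = "PartitionResult")
}

#' Exact minimum normalized cut by enumeration
#'
#' Exhaustive minimizer of \eqn{R/(\kappa_1 \kappa_2)} over all nontrivial
#' bipartitions; the test oracle for [spectral_ncut()]. Ties are broken by
#' the lexicographically smallest side vector (node 1 is always on side 1).
#'
#' @param g A `WeightedGraph` with at most 20 nodes.
#' @return A `PartitionResult` with the spectral fields (`nu2`, `lambda2`,
#'   `F`) set to `NA`.
#' @export
brute_force_ncut <- function(g) {
  stopifnot(inherits(g, "WeightedGraph"))
  A <- g$weights
  V <- nrow(A)
  if (V > 20L) stop("brute_force_ncut: more than 20 nodes")
  if (V < 2L) stop("brute_force_ncut: need at least 2 nodes")
  d <- g$degrees
  best_obj <- Inf
  best_side <- NULL
  # node 1 fixed on side 1; enumerate assignments of nodes 2..V
  for (code in 1:(2^(V - 1L) - 1L)) {
    side <- c(1L, 1L + as.integer(intToBits(code))[seq_len(V - 1L)])
    cross <- outer(side, side, `!=`)
    R <- sum(A[cross]) / 2
    k1 <- sum(d[side == 1L]); k2 <- sum(d[side == 2L])
    obj <- R / (k1 * k2)
    if (obj < best_obj - 1e-15 ||
        (abs(obj - best_obj) <= 1e-15 && !is.null(best_side) &&
         lex_less(side, best_side))) {
      best_obj <- obj
      best_side <- side
    }
  }
  k1 <- sum(d[best_side == 1L]); k2 <- sum(d[best_side == 2L])
  cross <- outer(best_side, best_side, `!=`)
  structure(list(nu2 = NULL, lambda2 = NA_real_, side = best_side,
                 cut_R = sum(A[cross]) / 2, kappa1 = k1, kappa2 = k2,
                 F = NA_real_, objective = best_obj),
            class = "PartitionResult")
}

lex_less <- function(a, b) {
  diff <- which(a != b)
  length(diff) > 0L && a[diff[1L]] < b[diff[1L]]
}

#' Orient a bipartition into A/B compartments by CpG density
#'
#' Expands the node-level \eqn{\nu_2} to a per-bin vector through the loci
#' groups, computes its Pearson correlation with CpG density over unmasked
#' bins, negates the vector if the correlation is negative (A compartments
#' are CpG-rich), and labels bins A where the oriented value is >= 0, B
#' otherwise. A small absolute correlation flags weak compartmentalization;
#' an undefined correlation (zero variance) leaves the profile unoriented
#' with the flag set.
#'
#' @param partition A `PartitionResult` from [spectral_ncut()].
#' @param state The `ChangePointState` the partition was built from.
#' @param cpg A `CpGTrack` of length `n`.
#' @param n Number of bins.
#' @param weak_threshold Absolute-correlation threshold below which the
#'   profile is flagged weak (default 0.2).
#' @param mask Optional logical usable-bin vector (masked bins get NA labels
#'   and values and are excluded from the correlation).
#' @return A `CompartmentProfile`: `labels` ("A"/"B"/NA), `ncut_values`
#'   (oriented per-bin values), `cpg_corr` (oriented correlation),
#'   `strength` (NA here; filled by [annotate_cell()]), `weak_flag`,
#'   `K_used`, `seed_list`, `chrom`, `resolution`, `bin_start`.
#' @export
assign_ab <- function(partition, state, cpg, n = state$n,
                      weak_threshold = 0.2, mask = rep(TRUE, n)) {
  stopifnot(inherits(partition, "PartitionResult"),
            inherits(state, "ChangePointState"),
            inherits(cpg, "CpGTrack"))
  if (length(cpg$values) != n) {
    stop("assign_ab: CpG track length ", length(cpg$values),
         " does not match n = ", n)
  }
  if (is.null(partition$nu2)) stop("assign_ab: partition carries no nu2 vector")
  g <- group_ids(state, mask)
  vals <- rep(NA_real_, n)
  ok <- g >= 0L
  vals[ok] <- partition$nu2[g[ok] + 1L]
  weak <- FALSE
  cc <- NA_real_
  if (sum(ok) >= 2L && stats::sd(vals[ok]) > 0 && stats::sd(cpg$values[ok]) > 0) {
    cc <- stats::cor(vals[ok], cpg$values[ok])
    if (cc < 0) {
      vals <- -vals
      cc <- -cc
    }
    weak <- cc < weak_threshold
  } else {
    warning("assign_ab: correlation undefined (zero variance); profile left unoriented")
    weak <- TRUE
  }
  labels <- rep(NA_character_, n)
  labels[ok] <- ifelse(vals[ok] >= 0, "A", "B")
  structure(list(labels = labels, ncut_values = vals, cpg_corr = cc,
                 strength = NA_real_, weak_flag = weak, K_used = state$K,
                 seed_list = integer(0), chrom = cpg$chrom,
                 resolution = cpg$resolution, bin_start = 0),
            class = "CompartmentProfile")
}

#' @export
print.CompartmentProfile <- function(x, ...) {
  nA <- sum(x$labels == "A", na.rm = TRUE)
  nB <- sum(x$labels == "B", na.rm = TRUE)
  cat(sprintf(
    "CompartmentProfile: %s @ %s bp, %d bins (A: %d, B: %d, masked: %d)\n",
    x$chrom, format(x$resolution, big.mark = ",", scientific = FALSE), length(x$labels), nA, nB,
    sum(is.na(x$labels))))
  cat(sprintf("  K = %d, CpG correlation %.3f%s, strength %.3f\n",
              x$K_used, x$cpg_corr, if (isTRUE(x$weak_flag)) " (weak)" else "",
              x$strength))
  invisible(x)
}

#' Compartmental strength from normalized-cut solutions
#'
#' For each repeat, \eqn{-\log_2(F)} with \eqn{F = (1 - \lambda_2)/(2m)};
#' the arithmetic mean over repeats is returned. Larger values indicate a
#' sharper two-compartment separation; \eqn{F = 0} (perfectly disconnected
#' sides) gives `Inf`, which propagates through the mean.
#'
#' @param results List of `PartitionResult` objects (one per repeat), or a
#'   single `PartitionResult`.
#' @return Mean strength (numeric scalar, possibly `Inf`).
#' @export
compartment_strength <- function(results) {
  if (inherits(results, "PartitionResult")) results <- list(results)
  if (length(results) == 0L) stop("compartment_strength: no results")
  Fs <- vapply(results, function(r) {
    stopifnot(inherits(r, "PartitionResult"))
    r$F
  }, numeric(1))
  if (any(is.na(Fs))) stop("compartment_strength: result carries no F value")
  if (any(Fs < 0)) stop("compartment_strength: negative F violates the eigenvalue bound")
  mean(-log2(Fs))
}
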