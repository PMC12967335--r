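#' Run configuration for compartment annotation
#'
#' Collects the tunable parameters of the annotation pipeline. Defaults
#' follow the method's standard settings: 10 Metropolis-Hastings repeats per
#' cell, change-point candidates 10 to 200 in steps of 10 for the K-selection
#' rule with stability thresholds 0.8 (correlation) and 0.9 (intersection),
#' K determined on the first 5 cells, bins with fewer than 1 raw contact
#' masked, and a 0.2 weak-orientation threshold.
#'
#' @param K Number of change points, or `"auto"` to resolve per dataset via
#'   [select_K()].
#' @param n_iter MH chain length; `NULL` means `20 * (n - 1)`.
#' @param n_repeats Independent MH repeats per cell (default 10).
#' @param seed Master integer seed; all per-cell and per-repeat seeds derive
#'   from it deterministically.
#' @param weak_threshold Absolute CpG-correlation threshold flagging weak
#'   compartmentalization.
#' @param min_marginal Row-sum threshold for [mask_bins()].
#' @param K_candidates Increasing candidate K grid for [select_K()].
#' @param corr_threshold,inter_threshold Stability thresholds in `(0, 1]`
#'   for consecutive-K correlation and intersection.
#' @param cells_for_K Number of leading cells examined by [select_K()].
#' @return A `RunConfig` list.
#' @export
run_config <- function(K = "auto", n_iter = NULL, n_repeats = 10L, seed = 1L,
                       weak_threshold = 0.2, min_marginal = 1,
                       K_candidates = seq(10L, 200L, by = 10L),
                       corr_threshold = 0.8, inter_threshold = 0.9,
                       cells_for_K = 5L) {
  if (!identical(K, "auto")) {
    K <- as.integer(K)
    stopifnot(K >= 1L)
  }
  stopifnot(corr_threshold > 0, corr_threshold <= 1,
            inter_threshold > 0, inter_threshold <= 1,
            n_repeats >= 1L, cells_for_K >= 1L)
  if (is.unsorted(K_candidates, strictly = TRUE)) {
    stop("run_config: K_candidates must be strictly increasing")
  }
  structure(list(K = K, n_iter = n_iter, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), weak_threshold = weak_threshold,
                 min_marginal = min_marginal,
                 K_candidates = as.integer(K_candidates),
                 corr_threshold = corr_threshold,
                 inter_threshold = inter_threshold,
                 cells_for_K = as.integer(cells_for_K)),
            class = "RunConfig")
}

# deterministic stream of derived seeds, kept below 2^31 - 1
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + index * 104729) %%
               2147483647)
}

#' Annotate A/B compartments for one cell
#'
#' The per-cell pipeline: mask uninformative bins, run `n_repeats`
#' independent MH chains for the change points on the raw matrix, collapse
#' the O/E-normalized matrix to the block graph of each repeat's MAP state,
#' solve the normalized cut, and orient by CpG. The reported labels and
#' values come from the repeat with the highest MAP log-posterior; the
#' compartmental strength is averaged over all repeats. Fully reproducible
#' from the inputs and `cfg$seed`.
#'
#' @param raw A raw `ContactMatrix`.
#' @param cpg A `CpGTrack` aligned with the matrix.
#' @param cfg A `RunConfig` with a numeric `K` (use [annotate_dataset()] for
#'   `K = "auto"`).
#' @param expected An `ExpectedProfile`, normally estimated from a
#'   pseudo-bulk pool; if `NULL` it is computed from the cell itself with a
#'   warning (single-cell expected profiles are noisy).
#' @return A `CompartmentProfile` with `strength` and `seed_list` filled in.
#' @export
annotate_cell <- function(raw, cpg, cfg = run_config(K = 10L),
                          expected = NULL) {
  stopifnot(inherits(raw, "ContactMatrix"), inherits(cpg, "CpGTrack"),
            inherits(cfg, "RunConfig"))
  if (identical(cfg$K, "auto")) {
    stop("annotate_cell: K = 'auto' needs a dataset; use annotate_dataset() or select_K()")
  }
  n <- n_bins(raw)
  K <- cfg$K
  if (n < K + 2L) stop("annotate_cell: n = ", n, " too small for K = ", K)
  if (length(cpg$values) != n) stop("annotate_cell: CpG track length mismatch")
  masked <- mask_bins(raw, cfg$min_marginal)
  if (sum(masked$mask) < K + 2L) {
    stop("annotate_cell: only ", sum(masked$mask),
         " usable bins for K = ", K)
  }
  if (is.null(expected)) {
    warning("annotate_cell: no expected profile supplied; estimating from the cell itself")
    expected <- expected_profile(masked)
  }
  oe <- oe_normalize(masked, expected)
  n_iter <- if (is.null(cfg$n_iter)) 20L * (n - 1L) else as.integer(cfg$n_iter)
  seeds <- vapply(seq_len(cfg$n_repeats), function(r) derive_seed(cfg$seed, r),
                  integer(1))
  repeats <- lapply(seeds, function(s) {
    chain <- mh_sample(masked, K, n_iter = n_iter, seed = s)
    st <- map_changepoints(chain)
    part <- spectral_ncut(block_graph(oe, st))
    list(state = st, partition = part, map_lp = max(chain$log_posts))
  })
  best <- which.max(vapply(repeats, `[[`, numeric(1), "map_lp"))
  prof <- assign_ab(repeats[[best]]$partition, repeats[[best]]$state, cpg,
                    n = n, weak_threshold = cfg$weak_threshold,
                    mask = masked$mask)
  prof$strength <- compartment_strength(lapply(repeats, `[[`, "partition"))
  prof$seed_list <- seeds
  prof$map_log_posterior <- repeats[[best]]$map_lp
  prof$bin_start <- raw$bin_start
  prof
}

#' Annotate A/B compartments for a dataset of cells
#'
#' Builds the pseudo-bulk expected profile once, resolves `K` by the
#' stability rule when `cfg$K == "auto"`, and annotates every cell with the
#' same fixed `K`; per-cell seeds derive deterministically from `cfg$seed`
#' and the cell index.
#'
#' @param cells List of aligned raw `ContactMatrix` objects.
#' @param cpg A `CpGTrack` shared by all cells.
#' @param cfg A `RunConfig`.
#' @param verbose Print a one-line summary per cell.
#' @return A `CompartmentMatrix`: `profiles` (list), `binary` (cells x bins,
#'   1/0/NA), `ncut` (cells x bins, real), `K`, `chrom`, `resolution`.
#' @export
annotate_dataset <- function(cells, cpg, cfg = run_config(), verbose = FALSE) {
  if (length(cells) == 0L) stop("annotate_dataset: empty dataset")
  stopifnot(all(vapply(cells, inherits, logical(1), "ContactMatrix")))
  bulk <- pseudo_bulk(cells)
  expected <- expected_profile(bulk)
  K <- if (identical(cfg$K, "auto")) select_K(cells, cpg, cfg) else cfg$K
  n <- n_bins(cells[[1L]])
  profiles <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cfg_i <- cfg
    cfg_i$K <- K
    cfg_i$seed <- derive_seed(cfg$seed, 100000L + i)
    profiles[[i]] <- annotate_cell(cells[[i]], cpg, cfg_i, expected)
    if (verbose) {
      p <- profiles[[i]]
      message(sprintf(
        "cell %d: K=%d map_lp=%.2f cpg_corr=%.3f strength=%.2f%s",
        i, K, p$map_log_posterior, p$cpg_corr, p$strength,
        if (isTRUE(p$weak_flag)) " WEAK" else ""))
    }
  }
  binary <- t(vapply(profiles, function(p) as_binary_labels(p$labels),
                     numeric(n)))
  ncut <- t(vapply(profiles, `[[`, numeric(n), "ncut_values"))
  structure(list(profiles = profiles, binary = binary, ncut = ncut, K = K,
                 chrom = cpg$chrom, resolution = cpg$resolution),
            class = "CompartmentMatrix")
}

#' @export
print.CompartmentMatrix <- function(x, ...) {
  cat(sprintf("CompartmentMatrix: %d cells x %d bins (%s @ %s bp), K = %d\n",
              nrow(x$binary), ncol(x$binary), x$chrom,
              format(x$resolution, big.mark = ",", scientific = FALSE), x$K))
  invisible(x)
}

#' Data-driven choice of the number of change points
#'
#' For each of the first `cfg$cells_for_K` cells, candidate K values are
#' scanned in increasing order; annotations at consecutive candidates are
#' compared by Pearson correlation of the real-valued profiles and by
#' intersection of the binary labels, and the first K whose successor agrees
#' beyond both thresholds is selected (annotation has stabilized). If no
#' pair qualifies the largest candidate is selected with a warning. The
#' returned dataset-level K is the maximum over the examined cells. Each
#' candidate annotation uses a single MH repeat.
#'
#' @inheritParams annotate_dataset
#' @return The selected K (integer).
#' @export
select_K <- function(cells, cpg, cfg = run_config()) {
  if (length(cells) == 0L) stop("select_K: empty dataset")
  n <- n_bins(cells[[1L]])
  cand <- cfg$K_candidates
  if (any(cand > n - 2L)) {
    warning("select_K: candidates above n - 2 = ", n - 2L, " truncated")
    cand <- cand[cand <= n - 2L]
  }
  if (length(cand) < 2L) stop("select_K: need at least 2 feasible candidates")
  expected <- expected_profile(pseudo_bulk(cells))
  use <- seq_len(min(cfg$cells_for_K, length(cells)))
  chosen <- integer(length(use))
  for (ci in use) {
    base_seed <- derive_seed(cfg$seed, 200000L + ci)
    annotate_at <- function(K) {
      cfg_k <- cfg
      cfg_k$K <- K
      cfg_k$n_repeats <- 1L
      cfg_k$seed <- derive_seed(base_seed, K)
      annotate_cell(cells[[ci]], cpg, cfg_k, expected)
    }
    prev <- annotate_at(cand[1L])
    sel <- NA_integer_
    for (j in 2:length(cand)) {
      cur <- annotate_at(cand[j])
      ok <- !is.na(prev$ncut_values) & !is.na(cur$ncut_values)
      stable <- FALSE
      if (sum(ok) >= 3L && stats::sd(prev$ncut_values[ok]) > 0 &&
          stats::sd(cur$ncut_values[ok]) > 0) {
        cc <- stats::cor(prev$ncut_values[ok], cur$ncut_values[ok])
        iv <- intersection(prev$labels, cur$labels)
        stable <- cc > cfg$corr_threshold && iv > cfg$inter_threshold
      }
      if (stable) {
        sel <- cand[j - 1L]
        break
      }
      prev <- cur
    }
    if (is.na(sel)) {
      warning("select_K: cell ", ci,
              " never stabilized; using the largest candidate")
      sel <- cand[length(cand)]
    }
    chosen[ci] <- sel
  }
  max(chosen)
}
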