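#' Construct a contact matrix
#'
#' A `ContactMatrix` holds one intrachromosomal Hi-C matrix for one cell (or a
#' pseudo-bulk pool of cells) together with its genomic metadata and a per-bin
#' usability mask. The matrix must be square, symmetric and non-negative;
#' rows/columns index fixed-size genomic bins.
#'
#' @param values Square symmetric non-negative numeric matrix (raw counts or
#'   observed/expected ratios).
#' @param chrom Chromosome name.
#' @param resolution Bin size in base pairs.
#' @param bin_start Genomic start (bp) of bin 0.
#' @param mask Logical vector, `TRUE` for usable bins. Defaults to all usable.
#' @param normalized Either `"raw"` (counts) or `"oe"` (observed/expected).
#' @param n_cells Number of cells pooled into this matrix (1 for a single
#'   cell; set by [pseudo_bulk()]).
#'
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(values, chrom = "chr1", resolution = 100000L,
                           bin_start = 0L, mask = NULL,
                           normalized = c("raw", "oe"), n_cells = 1L) {
  normalized <- match.arg(normalized)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    stop("contact matrix must be square, got ", nrow(values), "x", ncol(values))
  }
  n <- nrow(values)
  if (n < 2L) stop("contact matrix needs at least 2 bins")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("contact matrix entries must be finite")
  }
  if (any(values < 0)) stop("contact matrix entries must be non-negative")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("contact matrix must be symmetric")
  }
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(is.logical(mask), length(mask) == n, !anyNA(mask))
  dimnames(values) <- NULL
  structure(
    list(values = values, chrom = chrom,
         resolution = as.numeric(resolution),
         bin_start = as.numeric(bin_start),
         mask = mask, normalized = normalized,
         n_cells = as.integer(n_cells)),
    class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("ContactMatrix: %s, %d bins @ %s bp (%s)\n",
              x$chrom, n, format(x$resolution, big.mark = ",", scientific = FALSE), x$normalized))
  cat(sprintf("  usable bins: %d/%d; total signal: %.4g; cells pooled: %d\n",
              sum(x$mask), n, sum(x$values), x$n_cells))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param m A `ContactMatrix`.
#' @return Integer bin count.
#' @export
n_bins <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  nrow(m$values)
}

#' Pool single-cell matrices into a pseudo-bulk matrix
#'
#' Elementwise sum of the cells' contact matrices. The pseudo-bulk mask is the
#' union of the per-cell masks (a bin usable in any cell stays usable).
#'
#' @param cells List of `ContactMatrix` objects sharing chromosome, resolution
#'   and dimension, all raw.
#' @return A raw `ContactMatrix` with `n_cells` set to the pool size.
#' @export
pseudo_bulk <- function(cells) {
  if (length(cells) == 0L) stop("pseudo_bulk: empty cell list")
  stopifnot(all(vapply(cells, inherits, logical(1), "ContactMatrix")))
  ref <- cells[[1L]]
  n <- n_bins(ref)
  for (cell in cells) {
    if (n_bins(cell) != n || cell$chrom != ref$chrom ||
        cell$resolution != ref$resolution) {
      stop("pseudo_bulk: cells must share chromosome, resolution and dimension")
    }
    if (cell$normalized != "raw") stop("pseudo_bulk expects raw matrices")
  }
  total <- Reduce(`+`, lapply(cells, `[[`, "values"))
  mask <- Reduce(`|`, lapply(cells, `[[`, "mask"))
  contact_matrix(total, chrom = ref$chrom, resolution = ref$resolution,
                 bin_start = ref$bin_start, mask = mask, normalized = "raw",
                 n_cells = sum(vapply(cells, `[[`, integer(1), "n_cells")))
}

#' Expected contact frequency by genomic separation
#'
#' Computes the mean contact count at each genomic separation (matrix band)
#' from a pseudo-bulk matrix, the expected profile used for observed/expected
#' normalization. Only pairs with both bins unmasked contribute; bands with no
#' valid pair get 0.
#'
#' @param bulk A raw `ContactMatrix`, typically from [pseudo_bulk()].
#' @return An `ExpectedProfile`: list with `band_means` (length n, entry d+1 is
#'   the mean at separation d bins) and `source_n_cells`.
#' @export
expected_profile <- function(bulk) {
  stopifnot(inherits(bulk, "ContactMatrix"))
  if (bulk$normalized != "raw") stop("expected_profile expects a raw matrix")
  n <- n_bins(bulk)
  Y <- bulk$values
  keep <- bulk$mask
  band_means <- numeric(n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    ok <- keep[i] & keep[i + d]
    band_means[d + 1L] <- if (any(ok)) mean(Y[cbind(i[ok], i[ok] + d)]) else 0
  }
  structure(list(band_means = band_means,
                 source_n_cells = bulk$n_cells),
            class = "ExpectedProfile")
}

#' Observed/expected normalization of a contact matrix
#'
#' Divides each entry by the expected count at its genomic separation. Bands
#' whose expected value is 0 map to 0 (kept finite; the affected pairs carry no
#' signal). Refuses to renormalize an already-normalized matrix.
#'
#' @param cell A raw `ContactMatrix`.
#' @param expected An `ExpectedProfile` of matching length, usually estimated
#'   from a pseudo-bulk pool via [expected_profile()].
#' @return A `ContactMatrix` with `normalized = "oe"`.
#' @export
oe_normalize <- function(cell, expected) {
  stopifnot(inherits(cell, "ContactMatrix"), inherits(expected, "ExpectedProfile"))
  if (cell$normalized != "raw") {
    stop("oe_normalize: input is already normalized")
  }
  n <- n_bins(cell)
  if (length(expected$band_means) != n) {
    stop("oe_normalize: expected profile length ", length(expected$band_means),
         " does not match matrix dimension ", n)
  }
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  e <- expected$band_means[d + 1L]
  out <- ifelse(e > 0, cell$values / e, 0)
  dim(out) <- c(n, n)
  res <- contact_matrix(out, chrom = cell$chrom, resolution = cell$resolution,
                        bin_start = cell$bin_start, mask = cell$mask,
                        normalized = "raw", n_cells = cell$n_cells)
  res$normalized <- "oe"
  res
}

#' Mask uninformative bins
#'
#' Marks bins whose marginal (row sum) falls below a threshold as unusable.
#' Masked bins are excluded from block statistics, graph weights and
#' correlations downstream. Idempotent; masking only ever removes bins.
#'
#' @param m A raw `ContactMatrix`.
#' @param min_marginal Minimum row sum for a bin to stay usable. Default 1 raw
#'   contact, which removes fully-unobserved bins.
#' @return The matrix with an updated mask.
#' @export
mask_bins <- function(m, min_marginal = 1) {
  stopifnot(inherits(m, "ContactMatrix"), min_marginal >= 0)
  if (m$normalized != "raw") stop("mask_bins expects a raw matrix")
  marg <- rowSums(m$values)
  mask <- m$mask & (marg >= min_marginal)
  if (!any(mask)) stop("mask_bins: all bins masked (min_marginal = ",
                       min_marginal, ")")
  m$mask <- mask
  m
}
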