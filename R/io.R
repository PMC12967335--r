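#' Read a contact matrix from disk
#'
#' Supports two plain-text layouts: `dense` (whitespace-delimited square
#' matrix) and `triplet` (three columns `bin_i bin_j count`, 0-based bin
#' indices). Triplet input is symmetrized: a pair given as both (i,j) and
#' (j,i) is treated as the same entry and the counts are summed once, with a
#' warning, so upper-triangle dumps and full dumps both read correctly.
#' Cooler (HDF5) input is not supported by this build; export the chromosome
#' of interest to one of the text layouts first.
#'
#' @param path Path to the file.
#' @param format_name One of `"dense"`, `"triplet"`.
#' @param chrom Chromosome name to attach.
#' @param resolution Bin size in bp.
#' @param n Bin count, required for triplet input when trailing empty bins
#'   would otherwise be dropped; defaults to `max(index) + 1`.
#' @param bin_start Genomic start of bin 0 (bp).
#' @return A raw `ContactMatrix`.
#' @export
read_matrix <- function(path, format_name = c("dense", "triplet", "cooler"),
                        chrom = "chr1", resolution = 100000L, n = NULL,
                        bin_start = 0L) {
  format_name <- match.arg(format_name)
  if (format_name == "cooler") {
    stop("read_matrix: cooler (HDF5) input is not supported; ",
         "supported formats are 'dense' and 'triplet'")
  }
  if (!file.exists(path)) stop("read_matrix: file not found: ", path)
  if (format_name == "dense") {
    vals <- as.matrix(utils::read.table(path, header = FALSE))
    if (nrow(vals) != ncol(vals)) {
      stop("read_matrix: dense input is not square (",
           nrow(vals), "x", ncol(vals), ")")
    }
    if (any(vals < 0)) stop("read_matrix: negative counts in input")
    return(contact_matrix(vals, chrom = chrom, resolution = resolution,
                          bin_start = bin_start))
  }
  tri <- utils::read.table(path, header = FALSE)
  if (ncol(tri) != 3L) stop("read_matrix: triplet input needs 3 columns")
  i <- as.integer(tri[[1L]]); j <- as.integer(tri[[2L]]); cnt <- tri[[3L]]
  if (any(i < 0L) || any(j < 0L)) stop("read_matrix: negative bin index")
  if (any(cnt < 0)) stop("read_matrix: negative counts in input")
  if (is.null(n)) n <- max(i, j) + 1L
  if (max(i, j) + 1L > n) stop("read_matrix: bin index exceeds n")
  # canonical (lower, upper) key per unordered pair; duplicates summed once
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- lo * n + hi
  if (anyDuplicated(key)) {
    warning("read_matrix: duplicate (i,j)/(j,i) entries summed")
    agg <- rowsum(cnt, key)
    key <- as.numeric(rownames(agg)); cnt <- agg[, 1L]
    lo <- key %/% n; hi <- key %% n
  }
  vals <- matrix(0, n, n)
  vals[cbind(lo + 1L, hi + 1L)] <- cnt
  vals[cbind(hi + 1L, lo + 1L)] <- cnt
  contact_matrix(vals, chrom = chrom, resolution = resolution,
                 bin_start = bin_start)
}

#' Write a contact matrix to disk
#'
#' Inverse of [read_matrix()]: `dense` writes the full square matrix,
#' `triplet` writes the nonzero upper triangle (diagonal included) as
#' 0-based `bin_i bin_j count` rows.
#'
#' @param m A `ContactMatrix`.
#' @param path Output path.
#' @param format_name `"dense"` or `"triplet"`.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path, format_name = c("dense", "triplet")) {
  format_name <- match.arg(format_name)
  stopifnot(inherits(m, "ContactMatrix"))
  if (format_name == "dense") {
    utils::write.table(m$values, path, row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(m$values, diag = TRUE) & m$values != 0,
                 arr.ind = TRUE)
    df <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L,
                     count = m$values[idx])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Construct a CpG density track
#'
#' @param values Numeric vector, one CpG density value per bin.
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @return A `CpGTrack`.
#' @export
cpg_track <- function(values, chrom = "chr1", resolution = 100000L) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("cpg_track: values must be finite")
  }
  structure(list(values = values, chrom = chrom,
                 resolution = as.numeric(resolution)),
            class = "CpGTrack")
}

#' Read a per-bin CpG density track from a bedGraph file
#'
#' Intervals use 0-based half-open coordinates. Each bin's value is the
#' coverage-weighted mean of the interval values overlapping it; bins with no
#' coverage get 0.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param chrom Chromosome to extract; an error lists available chromosomes if
#'   absent.
#' @param resolution Bin size in bp.
#' @param n Number of bins.
#' @param bin_start Genomic start of bin 0 (bp).
#' @return A `CpGTrack` of length `n`.
#' @export
read_cpg_track <- function(path, chrom, resolution, n, bin_start = 0L) {
  if (!file.exists(path)) stop("read_cpg_track: file not found: ", path)
  bg <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  have <- unique(bg$chrom)
  bg <- bg[bg$chrom == chrom, , drop = FALSE]
  if (nrow(bg) == 0L) {
    stop("read_cpg_track: chromosome '", chrom, "' not in file; available: ",
         paste(have, collapse = ", "))
  }
  acc <- numeric(n)   # sum(value * overlap bp)
  cov <- numeric(n)   # sum(overlap bp)
  for (r in seq_len(nrow(bg))) {
    s <- bg$start[r]; e <- bg$end[r]; v <- bg$value[r]
    b0 <- max(0L, floor((s - bin_start) / resolution))
    b1 <- min(n - 1L, floor((e - bin_start - 1) / resolution))
    if (b1 < b0) next
    for (b in b0:b1) {
      ov <- min(e, bin_start + (b + 1) * resolution) -
        max(s, bin_start + b * resolution)
      if (ov > 0) {
        acc[b + 1L] <- acc[b + 1L] + v * ov
        cov[b + 1L] <- cov[b + 1L] + ov
      }
    }
  }
  vals <- ifelse(cov > 0, acc / ifelse(cov > 0, cov, 1), 0)
  cpg_track(vals, chrom = chrom, resolution = resolution)
}

#' Write compartment profiles to disk
#'
#' `bedgraph` writes one file per cell (`<path>_cell<i>.bedgraph`) holding the
#' per-bin real-valued normalized-cut value. `tsv` writes two cells-by-bins
#' tables: `<path>_labels.tsv` with binary labels (A = 1, B = 0, masked = NA)
#' and `<path>_ncut.tsv` with the real values. Coordinates are 0-based
#' half-open.
#'
#' @param profiles List of `CompartmentProfile` objects sharing chromosome and
#'   resolution.
#' @param path Output path prefix.
#' @param format_name `"bedgraph"` or `"tsv"`.
#' @return Invisibly, the vector of files written.
#' @export
write_compartments <- function(profiles, path,
                               format_name = c("bedgraph", "tsv")) {
  format_name <- match.arg(format_name)
  if (length(profiles) == 0L) stop("write_compartments: empty profile list")
  stopifnot(all(vapply(profiles, inherits, logical(1), "CompartmentProfile")))
  ref <- profiles[[1L]]
  for (p in profiles) {
    if (p$chrom != ref$chrom || p$resolution != ref$resolution) {
      stop("write_compartments: profiles must share chromosome and resolution")
    }
  }
  nb <- length(ref$ncut_values)
  starts <- ref$bin_start + (seq_len(nb) - 1L) * ref$resolution
  if (format_name == "bedgraph") {
    files <- character(length(profiles))
    for (ci in seq_along(profiles)) {
      p <- profiles[[ci]]
      f <- sprintf("%s_cell%d.bedgraph", path, ci)
      df <- data.frame(chrom = p$chrom, start = format(starts, scientific = FALSE, trim = TRUE),
                       end = format(starts + p$resolution, scientific = FALSE, trim = TRUE),
                       value = p$ncut_values)
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      files[ci] <- f
    }
    return(invisible(files))
  }
  lab <- t(vapply(profiles, function(p) ifelse(is.na(p$labels), NA_real_,
                                               as.numeric(p$labels == "A")),
                  numeric(nb)))
  ncv <- t(vapply(profiles, `[[`, numeric(nb), "ncut_values"))
  f1 <- paste0(path, "_labels.tsv"); f2 <- paste0(path, "_ncut.tsv")
  utils::write.table(lab, f1, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(ncv, f2, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(c(f1, f2))
}
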