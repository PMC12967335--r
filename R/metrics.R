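# normalize label input: accepts "A"/"B"/NA character or 1/0/NA numeric,
# returns numeric 1 (A) / 0 (B) / NA
as_binary_labels <- function(x) {
  if (is.character(x)) {
    out <- rep(NA_real_, length(x))
    out[x == "A"] <- 1
    out[x == "B"] <- 0
    if (any(!is.na(x) & !(x %in% c("A", "B")))) {
      stop("labels must be 'A', 'B' or NA")
    }
    return(out)
  }
  x <- as.numeric(x)
  if (any(!is.na(x) & !(x %in% c(0, 1)))) stop("labels must be 0, 1 or NA")
  x
}

#' Agreement between two binary compartment annotations
#'
#' The fraction of jointly unmasked bins assigned to the same compartment.
#' No orientation flipping is applied: A/B polarity is anchored by CpG, so
#' disagreement in polarity counts as disagreement.
#'
#' @param pred,truth Label vectors of equal length: `"A"`/`"B"`/`NA`
#'   characters or 1/0/NA numerics.
#' @return Agreement fraction in `[0, 1]` with attribute `n_used`.
#' @export
intersection <- function(pred, truth) {
  pred <- as_binary_labels(pred)
  truth <- as_binary_labels(truth)
  if (length(pred) != length(truth)) stop("intersection: length mismatch")
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) stop("intersection: no jointly unmasked positions")
  structure(mean(pred[ok] == truth[ok]), n_used = sum(ok))
}

#' Per-locus annotation accuracy across cells
#'
#' For each bin, the fraction of jointly unmasked cells whose predicted label
#' matches the truth.
#'
#' @param preds,truth Cells-by-bins binary label matrices (1/0/NA) of the
#'   same shape.
#' @return Numeric vector, one accuracy per bin; NA where no jointly
#'   unmasked cell exists.
#' @export
per_locus_accuracy <- function(preds, truth) {
  preds <- as.matrix(preds); truth <- as.matrix(truth)
  if (!all(dim(preds) == dim(truth))) {
    stop("per_locus_accuracy: shape mismatch")
  }
  vapply(seq_len(ncol(preds)), function(b) {
    p <- as_binary_labels(preds[, b]); t <- as_binary_labels(truth[, b])
    ok <- !is.na(p) & !is.na(t)
    if (!any(ok)) NA_real_ else mean(p[ok] == t[ok])
  }, numeric(1))
}

#' Binary compartment variance per locus
#'
#' For each bin, the population variance `p * (1 - p)` of the binary labels
#' (A = 1, B = 0) across unmasked cells, which lies in `[0, 0.25]` and
#' attains 0.25 at an even A/B split.
#'
#' @param labels Cells-by-bins binary label matrix (1/0/NA or "A"/"B"/NA).
#' @return Numeric vector of per-bin variances; NA where fewer than 2 cells
#'   are unmasked.
#' @export
binary_variance <- function(labels) {
  labels <- as.matrix(labels)
  vapply(seq_len(ncol(labels)), function(b) {
    v <- as_binary_labels(labels[, b])
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    p <- mean(v)
    p * (1 - p)
  }, numeric(1))
}

#' Classify loci as stable or variable by compartment variance
#'
#' At `percentile = 50`, bins below the median variance are stable and bins
#' at or above it are variable. At a stricter `percentile = q < 50`, the
#' bottom q% are stable, the top q% are variable, and the middle is NA.
#' Percentiles use the linear-interpolation quantile over non-NA bins.
#'
#' @param variances Per-bin variances (e.g. from [binary_variance()]).
#' @param percentile Cutoff percentile in `(0, 50]`.
#' @return Character vector in `{"stable", "variable", NA}`.
#' @export
stable_variable <- function(variances, percentile = 50) {
  stopifnot(percentile > 0, percentile <= 50)
  ok <- !is.na(variances)
  if (!any(ok)) stop("stable_variable: all variances are NA")
  out <- rep(NA_character_, length(variances))
  if (percentile == 50) {
    med <- stats::quantile(variances[ok], 0.5, names = FALSE)
    out[ok] <- ifelse(variances[ok] < med, "stable", "variable")
  } else {
    lo <- stats::quantile(variances[ok], percentile / 100, names = FALSE)
    hi <- stats::quantile(variances[ok], 1 - percentile / 100, names = FALSE)
    out[ok & variances < lo] <- "stable"
    out[ok & variances > hi] <- "variable"
  }
  out
}

#' Correlation between two real-valued annotations
#'
#' Pearson or Spearman correlation over jointly non-NA positions, with the
#' count of positions used attached.
#'
#' @param a,b Numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation with attribute `n_used`; NA with a warning when
#'   either vector has zero variance.
#' @export
paired_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("paired_correlation: length mismatch")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("paired_correlation: fewer than 3 jointly non-NA positions")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    warning("paired_correlation: zero variance; correlation undefined")
    return(structure(NA_real_, n_used = sum(ok)))
  }
  structure(stats::cor(a[ok], b[ok], method = method), n_used = sum(ok))
}
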