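# Expression-matrix normalization and intensity filtering.
#
# The tool ingests probe-set-level matrices that have already been
# summarized (e.g. MAS5 output); CEL-file processing is out of scope.

#' Validate an expression matrix
#'
#' An expression matrix is a numeric probe-sets-by-samples matrix on the
#' linear intensity scale, with unique probe IDs as row names and unique
#' sample IDs as column names and no missing entries.
#'
#' @param x matrix or data frame coercible to one.
#' @return the validated numeric matrix.
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs probe IDs as rownames and sample IDs ",
         "as colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicated probe IDs", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicated sample IDs", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("expression matrix contains missing or non-finite entries",
         call. = FALSE)
  }
  x
}

# Trimmed mean with floor(trim * n) values discarded from each tail;
# deterministic and exactly invertible by rescaling.
trimmed_mean <- function(v, trim) {
  n <- length(v)
  k <- floor(trim * n)
  if (k > 0L) {
    v <- sort(v)[(k + 1L):(n - k)]
  }
  mean(v)
}

#' Scale each array to a common trimmed-mean intensity
#'
#' Per sample (column), the mean intensity after discarding the lowest and
#' highest `trim_fraction` of values is computed, and the column is
#' multiplied by `target / trimmed_mean` so every array's 2% trimmed mean
#' equals `target` (150 by default, the convention used when training the
#' marker panel on MAS5-summarized arrays).
#'
#' @param matrix expression matrix (see [as_expression_matrix()]),
#'   non-negative intensities.
#' @param trim_fraction fraction trimmed from each tail, in `[0, 0.5)`.
#' @param target post-scaling trimmed mean.
#' @return the rescaled matrix.  Applying the function twice is a no-op.
#' @export
trimmed_mean_scale <- function(matrix, trim_fraction = 0.02, target = 150) {
  matrix <- as_expression_matrix(matrix)
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("'trim_fraction' must lie in [0, 0.5)", call. = FALSE)
  }
  if (any(matrix < 0)) {
    stop("negative intensities; floor them before scaling", call. = FALSE)
  }
  tm <- apply(matrix, 2L, trimmed_mean, trim = trim_fraction)
  zero <- tm == 0
  if (any(zero)) {
    stop("trimmed mean is zero for sample(s): ",
         paste(colnames(matrix)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(matrix, 2L, target / tm, `*`)
}

#' Filter probe sets by their upper-quantile log2 intensity
#'
#' Keeps probe sets whose per-probe 90th percentile of log2 intensity is
#' strictly greater than `min_log2` (default 6), removing probes expressed
#' near background in nearly all samples.  Quantiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#' Intensities are floored at `floor_intensity` before taking log2 so the
#' transform is defined for zero entries of summarized data.
#'
#' @param matrix expression matrix on the linear scale.
#' @param quantile probe-level quantile inspected (default 0.90).
#' @param min_log2 log2 threshold the quantile must exceed (default 6).
#' @param floor_intensity linear floor applied before log2 (default 1).
#' @return list with `matrix` (the surviving rows, input order preserved)
#'   and `report`, a `"filter_report"` with counts and parameters.
#' @export
intensity_filter <- function(matrix, quantile = 0.90, min_log2 = 6,
                             floor_intensity = 1) {
  matrix <- as_expression_matrix(matrix)
  stopifnot(quantile > 0, quantile < 1)
  lg <- log2(pmax(matrix, floor_intensity))
  q <- apply(lg, 1L, stats::quantile, probs = quantile, names = FALSE,
             type = 7)
  keep <- q > min_log2
  report <- structure(
    list(n_input_probes = nrow(matrix), n_passed = sum(keep),
         threshold_log2 = min_log2, quantile = quantile),
    class = "filter_report")
  list(matrix = matrix[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "intensity filter: %d of %d probe sets kept (%.0fth percentile log2 > %g)\n",
    x$n_passed, x$n_input_probes, 100 * x$quantile, x$threshold_log2))
  invisible(x)
}

#' Wide quantile spread of a probe's intensities
#'
#' The 95th minus the 5th quantile of (optionally log2) intensities, a
#' probe-level diagnostic of dynamic range: bimodal "on/off" probes have a
#' large spread.  This deliberately wider-than-conventional "IQR" (95-5
#' rather than 75-25) is kept under an honest name.
#'
#' @param values numeric intensities for one probe, length >= 2.
#' @param log2 take log2 (with a floor of 1) first (default `TRUE`).
#' @return the spread, a single number.
#' @export
spread_90 <- function(values, log2 = TRUE) {
  if (length(values) < 2L) {
    stop("need at least two values to compute a spread", call. = FALSE)
  }
  if (log2) values <- base::log2(pmax(values, 1))
  qs <- stats::quantile(values, c(0.05, 0.95), names = FALSE, type = 7)
  qs[2L] - qs[1L]
}
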