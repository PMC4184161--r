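# Transcriptome-wide bimodality scan and marker-candidate selection.

#' Minor mode fraction of a probe's intensities
#'
#' Fraction of samples on the smaller side of a bimodality threshold,
#' standing in for the minor allele frequency of a haplotype-specific probe
#' set: `min(f, 1 - f)` where `f` is the fraction of samples strictly above
#' the threshold.
#'
#' @param values per-probe log2 intensities.
#' @param threshold finite split point on the same scale.
#' @return value in `[0, 0.5]`.
#' @export
minor_mode_fraction <- function(values, threshold) {
  if (!is.finite(threshold)) stop("'threshold' must be finite", call. = FALSE)
  f <- mean(values > threshold)
  min(f, 1 - f)
}

#' Suggest an intensity threshold separating two expression modes
#'
#' Automates the visual-inspection cut-off: the sorted values are split at
#' the point minimizing total within-group variance (exhaustive over all
#' n - 1 splits, i.e. exact 1-D two-means), and the threshold is the
#' midpoint of the two group means.  For probes without evidence of
#' bimodality (dip p-value >= `fallback_p`, when a p-value is supplied) the
#' median is returned instead with `fallback = TRUE`, as a two-means split
#' of unimodal data is arbitrary.
#'
#' @param values per-probe log2 intensities, length >= 10.
#' @param dip_p optional empirical dip p-value for this probe.
#' @param fallback_p p-value at or above which the median fallback is used.
#' @return list with `threshold_log2` and `fallback` (logical).
#' @export
suggest_threshold <- function(values, dip_p = NULL, fallback_p = 0.05) {
  n <- length(values)
  if (n < 10L) stop("need >= 10 values to suggest a threshold", call. = FALSE)
  if (!is.null(dip_p) && dip_p >= fallback_p) {
    return(list(threshold_log2 = stats::median(values), fallback = TRUE))
  }
  s <- sort(values)
  # exhaustive scan: within-group sum of squares for split after position k
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1L)
  ss_left <- cs2[k] - cs[k]^2 / k
  nr <- n - k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / nr
  best <- which.min(ss_left + ss_right)
  mean_left <- cs[best] / best
  mean_right <- (cs[n] - cs[best]) / (n - best)
  list(threshold_log2 = (mean_left + mean_right) / 2, fallback = FALSE)
}

#' Scan an expression matrix for bimodal probe sets
#'
#' For every probe set, computes the dip statistic of the log2 intensities,
#' an empirical p-value against a shared Monte-Carlo null for this sample
#' size, and Benjamini-Hochberg adjusted p-values across all tested probes.
#' Candidates are probes with raw empirical p below `alpha` (the selection
#' the marker panel was trained with, with `adjusted_p` reported alongside)
#' and a minor mode fraction of at least `minority_floor`, which keeps
#' single-outlier probes out of the candidate list.
#'
#' Candidates are ranked by ascending empirical p, then descending dip,
#' then probe ID, so reports are deterministic.
#'
#' @param matrix expression matrix, already scaled and filtered, with at
#'   least 5 samples.
#' @param n_sims Monte-Carlo draws for the null (default 1e6; scans used
#'   for testing typically use 1e4).
#' @param alpha selection threshold on the raw empirical p (default 0.001).
#' @param seed seed for the null simulation.
#' @param minority_floor minimum minor mode fraction for candidates.
#' @param floor_intensity linear floor applied before log2.
#' @param include optional character vector of probe IDs to force into the
#'   candidate table regardless of `alpha` (marker panels may deliberately
#'   carry probes that narrowly miss the cut).
#' @return An object of class `"scan_result"`: list with `candidates` and
#'   `all_probes` data frames (columns `probe_id`, `dip`, `empirical_p`,
#'   `adjusted_p`, `minor_mode_fraction`, `suggested_threshold_log2`,
#'   `threshold_fallback`, `spread_90`), plus `n`, `n_sims`, `alpha`,
#'   `seed`.
#' @export
scan_bimodal <- function(matrix, n_sims = 1e6, alpha = 0.001, seed = 1L,
                         minority_floor = 0.05, floor_intensity = 1,
                         include = NULL) {
  matrix <- as_expression_matrix(matrix)
  n <- ncol(matrix)
  if (n < 5L) {
    stop("need at least 5 samples for a meaningful dip null (got ", n, ")",
         call. = FALSE)
  }
  lg <- log2(pmax(matrix, floor_intensity))
  null <- simulate_null_dips(n, n_sims, seed)

  probes <- rownames(lg)
  dips <- numeric(length(probes))
  emp_p <- numeric(length(probes))
  mmf <- numeric(length(probes))
  thr <- numeric(length(probes))
  fb <- logical(length(probes))
  spr <- numeric(length(probes))
  for (i in seq_along(probes)) {
    v <- lg[i, ]
    dips[i] <- dip_stat_sorted(sort(v))
    emp_p[i] <- sum(null$dips > dips[i]) / null$n_sims
    st <- suggest_threshold(v, dip_p = emp_p[i])
    thr[i] <- st$threshold_log2
    fb[i] <- st$fallback
    mmf[i] <- minor_mode_fraction(v, thr[i])
    spr[i] <- spread_90(v, log2 = FALSE)
  }
  adj_p <- bh_adjust(emp_p)

  all_probes <- data.frame(
    probe_id = probes, dip = dips, empirical_p = emp_p, adjusted_p = adj_p,
    minor_mode_fraction = mmf, suggested_threshold_log2 = thr,
    threshold_fallback = fb, spread_90 = spr,
    stringsAsFactors = FALSE, row.names = NULL)

  selected <- (emp_p < alpha & mmf >= minority_floor) |
    all_probes$probe_id %in% include
  candidates <- all_probes[selected, , drop = FALSE]
  ord <- order(candidates$empirical_p, -candidates$dip, candidates$probe_id)
  candidates <- candidates[ord, , drop = FALSE]
  row.names(candidates) <- NULL

  structure(
    list(candidates = candidates, all_probes = all_probes, n = n,
         n_sims = null$n_sims, alpha = alpha, seed = null$seed,
         minority_floor = minority_floor),
    class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "bimodality scan: %d probe sets, n = %d samples, %d null draws (seed %d)\n",
    nrow(x$all_probes), x$n, x$n_sims, x$seed))
  cat(sprintf("%d candidate(s) at empirical p < %g, minor fraction >= %g\n",
              nrow(x$candidates), x$alpha, x$minority_floor))
  if (nrow(x$candidates)) {
    top <- utils::head(x$candidates, 10L)
    top$empirical_p <- format_pvalue(top$empirical_p, x$n_sims)
    print(top, digits = 3)
  }
  invisible(x)
}

#' Write a candidate table as TSV
#'
#' Columns mirror the scan result; empirical p-values are rendered with
#' [format_pvalue()] (zero counts as `"< 1/n_sims"`).
#'
#' @param scan a `"scan_result"`.
#' @param path output path.
#' @param annotation optional data frame of per-probe pass-through columns
#'   (e.g. gene symbols), joined on `probe_id`.
#' @export
write_candidates <- function(scan, path, annotation = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  df <- scan$candidates
  if (!is.null(annotation)) {
    stopifnot("probe_id" %in% names(annotation))
    df <- merge(df, annotation, by = "probe_id", all.x = TRUE, sort = FALSE)
    df <- df[order(df$empirical_p, -df$dip, df$probe_id), , drop = FALSE]
  }
  df$empirical_p <- format_pvalue(df$empirical_p, scan$n_sims)
  df$adjusted_p <- format_pvalue(df$adjusted_p, scan$n_sims)
  write_tsv_report(df, path)
}
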