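# Monte-Carlo null distribution of the dip statistic and empirical p-values.

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.null_cache <- new.env(parent = emptyenv())

#' Simulate the null distribution of the dip statistic
#'
#' Draws `n_sims` samples of size `n` from a normal distribution and reduces
#' each to its dip statistic, giving the Monte-Carlo null against which
#' observed dips are judged.  Because the dip is invariant under affine
#' transforms, the normal's mean and standard deviation are irrelevant; the
#' standard normal is used.
#'
#' One null is needed per dataset size `n`, not per probe set, so results
#' are cached in-memory per `(n, n_sims, seed)` and can be serialized with
#' [write_null_dips()] / [read_null_dips()].
#'
#' @param n sample size (number of arrays/samples); must be >= 2.
#' @param n_sims number of Monte-Carlo draws (>= 1).  The transcriptome-wide
#'   scan defaults to 1e6 draws; smaller values trade p-value resolution for
#'   speed (the attainable minimum p is `1/n_sims`).
#' @param seed integer seed governing the whole simulation; recorded in the
#'   result so runs are reproducible.
#' @param cache use/populate the in-memory cache (default `TRUE`).
#' @return An object of class `"dip_null"`: list with `n`, `n_sims`, `seed`
#'   and `dips` (numeric vector of length `n_sims`).
#' @export
simulate_null_dips <- function(n, n_sims, seed = 1L, cache = TRUE) {
  n <- as.integer(n)
  n_sims <- as.integer(n_sims)
  seed <- as.integer(seed)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2", call. = FALSE)
  if (is.na(n_sims) || n_sims < 1L) {
    stop("'n_sims' must be an integer >= 1", call. = FALSE)
  }
  key <- sprintf("n%d_sims%d_seed%d", n, n_sims, seed)
  if (cache && !is.null(.null_cache[[key]])) return(.null_cache[[key]])
  dips <- with_seed(seed, {
    vapply(seq_len(n_sims),
           function(i) dip_stat_sorted(sort(stats::rnorm(n))),
           numeric(1L))
  })
  out <- structure(list(n = n, n_sims = n_sims, seed = seed, dips = dips),
                   class = "dip_null")
  if (cache) .null_cache[[key]] <- out
  out
}

#' @export
print.dip_null <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo dip null: n = %d, n_sims = %d, seed = %d\n", x$n,
    x$n_sims, x$seed))
  cat(sprintf("  dip quantiles: %s\n",
              paste(sprintf("%.4f", stats::quantile(x$dips, c(.5, .95, .999))),
                    collapse = " / ")))
  invisible(x)
}

#' Clear the in-memory null-distribution cache
#' @return invisibly, the number of entries removed.
#' @export
clear_null_cache <- function() {
  keys <- ls(.null_cache)
  rm(list = keys, envir = .null_cache)
  invisible(length(keys))
}

#' Serialize a dip null distribution to a plain-text table
#'
#' The file is TSV: a single header line `n n_sims seed` with their values,
#' then one simulated dip per line.
#'
#' @param null a `"dip_null"` object.
#' @param path output file path.
#' @export
write_null_dips <- function(null, path) {
  stopifnot(inherits(null, "dip_null"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("n\t%d\nn_sims\t%d\nseed\t%d", null$n, null$n_sims,
                     null$seed), con)
  writeLines(format(null$dips, digits = 17, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' @rdname write_null_dips
#' @param path file written by [write_null_dips()].
#' @param cache insert the restored null into the in-memory cache.
#' @export
read_null_dips <- function(path, cache = TRUE) {
  lines <- readLines(path)
  meta <- strsplit(lines[1:3], "\t", fixed = TRUE)
  vals <- stats::setNames(
    as.integer(vapply(meta, `[`, "", 2L)),
    vapply(meta, `[`, "", 1L))
  dips <- as.numeric(lines[-(1:3)])
  out <- structure(list(n = vals[["n"]], n_sims = vals[["n_sims"]],
                        seed = vals[["seed"]], dips = dips),
                   class = "dip_null")
  if (length(dips) != out$n_sims) {
    stop("corrupt null table: ", length(dips), " dips but n_sims = ",
         out$n_sims, call. = FALSE)
  }
  if (cache) {
    key <- sprintf("n%d_sims%d_seed%d", out$n, out$n_sims, out$seed)
    .null_cache[[key]] <- out
  }
  out
}

#' Empirical p-value of an observed dip statistic
#'
#' The p-value is the proportion of simulated null dips strictly greater
#' than the observed dip.  A count of zero is stored as `p = 0` and rendered
#' as `"< 1/n_sims"` by [format_pvalue()], since the Monte-Carlo resolution
#' cannot distinguish it from any value below `1/n_sims`.
#'
#' @param observed a `"dip_result"` from [compute_dip()], or a bare dip value
#'   (in which case `n` is not checked against the null).
#' @param null a `"dip_null"` from [simulate_null_dips()]; its `n` must match
#'   the observed sample size.
#' @return An object of class `"dip_pvalue"`: list with `observed_dip`, `p`,
#'   `count_greater` and `n_sims`.
#' @export
empirical_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "dip_null"))
  if (inherits(observed, "dip_result")) {
    if (observed$n != null$n) {
      stop(sprintf(
        "sample size mismatch: observed n = %d but null simulated at n = %d",
        observed$n, null$n), call. = FALSE)
    }
    obs <- observed$dip
  } else {
    obs <- as.numeric(observed)
    if (length(obs) != 1L || !is.finite(obs)) {
      stop("'observed' must be a dip_result or a single finite value",
           call. = FALSE)
    }
  }
  cnt <- sum(null$dips > obs)
  structure(list(observed_dip = obs, p = cnt / null$n_sims,
                 count_greater = cnt, n_sims = null$n_sims),
            class = "dip_pvalue")
}

#' @export
print.dip_pvalue <- function(x, ...) {
  cat(sprintf("observed dip %.6g: empirical p %s (%d of %d null dips greater)\n",
              x$observed_dip, format_pvalue(x$p, x$n_sims), x$count_greater,
              x$n_sims))
  invisible(x)
}

#' Render an empirical p-value for reports
#'
#' Zero counts render as `"< 1/n_sims"`; other values in scientific notation
#' with three significant digits.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param n_sims the Monte-Carlo draw count behind `p`.
#' @return character vector.
#' @export
format_pvalue <- function(p, n_sims) {
  ifelse(p == 0,
         sprintf("< %.2e", 1 / n_sims),
         sprintf("%.3g", p))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (delegated to
#' [stats::p.adjust()]), with input validation: all values must lie in
#' `[0, 1]`.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted values in the original order, each >= its input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("'pvalues' must be numeric", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
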