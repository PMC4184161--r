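#' Hartigan's dip statistic for unimodality
#'
#' Computes the dip statistic: the smallest sup-norm distance between the
#' empirical distribution function of `x` and the set of unimodal
#' distribution functions (convex up to a mode, concave after it).  Large
#' values indicate departure from unimodality, e.g. the bimodal "on/off"
#' expression of haplotype-specific probe sets across donors.
#'
#' The statistic is computed by the iterative greatest-convex-minorant /
#' least-concave-majorant algorithm over candidate modal intervals.  It is
#' deterministic, invariant under strictly increasing affine transforms of
#' the data, and bounded by `1/(2n) <= dip <= 1/4` for `n >= 2`.
#'
#' Samples of size one and all-tied samples are consistent with a unimodal
#' (degenerate) distribution; they return the lower bound `1/(2n)` with the
#' `degenerate` flag set rather than erroring, because filtered expression
#' data can contain constant probes.
#'
#' @param x numeric vector of finite values; it is sorted internally and
#'   ties are kept (no jittering).
#' @return An object of class `"dip_result"`: a list with elements
#'   `dip` (the statistic), `modal_interval` (1-based index pair `(lo, hi)`
#'   into the sorted sample delimiting the final modal interval), `n`
#'   (sample size) and `degenerate` (logical).
#' @examples
#' compute_dip(c(0, 1))$dip                      # 0.25, the n = 2 bound
#' compute_dip(c(rnorm(25), rnorm(25, 6)))$dip   # large: bimodal
#' @seealso [simulate_null_dips()], [empirical_pvalue()]
#' @export
compute_dip <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("'x' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("'x' contains non-finite values", call. = FALSE)
  }
  xs <- sort(x)
  n <- length(xs)
  if (n == 1L) {
    return(new_dip_result(1 / (2 * n), c(1L, 1L), n, degenerate = TRUE))
  }
  if (xs[1L] == xs[n]) {
    return(new_dip_result(1 / (2 * n), c(1L, n), n, degenerate = TRUE))
  }
  res <- dip_gcm_lcm(xs)
  new_dip_result(res$dip, res$modal_interval, n, degenerate = FALSE)
}

new_dip_result <- function(dip, modal_interval, n, degenerate) {
  structure(
    list(dip = dip, modal_interval = as.integer(modal_interval), n = n,
         degenerate = degenerate),
    class = "dip_result"
  )
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigan dip statistic: %.6g  (n = %d%s)\n", x$dip, x$n,
              if (x$degenerate) ", degenerate sample" else ""))
  cat(sprintf("Modal interval (sorted-sample indices): [%d, %d]\n",
              x$modal_interval[1L], x$modal_interval[2L]))
  invisible(x)
}

# Core GCM/LCM iteration on a sorted sample with at least two distinct
# values.  Works in "count" units; the returned dip is divided by 2n.
#
# mn[j] holds, for the greatest convex minorant fit, the previous index
# whose combination with j is necessary; mj[k] the analogue for the least
# concave majorant.  Tie handling is exact: comparisons use
# cross-multiplied slopes, so zero denominators never arise.
dip_gcm_lcm <- function(x) {
  n <- length(x)

  mn <- integer(n)
  mn[1L] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }

  mj <- integer(n)
  mj[n] <- n
  for (k in (n - 1L):1L) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  low <- 1L
  high <- n
  dip <- 1  # count units; lower bound 1/(2n) after final scaling

  repeat {
    # Change points of the GCM from high down to low, and of the LCM from
    # low up to high, within the current modal interval candidate.
    gcm <- integer(0L)
    gcm[1L] <- high
    i <- 1L
    while (gcm[i] > low) {
      gcm[i + 1L] <- mn[gcm[i]]
      i <- i + 1L
    }
    l_gcm <- i
    ig <- i
    ix <- ig - 1L

    lcm <- integer(0L)
    lcm[1L] <- low
    i <- 1L
    while (lcm[i] < high) {
      lcm[i + 1L] <- mj[lcm[i]]
      i <- i + 1L
    }
    l_lcm <- i
    ih <- i
    iv <- 2L

    # Largest distance between the GCM and the LCM on [low, high].
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]
        lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          # next change point comes from the LCM
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv - 1L
          }
        } else {
          # next change point comes from the GCM
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv
          }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1
    }

    if (d < dip) break

    # Dip within the convex minorant section ...
    dip_l <- 0
    if (ig < l_gcm) {
      for (j in ig:(l_gcm - 1L)) {
        max_t <- 1
        j_ <- gcm[j]
        jb <- gcm[j + 1L]
        if (j_ - jb > 1L && x[j_] != x[jb]) {
          C <- (j_ - jb) / (x[j_] - x[jb])
          jj <- jb:j_
          max_t <- max(1, (jj - jb + 1) - (x[jj] - x[jb]) * C)
        }
        if (dip_l < max_t) dip_l <- max_t
      }
    }

    # ... and within the concave majorant section.
    dip_u <- 0
    if (ih < l_lcm) {
      for (j in ih:(l_lcm - 1L)) {
        max_t <- 1
        j_ <- lcm[j]
        jb <- lcm[j + 1L]
        if (jb - j_ > 1L && x[jb] != x[j_]) {
          C <- (jb - j_) / (x[jb] - x[j_])
          jj <- j_:jb
          max_t <- max(1, (x[jj] - x[j_]) * C - (jj - j_ - 1))
        }
        if (dip_u < max_t) dip_u <- max_t
      }
    }

    dipnew <- max(dip_l, dip_u)
    if (dip < dipnew) dip <- dipnew

    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]
    high <- lcm[ih]
  }

  list(dip = dip / (2 * n), modal_interval = c(low, high))
}

# Fast internal path: dip value of an already-sorted sample, no validation.
dip_stat_sorted <- function(xs) {
  n <- length(xs)
  if (n == 1L || xs[1L] == xs[n]) return(1 / (2 * n))
  dip_gcm_lcm(xs)$dip
}
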