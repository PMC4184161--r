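# Independent brute-force oracle for the dip statistic, for small n.
#
# The dip of the empirical CDF F_n is the smallest d such that some unimodal
# CDF G (convex up to a mode, concave after it, with an atom permitted only
# at the mode) stays within sup-distance d of F_n.  Because G is monotone and
# F_n is a step function, the sup-distance constraint reduces to bands at the
# distinct data values q_g: G(q_g) in [A_g - d, B_g + d] where A_g = F_n(q_g)
# and B_g = F_n(q_g^-).  Candidate modes are each data value (where the atom
# decouples the left limit v- from the value v+) and each inter-point gap
# (where F_n = C constrains the mode value directly).  For a fixed mode every
# constraint -- bands, convexity/concavity triples among data points, and
# triples involving the mode value v -- is linear in d after eliminating v,
# so the minimal d for that mode is a maximum of closed-form thresholds; the
# oracle minimizes over modes (with 1-d refinement of the gap position).
#
# This derivation shares nothing with the GCM/LCM iteration in R/dip.R.

dip_oracle <- function(x, n_grid = 41L) {
  xs <- sort(x)
  n <- length(xs)
  q <- unique(xs)
  M <- length(q)
  if (M == 1L) return(1 / (2 * n))
  cnt <- tabulate(match(xs, q), M)
  A <- cumsum(cnt) / n       # F_n at q_g
  B <- A - cnt / n           # F_n just left of q_g

  width_d <- max((A - B) / 2)

  # largest d-threshold from convexity triples of data points in index set S
  conv_d <- function(S) {
    k <- length(S)
    if (k < 3L) return(-Inf)
    best <- -Inf
    for (ii in 2L:(k - 1L)) {
      i <- S[ii]
      for (jj in 1L:(ii - 1L)) {
        j <- S[jj]
        for (ll in (ii + 1L):k) {
          l <- S[ll]
          lam <- (q[l] - q[i]) / (q[l] - q[j])
          best <- max(best, (A[i] - lam * B[j] - (1 - lam) * B[l]) / 2)
        }
      }
    }
    best
  }
  conc_d <- function(S) {
    k <- length(S)
    if (k < 3L) return(-Inf)
    best <- -Inf
    for (ii in 2L:(k - 1L)) {
      i <- S[ii]
      for (jj in 1L:(ii - 1L)) {
        j <- S[jj]
        for (ll in (ii + 1L):k) {
          l <- S[ll]
          lam <- (q[l] - q[i]) / (q[l] - q[j])
          best <- max(best, (lam * A[j] + (1 - lam) * A[l] - B[i]) / 2)
        }
      }
    }
    best
  }

  # lower bounds on the mode value v, as rows (p, c) meaning v >= p + c*d
  lower_terms <- function(left, m) {
    p <- 0; cc <- 0                      # v >= 0
    for (l in left) {                    # monotonicity: v >= G(q_l)
      p <- c(p, A[l]); cc <- c(cc, -1)
    }
    if (length(left) >= 2L) {            # convexity triples (q_j, q_l, m)
      for (li in 2L:length(left)) {
        l <- left[li]
        for (ji in 1L:(li - 1L)) {
          j <- left[ji]
          r <- (m - q[l]) / (q[l] - q[j])
          p <- c(p, A[l] + (A[l] - B[j]) * r)
          cc <- c(cc, -(1 + 2 * r))
        }
      }
    }
    cbind(p, cc)
  }
  # upper bounds on v, rows (p, c) meaning v <= p + c*d
  upper_terms <- function(right, m) {
    p <- 1; cc <- 0                      # v <= 1
    if (length(right) >= 1L) {           # monotonicity: v <= G(q_first)
      p <- c(p, B[right[1L]]); cc <- c(cc, 1)
    }
    if (length(right) >= 2L) {           # concavity triples (m, q_r, q_s)
      for (ri in 1L:(length(right) - 1L)) {
        r <- right[ri]
        e <- q[r] - m
        for (si in (ri + 1L):length(right)) {
          s <- right[si]
          f <- q[s] - m
          p <- c(p, (B[r] * f - A[s] * e) / (f - e))
          cc <- c(cc, (f + e) / (f - e))
        }
      }
    }
    cbind(p, cc)
  }

  # smallest d such that every lower-bound term <= every upper-bound term
  cross_d <- function(L, U) {
    best <- -Inf
    for (a in seq_len(nrow(L))) {
      dc <- U[, 2L] - L[a, 2L]
      dp <- L[a, 1L] - U[, 1L]
      thr <- ifelse(dc > 0, dp / dc, ifelse(dp <= 0, -Inf, Inf))
      best <- max(best, thr)
    }
    best
  }

  # mode at data value q_i, atom allowed: left limit v- and value v+ decouple,
  # so the jump A_i - B_i is absorbed and group i's band width does not bind
  d_mode_at <- function(i) {
    left <- if (i > 1L) 1L:(i - 1L) else integer(0L)
    right <- if (i < M) (i + 1L):M else integer(0L)
    w <- if (M > 1L) max((A[-i] - B[-i]) / 2) else -Inf
    d0 <- max(w, conv_d(left), conc_d(right))
    L <- lower_terms(left, q[i])         # bounds on v-
    U <- upper_terms(right, q[i])        # bounds on v+
    # v- must also satisfy |v- - B_i| <= d; v+ must satisfy |v+ - A_i| <= d;
    # and v- <= v+ must be attainable.
    d_j <- max(
      cross_d(L, rbind(U, c(B[i], 1))),            # v- <= min(U, B_i + d)
      cross_d(rbind(c(B[i], -1), c(A[i], -1)), U)  # B_i - d, A_i - d <= U
    )
    max(d0, d_j)
  }

  # mode in the open gap (q_g, q_(g+1)) at position m; continuous there,
  # with F_n = A_g = C constraining v itself.
  d_mode_gap <- function(g, m) {
    left <- 1L:g
    right <- (g + 1L):M
    C <- A[g]
    L <- rbind(lower_terms(left, m), c(C, -1))
    U <- rbind(upper_terms(right, m), c(C, 1))
    max(width_d, conv_d(left), conc_d(right), cross_d(L, U))
  }

  best <- min(vapply(1L:M, d_mode_at, numeric(1L)))
  if (M >= 2L) {
    for (g in 1L:(M - 1L)) {
      lo <- q[g]
      hi <- q[g + 1L]
      ms <- seq(lo, hi, length.out = n_grid + 2L)
      ms <- ms[-c(1L, length(ms))]
      vals <- vapply(ms, function(m) d_mode_gap(g, m), numeric(1L))
      k <- which.min(vals)
      a <- if (k == 1L) lo else ms[k - 1L]
      b <- if (k == length(ms)) hi else ms[k + 1L]
      opt <- stats::optimize(function(m) d_mode_gap(g, m), c(a, b),
                             tol = 1e-12)
      best <- min(best, vals[k], opt$objective)
    }
  }
  max(best, 1 / (2 * n))
}
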