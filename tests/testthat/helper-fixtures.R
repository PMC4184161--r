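# Shared fixtures and small independent oracles.

fixture_matrix <- function() {
  read_expression_matrix(system.file(
    "extdata", "gse6751_hla_panel_matrix.tsv", package = "hlascore"))
}

fixture_annotation <- function() {
  read_annotation(system.file(
    "extdata", "gse6751_hla_panel_annotation.tsv", package = "hlascore"))
}

# Textbook Benjamini-Hochberg step-up, written directly from the
# definition: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Random sample generator used by the dip property tests.
random_dip_sample <- function(max_n = 8L) {
  n <- sample(2:max_n, 1L)
  switch(sample(1:5, 1L),
         stats::runif(n),
         stats::rnorm(n),
         c(stats::rnorm(ceiling(n / 2)), stats::rnorm(floor(n / 2), 4)),
         round(stats::runif(n), 1),          # frequent ties
         sample(1:3, n, replace = TRUE))     # heavy ties
}

# Matrix of "planted" bimodal probes: each probe has exactly
# round(minor_frac * n) samples in the high mode.  Linear scale.
planted_bimodal_matrix <- function(n_probes, n_samples = 47L,
                                   minor_frac = 0.3, mode_low = 4,
                                   mode_high = 10, sd_log2 = 0.5,
                                   n_background = 0L) {
  k <- round(minor_frac * n_samples)
  rows <- t(vapply(seq_len(n_probes), function(i) {
    v <- stats::rnorm(n_samples, mode_low, sd_log2)
    hi <- sample.int(n_samples, k)
    v[hi] <- stats::rnorm(k, mode_high, sd_log2)
    2^v
  }, numeric(n_samples)))
  if (n_background > 0L) {
    mid <- (mode_low + mode_high) / 2
    bg <- matrix(2^stats::rnorm(n_background * n_samples, mid, sd_log2),
                 nrow = n_background)
    rows <- rbind(rows, bg)
  }
  rownames(rows) <- c(sprintf("planted_%03d", seq_len(n_probes)),
                      if (n_background > 0L)
                        sprintf("background_%04d", seq_len(n_background)))
  colnames(rows) <- sprintf("S%02d", seq_len(n_samples))
  rows
}

# Small simulated dataset scored against its own marker panel; returns the
# flag report and the injected swaps.
simulate_and_flag <- function(n_donors = 20L, samples_per_donor = 4L,
                              n_bimodal = 3L, mixup_rate = 0,
                              sd_log2 = 0.5, seed = 1L,
                              gender = FALSE) {
  ds <- generate_dataset(sim_config(
    n_donors = n_donors, samples_per_donor = samples_per_donor,
    n_probes_total = n_bimodal + 5L, n_bimodal = n_bimodal,
    mode_low_log2 = 4, mode_high_log2 = 10, sd_log2 = sd_log2,
    n_gender_probes = if (gender) 5L else 0L,
    mixup_rate = mixup_rate, seed = seed))
  panel <- marker_panel(sprintf("bimodal_%03d", seq_len(n_bimodal)), 128,
                        name = "sim")
  scores <- score_samples(ds$matrix, panel)
  report <- check_donor_consistency(scores, ds$annotation, panel)
  list(ds = ds, panel = panel, scores = scores, report = report)
}
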