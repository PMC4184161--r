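# Synthetic expression datasets with the statistical structure the method
# assumes: donor-level bimodal "on/off" marker states shared by all of a
# donor's samples, sex-dependent heterosome probes, unimodal background
# probes, and optional injected donor-label mix-ups.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the regimes the method is used in: a few dozen donors
#' sampled at four time points; bimodal markers with "off" and "on" modes
#' at 4 and 10 on the log2 scale (midpoint 7, i.e. linear 128, matching
#' the default panel threshold) with a log2 standard deviation of 0.5, so
#' planted markers at around 47 samples give dips in the 0.12-0.15 range
#' typical of real fingerprinting probe sets; a donor-level minor allele
#' frequency of 0.3; and a unimodal background at the inter-mode midpoint.
#'
#' @param n_donors number of donors.
#' @param samples_per_donor serial samples (time points) per donor.
#' @param n_probes_total total probes; background probes fill whatever
#'   `n_bimodal + n_gender_probes` leaves.
#' @param n_bimodal number of bimodal (haplotype-like) marker probes.
#' @param minor_allele_freq donor-level probability of the high state, in
#'   `(0, 0.5]`.
#' @param mode_low_log2,mode_high_log2 the two expression modes (log2).
#' @param sd_log2 within-mode standard deviation (log2).
#' @param n_gender_probes sex-panel probes; the last one is XIST-like
#'   (high in females), the others Y-linked (high in males).  0 disables.
#' @param frac_female probability a donor is female.
#' @param mixup_rate fraction of samples whose recorded donor ID is
#'   swapped to a different donor, in `[0, 1)`.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return validated config list of class `"sim_config"`.
#' @export
sim_config <- function(n_donors = 12L, samples_per_donor = 4L,
                       n_probes_total = 1000L, n_bimodal = 20L,
                       minor_allele_freq = 0.3, mode_low_log2 = 4,
                       mode_high_log2 = 10, sd_log2 = 0.5,
                       n_gender_probes = 5L, frac_female = 0.5,
                       mixup_rate = 0, seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              samples_per_donor = as.integer(samples_per_donor),
              n_probes_total = as.integer(n_probes_total),
              n_bimodal = as.integer(n_bimodal),
              minor_allele_freq = minor_allele_freq,
              mode_low_log2 = mode_low_log2,
              mode_high_log2 = mode_high_log2, sd_log2 = sd_log2,
              n_gender_probes = as.integer(n_gender_probes),
              frac_female = frac_female, mixup_rate = mixup_rate,
              seed = as.integer(seed))
  problems <- character(0L)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_donors >= 1L, "n_donors must be >= 1")
  chk(cfg$samples_per_donor >= 1L, "samples_per_donor must be >= 1")
  chk(cfg$n_bimodal >= 0L && cfg$n_gender_probes >= 0L,
      "probe counts must be >= 0")
  chk(cfg$n_bimodal + cfg$n_gender_probes <= cfg$n_probes_total,
      "n_bimodal + n_gender_probes must not exceed n_probes_total")
  chk(cfg$minor_allele_freq > 0 && cfg$minor_allele_freq <= 0.5,
      "minor_allele_freq must lie in (0, 0.5]")
  chk(cfg$mode_high_log2 > cfg$mode_low_log2,
      "mode_high_log2 must exceed mode_low_log2")
  chk(cfg$sd_log2 > 0, "sd_log2 must be > 0")
  chk(cfg$frac_female >= 0 && cfg$frac_female <= 1,
      "frac_female must lie in [0, 1]")
  chk(cfg$mixup_rate >= 0 && cfg$mixup_rate < 1,
      "mixup_rate must lie in [0, 1)")
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic expression dataset with known truth
#'
#' Bimodal marker probes get one donor-level state each (`high` with
#' probability `minor_allele_freq`); every sample of a donor draws its
#' log2 intensity from the donor's mode, so the state is constant within
#' donors, as for a genuine haplotype.  Background probes are unimodal at
#' the inter-mode midpoint.  Sex-panel probes follow the donor's true sex.
#' Intensities are exported on the linear scale (2^log2).  If
#' `mixup_rate > 0`, recorded donor IDs are swapped via [inject_mixups()]
#' after generation, so the expression data always reflect the true
#' donors.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (linear expression matrix), `annotation`
#'   (sample_id, donor_id, timepoint, declared_sex, dataset_id; donor IDs
#'   as recorded, i.e. after any mix-ups), and `truth` (list: `states`
#'   donor-by-marker logical matrix of high states, `sex` per donor,
#'   `swaps` data frame of injected mix-ups).
#' @export
generate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    donors <- sprintf("D%02d", seq_len(cfg$n_donors))
    sex <- stats::setNames(
      ifelse(stats::runif(cfg$n_donors) < cfg$frac_female, "F", "M"), donors)
    samples <- as.vector(t(outer(donors, seq_len(cfg$samples_per_donor),
                                 function(d, t) sprintf("%s_T%d", d, t))))
    donor_of <- rep(donors, each = cfg$samples_per_donor)
    ns <- length(samples)

    bim_ids <- if (cfg$n_bimodal) sprintf("bimodal_%03d",
                                          seq_len(cfg$n_bimodal))
    else character(0L)
    gender_ids <- if (cfg$n_gender_probes) {
      if (cfg$n_gender_probes == 1L) "gender_XIST"
      else c(sprintf("gender_Y%d", seq_len(cfg$n_gender_probes - 1L)),
             "gender_XIST")
    } else character(0L)
    n_bg <- cfg$n_probes_total - cfg$n_bimodal - cfg$n_gender_probes
    bg_ids <- if (n_bg) sprintf("background_%04d", seq_len(n_bg))
    else character(0L)

    mid <- (cfg$mode_low_log2 + cfg$mode_high_log2) / 2
    states <- matrix(stats::runif(cfg$n_donors * cfg$n_bimodal) <
                       cfg$minor_allele_freq,
                     nrow = cfg$n_donors,
                     dimnames = list(donors, bim_ids))

    lg <- matrix(NA_real_, nrow = cfg$n_probes_total, ncol = ns,
                 dimnames = list(c(bim_ids, gender_ids, bg_ids), samples))
    for (p in seq_along(bim_ids)) {
      mode <- ifelse(states[donor_of, p], cfg$mode_high_log2,
                     cfg$mode_low_log2)
      lg[bim_ids[p], ] <- stats::rnorm(ns, mode, cfg$sd_log2)
    }
    if (cfg$n_gender_probes) {
      male <- sex[donor_of] == "M"
      for (g in seq_along(gender_ids)) {
        xist <- g == length(gender_ids) && grepl("XIST", gender_ids[g])
        high <- if (xist) !male else male
        mode <- ifelse(high, cfg$mode_high_log2, cfg$mode_low_log2)
        lg[gender_ids[g], ] <- stats::rnorm(ns, mode, cfg$sd_log2)
      }
    }
    if (n_bg) {
      lg[bg_ids, ] <- matrix(stats::rnorm(n_bg * ns, mid, cfg$sd_log2),
                             nrow = n_bg)
    }

    annotation <- data.frame(
      sample_id = samples, donor_id = donor_of,
      timepoint = rep(seq_len(cfg$samples_per_donor), cfg$n_donors),
      declared_sex = unname(sex[donor_of]), dataset_id = "SIM",
      stringsAsFactors = FALSE)

    swaps <- data.frame(sample_id = character(0L),
                        true_donor_id = character(0L),
                        recorded_donor_id = character(0L),
                        stringsAsFactors = FALSE)
    if (cfg$mixup_rate > 0) {
      mixed <- inject_mixups(annotation, cfg$mixup_rate,
                             seed = cfg$seed + 1L)
      annotation <- mixed$annotation
      swaps <- mixed$swaps
    }

    list(matrix = as_expression_matrix(2^lg), annotation = annotation,
         truth = list(states = states, sex = sex, swaps = swaps))
  })
}

#' Inject donor-label mix-ups into an annotation table
#'
#' For `ceiling(rate * n_samples)` randomly chosen samples the recorded
#' donor ID is replaced by a different donor's ID (a label reassignment:
#' the expression data keep reflecting the true donor).  Declared sex is
#' left as the true donor's sex, emulating a pure ID transcription error.
#'
#' @param annotation annotation data frame with at least two donors.
#' @param rate fraction of samples to relabel, `rate * n < n`.
#' @param seed RNG seed.
#' @return list with the modified `annotation` and `swaps` (data frame:
#'   `sample_id`, `true_donor_id`, `recorded_donor_id`).
#' @export
inject_mixups <- function(annotation, rate, seed = 1L) {
  donors <- unique(annotation$donor_id)
  if (length(donors) < 2L) {
    stop("need at least two donors to inject mix-ups", call. = FALSE)
  }
  n <- nrow(annotation)
  n_swap <- ceiling(rate * n)
  if (n_swap >= n) {
    stop("mix-up rate would relabel every sample", call. = FALSE)
  }
  if (n_swap == 0L) {
    return(list(annotation = annotation,
                swaps = data.frame(sample_id = character(0L),
                                   true_donor_id = character(0L),
                                   recorded_donor_id = character(0L),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    idx <- sample.int(n, n_swap)
    new_donor <- vapply(idx, function(i) {
      sample(setdiff(donors, annotation$donor_id[i]), 1L)
    }, "")
    swaps <- data.frame(sample_id = annotation$sample_id[idx],
                        true_donor_id = annotation$donor_id[idx],
                        recorded_donor_id = new_donor,
                        stringsAsFactors = FALSE)
    annotation$donor_id[idx] <- new_donor
    list(annotation = annotation, swaps = swaps)
  })
}
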