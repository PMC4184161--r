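# Binary panel scoring, sex calling, donor-consistency flagging and
# dataset summaries.

flag_levels <- c("OK", "SOFT", "HARD")

escalate <- function(current, new) {
  flag_levels[pmax(match(current, flag_levels), match(new, flag_levels))]
}

panel_intensities <- function(intensities, panel) {
  if (!is.null(names(intensities))) {
    missing <- setdiff(panel$probe_ids, names(intensities))
    if (length(missing)) {
      stop("missing panel probe(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    intensities <- intensities[panel$probe_ids]
  } else if (length(intensities) != length(panel$probe_ids)) {
    stop(sprintf("expected %d intensities for panel '%s', got %d",
                 length(panel$probe_ids), panel$name, length(intensities)),
         call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("panel intensities must be finite and >= 0", call. = FALSE)
  }
  as.numeric(intensities)
}

#' Score one sample against a marker panel
#'
#' Each panel probe contributes one binary digit: 1 if the sample's linear
#' intensity strictly surpasses the probe's threshold, 0 otherwise.  The
#' digit string (in panel order) is the sample's score; samples from the
#' same donor are expected to share it.
#'
#' @param intensities linear intensities; either named by probe ID or in
#'   panel order.
#' @param panel a `"marker_panel"`.
#' @return object of class `"sample_score"`: list with `digits` (string
#'   over 0/1), `bits` (integer vector) and `intensities`.
#' @examples
#' score_sample(c(45, 8041, 187), hla_panel())$digits   # "011"
#' @export
score_sample <- function(intensities, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  v <- panel_intensities(intensities, panel)
  bits <- as.integer(v > panel$thresholds)
  structure(list(digits = paste(bits, collapse = ""), bits = bits,
                 intensities = stats::setNames(v, panel$probe_ids)),
            class = "sample_score")
}

#' @export
print.sample_score <- function(x, ...) {
  cat(sprintf("score %s  (%s)\n", x$digits,
              paste(sprintf("%s=%g", names(x$intensities), x$intensities),
                    collapse = ", ")))
  invisible(x)
}

#' Score every sample of an expression matrix
#'
#' @param matrix expression matrix containing all panel probes.
#' @param panel a `"marker_panel"`.
#' @return data frame with `sample_id`, `score`, and one intensity column
#'   per panel probe.
#' @export
score_samples <- function(matrix, panel) {
  matrix <- as_expression_matrix(matrix)
  missing <- setdiff(panel$probe_ids, rownames(matrix))
  if (length(missing)) {
    stop("matrix lacks panel probe(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- matrix[panel$probe_ids, , drop = FALSE]
  scores <- apply(sub, 2L, function(v) {
    paste(as.integer(v > panel$thresholds), collapse = "")
  })
  out <- data.frame(sample_id = colnames(matrix), score = unname(scores),
                    stringsAsFactors = FALSE)
  for (p in panel$probe_ids) out[[p]] <- unname(sub[p, ])
  out
}

#' Call donor sex from a transcript sex panel
#'
#' Unanimous-panel rule: `M` if every Y-linked probe surpasses its
#' threshold and XIST does not; `F` if no Y-linked probe surpasses its
#' threshold and XIST does; `ambiguous` otherwise.  Ambiguity is a
#' first-class outcome, not an error: it marks samples whose sex evidence
#' is internally inconsistent.
#'
#' @param intensities linear intensities, named by probe ID or in panel
#'   order.
#' @param gender_panel a `"marker_panel"` with a `y_linked` attribute (see
#'   [redkx_panel()]).
#' @return object of class `"gender_call"`: list with `call` (one of
#'   `"F"`, `"M"`, `"ambiguous"`) and `evidence` (the per-probe digits).
#' @export
call_gender <- function(intensities, gender_panel = redkx_panel()) {
  stopifnot(inherits(gender_panel, "marker_panel"))
  y <- attr(gender_panel, "y_linked")
  if (is.null(y) || length(y) != length(gender_panel$probe_ids)) {
    stop("gender panel needs a 'y_linked' attribute marking Y-linked probes",
         call. = FALSE)
  }
  sc <- score_sample(intensities, gender_panel)
  bits <- sc$bits
  call <- if (all(bits[y] == 1L) && all(bits[!y] == 0L)) "M"
  else if (all(bits[y] == 0L) && all(bits[!y] == 1L)) "F"
  else "ambiguous"
  structure(list(call = call,
                 evidence = stats::setNames(bits, gender_panel$probe_ids)),
            class = "gender_call")
}

#' @export
print.gender_call <- function(x, ...) {
  cat(sprintf("sex call: %s  (digits %s)\n", x$call,
              paste(x$evidence, collapse = "")))
  invisible(x)
}

#' Sex calls for every sample of a matrix
#'
#' @inheritParams score_samples
#' @param gender_panel see [call_gender()].
#' @return data frame with `sample_id` and `gender_call`.
#' @export
call_genders <- function(matrix, gender_panel = redkx_panel()) {
  matrix <- as_expression_matrix(matrix)
  missing <- setdiff(gender_panel$probe_ids, rownames(matrix))
  if (length(missing)) {
    stop("matrix lacks sex-panel probe(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  calls <- vapply(colnames(matrix), function(s) {
    call_gender(matrix[gender_panel$probe_ids, s], gender_panel)$call
  }, "")
  data.frame(sample_id = colnames(matrix), gender_call = unname(calls),
             stringsAsFactors = FALSE)
}

majority_reference <- function(scores) {
  tab <- table(scores)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  # tie: the earliest sample whose score is among the tied winners
  scores[scores %in% winners][1L]
}

#' Check intra-donor score consistency
#'
#' Within each donor the majority score is taken as the reference (ties
#' broken by the earliest sample in annotation order).  A sample whose
#' digits differ from the reference only at probes whose intensity lies
#' within `soft_band_log2` of the threshold (on the log2 scale) is flagged
#' `SOFT` -- a slight transgression of the threshold, not critical on its
#' own.  Any other mismatch is flagged `HARD`: intensities fold-changes
#' away from the reference pattern suggest a possible sample mix-up.
#' Donors with a single sample cannot be checked and are annotated
#' `"no repeat"`.
#'
#' @param scores data frame from [score_samples()] (per-probe intensity
#'   columns are required for the soft-band decision).
#' @param annotation data frame with `sample_id` and `donor_id` covering
#'   every scored sample; order defines tie-breaking.
#' @param panel the `"marker_panel"` the scores came from.
#' @param soft_band_log2 half-width of the tolerance band around each
#'   log2 threshold (default 1.0, i.e. within two-fold of the threshold).
#' @return a `"donor_flag_report"` data frame with one row per sample:
#'   `sample_id`, `donor_id`, `hla_score`, `reference_score`, `flag`,
#'   `reasons` (`"; "`-joined, empty iff `flag == "OK"`), `note`, and
#'   logical `score_discordant`.
#' @export
check_donor_consistency <- function(scores, annotation, panel,
                                    soft_band_log2 = 1.0) {
  stopifnot(inherits(panel, "marker_panel"))
  missing <- setdiff(annotation$sample_id, scores$sample_id)
  if (length(missing)) {
    stop("annotation samples missing from scores: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(scores$sample_id, annotation$sample_id)
  if (length(extra)) {
    stop("scored samples absent from annotation: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  scores <- scores[match(annotation$sample_id, scores$sample_id), ,
                   drop = FALSE]
  k <- length(panel$probe_ids)

  out <- data.frame(
    sample_id = annotation$sample_id, donor_id = annotation$donor_id,
    hla_score = scores$score, reference_score = NA_character_,
    flag = "OK", reasons = "", note = "", score_discordant = FALSE,
    stringsAsFactors = FALSE)

  for (donor in unique(annotation$donor_id)) {
    idx <- which(annotation$donor_id == donor)
    if (length(idx) == 1L) {
      out$note[idx] <- "no repeat"
      out$reference_score[idx] <- out$hla_score[idx]
      next
    }
    ref <- majority_reference(out$hla_score[idx])
    out$reference_score[idx] <- ref
    ref_bits <- as.integer(strsplit(ref, "")[[1L]])
    for (i in idx) {
      bits <- as.integer(strsplit(out$hla_score[i], "")[[1L]])
      diff_pos <- which(bits != ref_bits)
      if (!length(diff_pos)) next
      probes <- panel$probe_ids[diff_pos]
      ints <- as.numeric(scores[scores$sample_id == out$sample_id[i],
                                probes])
      dist <- abs(log2(pmax(ints, .Machine$double.xmin)) -
                    log2(panel$thresholds[probes]))
      soft <- all(dist <= soft_band_log2)
      reason <- paste(sprintf(
        "%s at %g vs threshold %g (%.2g-fold)", probes, ints,
        panel$thresholds[probes],
        pmax(ints, 1) / panel$thresholds[probes]), collapse = "; ")
      reason <- paste0(
        if (soft) "score differs from donor reference (within soft band): "
        else "score differs from donor reference: ", reason)
      out$flag[i] <- if (soft) "SOFT" else "HARD"
      out$reasons[i] <- reason
      out$score_discordant[i] <- TRUE
    }
  }
  class(out) <- c("donor_flag_report", "data.frame")
  out
}

#' Fold sex calls into a donor flag report
#'
#' Adds a `gender_call` column and escalates flags to `HARD` with a
#' gender-mismatch reason when a sample's call contradicts its declared
#' sex, or when unambiguous calls disagree within a donor (the minority
#' call relative to the donor's majority is flagged).  Flags only ever
#' escalate (OK < SOFT < HARD).
#'
#' @param report a `"donor_flag_report"` from [check_donor_consistency()].
#' @param gender_calls data frame with `sample_id` and `gender_call`
#'   (values `F`/`M`/`ambiguous`), covering the report's samples.
#' @param declared_sex optional character vector named by sample ID (or a
#'   data frame with `sample_id`, `declared_sex`); values `F`/`M`, others
#'   ignored.
#' @return the augmented report, with logical column `gender_fail` added.
#' @export
combine_with_gender <- function(report, gender_calls, declared_sex = NULL) {
  stopifnot(inherits(report, "donor_flag_report"))
  if (is.data.frame(gender_calls)) {
    gc <- stats::setNames(as.character(gender_calls$gender_call),
                          gender_calls$sample_id)
  } else {
    gc <- gender_calls
  }
  missing <- setdiff(report$sample_id, names(gc))
  if (length(missing)) {
    stop("sex calls missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(declared_sex)) {
    declared_sex <- stats::setNames(as.character(declared_sex$declared_sex),
                                    declared_sex$sample_id)
  }
  report$gender_call <- unname(gc[report$sample_id])
  report$gender_fail <- FALSE

  add_reason <- function(i, reason) {
    report$flag[i] <<- escalate(report$flag[i], "HARD")
    report$reasons[i] <<- if (nzchar(report$reasons[i])) {
      paste(report$reasons[i], reason, sep = "; ")
    } else reason
    report$gender_fail[i] <<- TRUE
  }

  for (i in seq_len(nrow(report))) {
    call <- report$gender_call[i]
    dec <- if (!is.null(declared_sex)) declared_sex[report$sample_id[i]]
    else NA_character_
    if (call %in% c("F", "M") && !is.na(dec) && dec %in% c("F", "M") &&
        call != dec) {
      add_reason(i, sprintf(
        "gender mismatch: called %s but annotated %s", call, dec))
    }
  }
  for (donor in unique(report$donor_id)) {
    idx <- which(report$donor_id == donor)
    calls <- report$gender_call[idx]
    known <- calls %in% c("F", "M")
    if (sum(known) >= 2L && length(unique(calls[known])) > 1L) {
      maj <- majority_reference(calls[known])
      for (i in idx[known][calls[known] != maj]) {
        if (!report$gender_fail[i]) {
          add_reason(i, sprintf(
            "gender mismatch: called %s but donor majority is %s",
            report$gender_call[i], maj))
        }
      }
    }
  }
  report
}

#' Summarize a flag report per dataset
#'
#' One row per dataset: sample and repeat-donor counts, flagged samples,
#' sex-call failures and intra-donor score differences.  By default only
#' `HARD` flags count as flagged -- a slight threshold transgression
#' (`SOFT`) is noted but not critical; set `count_soft = TRUE` to include
#' them.
#'
#' @param report a (gender-augmented) `"donor_flag_report"`.
#' @param annotation annotation data frame with `sample_id`, `donor_id`,
#'   `dataset_id` and optionally `tissue` (passed through).
#' @param count_soft count `SOFT` flags as flagged (default `FALSE`).
#' @return data frame with one row per `dataset_id`: `n_samples`,
#'   `n_donors_with_repeats`, `n_flagged`, `n_gender_fail`, `n_score_diff`.
#' @export
summarize_dataset <- function(report, annotation, count_soft = FALSE) {
  stopifnot(inherits(report, "donor_flag_report"))
  ann <- annotation[match(report$sample_id, annotation$sample_id), ,
                    drop = FALSE]
  flagged_lvls <- if (count_soft) c("SOFT", "HARD") else "HARD"
  res <- lapply(split(seq_len(nrow(report)), ann$dataset_id), function(idx) {
    donors <- ann$donor_id[idx]
    data.frame(
      dataset_id = ann$dataset_id[idx[1L]],
      tissue = if ("tissue" %in% names(ann)) ann$tissue[idx[1L]]
      else NA_character_,
      n_samples = length(idx),
      n_donors_with_repeats = sum(table(donors) >= 2L),
      n_flagged = sum(report$flag[idx] %in% flagged_lvls),
      n_gender_fail = if ("gender_fail" %in% names(report)) {
        sum(report$gender_fail[idx])
      } else 0L,
      n_score_diff = sum(report$score_discordant[idx]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' HLA-DQA1 allele compatibility of a score's DQA1 digits
#'
#' The two HLA-DQA1 probe sets are allele-selective: each of their 11
#' probes either matches a given DQA1 allele's sequence perfectly or
#' covers a polymorphic site.  Given the score digits for 203290_at and
#' 213831_at, returns the alleles consistent with the observed
#' hybridization: a digit of 1 restricts to alleles matching at least
#' `match_floor` of the probe set's 11 probes, a digit of 0 to the
#' complement; the result is the intersection.  An empty result means the
#' digit pair is unresolved under this match floor.
#'
#' @param dqa1_digits two values in 0/1, for 203290_at then 213831_at.
#' @param match_floor minimum number of matching probes (of 11) for an
#'   allele to be considered hybridizing (default 9).
#' @param allele_matrix the allele-by-probe match table; defaults to the
#'   packaged table (see [hla_dqa1_matches()]).
#' @return character vector of allele names (empty if unresolved).
#' @examples
#' compatible_alleles(c(1, 0))                    # *0401, *0501
#' compatible_alleles(c(0, 1), match_floor = 11)  # *0103
#' @export
compatible_alleles <- function(dqa1_digits, match_floor = 9,
                               allele_matrix = hla_dqa1_matches()) {
  digits <- as.integer(dqa1_digits)
  if (length(digits) != 2L || any(is.na(digits)) ||
      !all(digits %in% c(0L, 1L))) {
    stop("'dqa1_digits' must be two values in {0, 1}", call. = FALSE)
  }
  sets <- c("203290_at", "213831_at")
  alleles <- unique(allele_matrix$allele)
  keep <- alleles
  for (j in 1:2) {
    sub <- allele_matrix[allele_matrix$probe_set == sets[j], , drop = FALSE]
    counts <- rowSums(sub[, grep("^p[0-9]", names(sub)), drop = FALSE])
    hybridizing <- sub$allele[counts >= match_floor]
    keep <- if (digits[j] == 1L) intersect(keep, hybridizing)
    else setdiff(keep, hybridizing)
  }
  keep
}

#' The packaged HLA-DQA1 allele-by-probe match table
#'
#' For each of seven common DQA1 alleles and each of the 11 probes of the
#' two HLA-DQA1 probe sets, whether the probe's sequence matches the
#' allele (1) or covers a polymorphism (0).  Shipped as static reference
#' data; the sequence alignment that produced it is not recomputed here.
#'
#' @return data frame with columns `allele`, `probe_set`, `p01` .. `p11`.
#' @export
hla_dqa1_matches <- function() {
  path <- system.file("extdata", "hla_dqa1_allele_matches.csv",
                      package = "hlascore", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
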