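# Marker panel definitions: ordered probe sets with per-probe linear
# intensity thresholds.  The order is significant: it fixes the digit
# positions of the binary score.

#' Define a marker panel
#'
#' @param probe_ids character vector of unique probe-set IDs; the order
#'   defines the digit positions of the score.
#' @param thresholds positive linear intensity thresholds, one per probe
#'   (recycled if length 1).  A digit is 1 iff the intensity strictly
#'   surpasses its threshold.
#' @param name panel name used in reports.
#' @return object of class `"marker_panel"`.
#' @export
marker_panel <- function(probe_ids, thresholds, name = "panel") {
  probe_ids <- as.character(probe_ids)
  if (anyDuplicated(probe_ids)) {
    stop("panel probe IDs must be unique", call. = FALSE)
  }
  thresholds <- rep_len(as.numeric(thresholds), length(probe_ids))
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop("thresholds must be positive finite numbers", call. = FALSE)
  }
  structure(list(name = name, probe_ids = probe_ids,
                 thresholds = stats::setNames(thresholds, probe_ids)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker panel '%s' (%d probe sets):\n", x$name,
              length(x$probe_ids)))
  for (i in seq_along(x$probe_ids)) {
    cat(sprintf("  digit %d: %s  > %g (log2 %.3g)\n", i, x$probe_ids[i],
                x$thresholds[i], log2(x$thresholds[i])))
  }
  invisible(x)
}

#' The default HLA fingerprinting panel
#'
#' Three haplotype-specific probe sets, in score digit order: 203290_at
#' (HLA-DQA1, *0401-allele-matched), 213831_at (HLA-DQA1,
#' *0103-allele-matched) and 209728_at (HLA-DRB4).  The default threshold
#' of 128 per probe corresponds to the empirically developed log2 cut-off
#' of 7 separating the "off" and "on" expression modes; per-probe
#' thresholds can be overridden, and re-tuning per tissue is recommended
#' when global intensity scaling differs.
#'
#' @param thresholds linear thresholds in digit order (default all 128).
#' @return a `"marker_panel"`.
#' @export
hla_panel <- function(thresholds = c(128, 128, 128)) {
  marker_panel(c("203290_at", "213831_at", "209728_at"), thresholds,
               name = "HLA-score")
}

#' The REDKX transcript sex panel
#'
#' Heterosome-expressed genes used to call donor sex from expression data:
#' Y-linked RPS4Y1 (201909_at), EIF1AY (204409_s_at), DDX3Y (205000_at)
#' and KDM5D (206700_s_at), plus X-inactivation transcript XIST
#' (224588_at).  Decision thresholds are configuration, not a published
#' constant; the default of 128 matches the HLA panel's scale and should
#' be tuned per tissue/platform.
#'
#' @param thresholds linear thresholds, one per probe in the order
#'   RPS4Y1, EIF1AY, DDX3Y, KDM5D, XIST (recycled if length 1).
#' @return a `"marker_panel"` with a `y_linked` attribute marking which
#'   probes are Y-chromosomal (all but XIST).
#' @export
redkx_panel <- function(thresholds = 128) {
  p <- marker_panel(
    c("201909_at", "204409_s_at", "205000_at", "206700_s_at", "224588_at"),
    thresholds, name = "REDKX")
  attr(p, "y_linked") <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  p
}

#' Read a panel definition from a YAML config file
#'
#' Expected keys: `name`, `probes` (list of `probe_id: threshold` pairs in
#' digit order) and optionally `y_linked` (logical vector for sex panels).
#'
#' @param path YAML file.
#' @return a `"marker_panel"`.
#' @export
read_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$probes)) {
    stop("panel config needs a 'probes' mapping of probe_id: threshold",
         call. = FALSE)
  }
  p <- marker_panel(names(cfg$probes), unlist(cfg$probes),
                    name = if (is.null(cfg$name)) "panel" else cfg$name)
  if (!is.null(cfg$y_linked)) attr(p, "y_linked") <- as.logical(cfg$y_linked)
  p
}
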