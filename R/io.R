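# Readers and writers for expression matrices and annotation tables.
#
# Matrix formats: TSV/CSV (first column probe IDs, header row sample IDs)
# and GCT 1.2.  Annotation: TSV with required columns sample_id, donor_id,
# timepoint, declared_sex, dataset_id.

#' Read an expression matrix
#'
#' The format is chosen from the file extension: `.gct` is parsed as GCT
#' 1.2, `.csv` as comma-separated, anything else as tab-separated.  For
#' TSV/CSV the first column holds probe IDs and the header row sample IDs.
#'
#' @param path file path.
#' @return a validated expression matrix (probes x samples).
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gct") return(read_gct(path))
  sep <- if (ext == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) {
    stop("malformed matrix file (need a probe-ID column plus >= 1 sample): ",
         path, call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensities in ", path, call. = FALSE)
  rownames(m) <- as.character(df[[1L]])
  as_expression_matrix(m)
}

read_gct <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !grepl("^#1\\.2", lines[1L])) {
    stop("not a GCT 1.2 file (missing '#1.2' header): ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][1:2])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 3L) stop("malformed GCT table: ", path, call. = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (nrow(m) != dims[1L] || ncol(m) != dims[2L]) {
    stop(sprintf("GCT header promises %d x %d but table is %d x %d",
                 dims[1L], dims[2L], nrow(m), ncol(m)), call. = FALSE)
  }
  as_expression_matrix(m)
}

#' Write an expression matrix
#'
#' TSV layout mirroring the reader: probe IDs in the first column
#' (`probe_id`), sample IDs in the header.  With `format = "gct"` a GCT 1.2
#' file is written (the Description column repeats the probe ID unless
#' `description` is given).  Numbers are written at full precision so that
#' write-then-read is an identity.
#'
#' @param matrix expression matrix.
#' @param path output path.
#' @param format `"tsv"` (default) or `"gct"`.
#' @param description optional character vector for the GCT Description
#'   column.
#' @export
write_expression_matrix <- function(matrix, path, format = c("tsv", "gct"),
                                    description = NULL) {
  matrix <- as_expression_matrix(matrix)
  format <- match.arg(format)
  num <- format(matrix, digits = 17, trim = TRUE, scientific = FALSE)
  if (format == "gct") {
    desc <- if (is.null(description)) rownames(matrix) else description
    header <- c("#1.2", paste(nrow(matrix), ncol(matrix), sep = "\t"),
                paste(c("Name", "Description", colnames(matrix)),
                      collapse = "\t"))
    body <- apply(cbind(rownames(matrix), desc, num), 1L, paste,
                  collapse = "\t")
  } else {
    header <- paste(c("probe_id", colnames(matrix)), collapse = "\t")
    body <- apply(cbind(rownames(matrix), num), 1L, paste, collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

annotation_columns <- c("sample_id", "donor_id", "timepoint", "declared_sex",
                        "dataset_id")

#' Read a sample-annotation table
#'
#' TSV with required columns `sample_id`, `donor_id`, `timepoint`,
#' `declared_sex`, `dataset_id`; extra columns (e.g. a precomputed
#' `gender_call`) pass through.
#'
#' @param path file path.
#' @return data frame, one row per sample.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  missing <- setdiff(annotation_columns, names(df))
  if (length(missing)) {
    stop("annotation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$donor_id <- as.character(df$donor_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in annotation", call. = FALSE)
  }
  df
}

#' Write a tab-separated report
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
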