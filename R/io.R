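#' Write a per-subject CMN as a CSV matrix with ROI-name header
#'
#' @param cmn CMN matrix (ideally with ROI dimnames).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cmn_csv <- function(cmn, path) {
  .validate_cmn(cmn)
  if (is.null(rownames(cmn))) {
    nm <- .roi_names(nrow(cmn))
    dimnames(cmn) <- list(nm, nm)
  }
  write.csv(as.data.frame(cmn), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cmn_csv
#' @export
read_cmn_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  .validate_cmn(m)
  m
}

#' Write a cohort feature table with edge-name headers
#'
#' Columns are `"roiA|roiB"` edge names; an extra first column carries the
#' subject id and a second the group label when available.
#'
#' @param features Subjects x n_f matrix from [build_feature_table()].
#' @param path Output file.
#' @param labels Optional group labels.
#' @return `path`, invisibly.
#' @export
write_feature_table_csv <- function(features, path, labels = NULL) {
  df <- data.frame(subject_id = rownames(features) %||%
                     sprintf("sub-%04d", seq_len(nrow(features))),
                   check.names = FALSE)
  if (!is.null(labels)) df$group <- as.character(labels)
  df <- cbind(df, as.data.frame(features, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FreeSurfer aparc-stats-like whitespace table
#'
#' Tolerates `#` comment lines; column names are taken from a
#' `# ColHeaders ...` comment when present, otherwise generic names are
#' used with the first column treated as the region name.
#'
#' @param path Path to the stats file.
#' @return data.frame with a `StructName` column and numeric measurement
#'   columns.
#' @export
read_aparc_stats <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#\\s*ColHeaders", lines, value = TRUE)
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(data_lines)) stopf("no data rows in %s", path)
  df <- read.table(text = data_lines, header = FALSE,
                   stringsAsFactors = FALSE)
  if (length(hdr)) {
    cols <- strsplit(trimws(sub("^#\\s*ColHeaders", "", hdr[1])),
                     "\\s+")[[1]]
    if (length(cols) == ncol(df)) names(df) <- cols
  }
  if (!"StructName" %in% names(df)) names(df)[1] <- "StructName"
  df
}

#' Read a tidy cohort attribute CSV
#'
#' Alias of [read_cohort_csv()]; tolerant of `#` comment lines.
#'
#' @param path Path to the CSV.
#' @return A `cmn_cohort`.
#' @export
read_attribute_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  read_cohort_csv(tmp)
}
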