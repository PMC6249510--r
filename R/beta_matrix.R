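#' Beta-value matrix container
#'
#' A validated container for array methylation beta values: a numeric
#' samples x probes matrix in \[0, 1\] with `NA` as the explicit missing
#' marker, plus an optional same-shape matrix of detection p-values.
#'
#' @param values numeric matrix, samples in rows, CpG probes in columns,
#'   with unique row and column names.  All non-missing entries must lie
#'   in \[0, 1\].
#' @param detection_p optional numeric matrix of per-measurement detection
#'   p-values with the same dimensions and dimnames as `values`.
#' @return An object of class `beta_matrix`.
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("s", 1:3), c("cg00000001", "cg00000002")))
#' b <- beta_matrix(m)
#' n_probes(b)
#' @export
beta_matrix <- function(values, detection_p = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample (row) and probe (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate probe identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at sample '%s', probe '%s' (value %g)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, 1], bad[1, 2]]))
  }
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values)))
      stop("detection_p shape does not match beta values")
    if (!identical(dimnames(detection_p), dimnames(values)))
      stop("detection_p dimnames do not match beta values")
    bad <- which(!is.na(detection_p) & (detection_p < 0 | detection_p > 1),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) stop("detection p-value out of [0,1]")
  }
  structure(list(values = values, detection_p = detection_p),
            class = "beta_matrix")
}

#' @rdname beta_matrix
#' @param x a `beta_matrix`.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname beta_matrix
#' @export
n_probes <- function(x) ncol(x$values)

#' @rdname beta_matrix
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname beta_matrix
#' @export
probe_ids <- function(x) colnames(x$values)

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d samples x %d probes (%.1f%% missing%s)\n",
              n_samples(x), n_probes(x),
              100 * mean(is.na(x$values)),
              if (is.null(x$detection_p)) "" else "; detection p present"))
  invisible(x)
}

#' Read a beta-value matrix from wide delimited text
#'
#' The on-disk layout is probes as rows and samples as columns (the 27K
#' platform is small enough that wide text is practical).  Values outside
#' \[0, 1\] or unparseable cells raise an error; nothing is silently
#' clipped.  Missing values are encoded as `NA`.
#'
#' @param path file path to the matrix.
#' @param dialect `"wide_tsv"` (default) or `"wide_csv"`.
#' @param detection_p_path optional path to a same-shape detection p-value
#'   matrix in the same dialect.
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(path, dialect = c("wide_tsv", "wide_csv"),
                             detection_p_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "wide_tsv") "\t" else ","
  read_wide <- function(p) {
    df <- utils::read.table(p, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, colClasses = "character",
                            comment.char = "")
    m <- as.matrix(df)
    num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
    bad <- which(is.na(num) & !(is.na(m) | m %in% c("NA", "", "NaN")),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("unparseable cell at probe '%s', sample '%s': '%s'",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                   m[bad[1, 1], bad[1, 2]]))
    t(num)  # internal orientation: samples x probes
  }
  vals <- read_wide(path)
  dp <- if (!is.null(detection_p_path)) read_wide(detection_p_path) else NULL
  beta_matrix(vals, detection_p = dp)
}

#' Write a beta-value matrix as wide delimited text
#'
#' @param x a [beta_matrix].
#' @param path output path.
#' @param dialect `"wide_tsv"` or `"wide_csv"`.
#' @param digits decimal digits retained in the serialization (round-trip
#'   precision; default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, dialect = c("wide_tsv", "wide_csv"),
                              digits = 6) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "wide_tsv") "\t" else ","
  m <- t(round(x$values, digits))  # probes as rows on disk
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe list (one identifier per line)
#'
#' Lines starting with `#` are comments; blank lines are skipped; the
#' result is a deduplicated character vector.  An empty file yields an
#' empty set with a warning.
#'
#' @param path file path.
#' @return character vector of unique probe identifiers.
#' @export
read_probe_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("probe list '", path, "' is empty")
    return(character(0))
  }
  ids <- unique(lines)
  if (length(ids) < length(lines))
    warning(length(lines) - length(ids), " duplicate probe id(s) dropped")
  op_log("io", sprintf("read %d unique probe ids from %s", length(ids), basename(path)))
  ids
}

#' The 13 behavioral measures of the drinking-behavior schema
#'
#' Alcohol Dependence Scale subscales and total (ADS), three AUDIT
#' consumption items and the AUDIT total, and the Impaired Control Scale
#' subscales and total (ICS).
#'
#' @return character vector of length 13.
#' @export
behavior_measures <- function() {
  c("ADS_con", "ADS_obs", "ADS_per", "ADS_phy", "ADS_tot",
    "AUDIT_1", "AUDIT_2", "AUDIT_3", "AUDIT_tot",
    "ICS_total", "ICS_ac", "ICS_fc", "ICS_pc")
}

#' Packaged behavioral-assessment schema
#'
#' The shipped schema table (measure, parent assessment, description)
#' behind [behavior_measures()].
#'
#' @return data.frame with 13 rows.
#' @export
behavior_schema <- function() {
  path <- system.file("extdata", "behavior_measures.tsv",
                      package = "oppomark", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' The six race levels used for dummy coding
#' @return character vector of length 6.
#' @export
race_levels <- function() {
  c("Caucasian", "AfricanAmerican", "AsianAmerican", "Hispanic",
    "Native", "Multiracial")
}

#' Read a sample sheet
#'
#' Fixed-name CSV with columns `sample_id`, `subject_id`, `cohort`,
#' `timepoint`, `group`, `age`, `sex`, `race`, `batch`, `vo2_increased`
#' and, optionally, the 13 behavioral measure columns.
#'
#' @param path CSV file path.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "cohort", "age", "sex", "race", "batch")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("sample sheet missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  df
}
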