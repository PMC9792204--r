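#' Construct a validated methylation matrix
#'
#' A methylation matrix is a numeric samples x CpGs matrix of beta values
#' (methylated fraction) in \[0, 1\], with unique sample IDs as row names and
#' unique CpG IDs as column names. Missing values are allowed.
#'
#' @param values Numeric matrix, rows = samples, columns = CpGs.
#' @param sample_ids Character vector of sample IDs. Defaults to existing
#'   row names.
#' @param cpg_ids Character vector of CpG IDs. Defaults to existing column
#'   names.
#' @return A matrix of class `methylation_matrix`.
#' @examples
#' m <- methylation_matrix(matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2),
#'                         sample_ids = c("s1", "s2"),
#'                         cpg_ids = c("cg01", "cg02"))
#' @export
methylation_matrix <- function(values, sample_ids = rownames(values),
                               cpg_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("beta values must be numeric")
  }
  if (is.null(sample_ids) || is.null(cpg_ids)) {
    stop("sample IDs and CpG IDs are required (row/column names or arguments)")
  }
  sample_ids <- as.character(sample_ids)
  cpg_ids <- as.character(cpg_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length of sample_ids does not match number of rows")
  }
  if (length(cpg_ids) != ncol(values)) {
    stop("length of cpg_ids does not match number of columns")
  }
  check_unique(sample_ids, "sample ID")
  check_unique(cpg_ids, "CpG ID")
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "beta values must lie in [0, 1]; %d offending value(s), first at sample '%s', CpG '%s' (%g)",
      length(bad), sample_ids[idx[1]], cpg_ids[idx[2]], values[bad[1]]))
  }
  dimnames(values) <- list(sample_ids, cpg_ids)
  class(values) <- c("methylation_matrix", class(values))
  values
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s(s): %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  invisible(ids)
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %d samples x %d CpGs, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a methylation beta matrix from delimited text
#'
#' Expects samples in rows and CpGs in columns: the first column holds sample
#' IDs and the header row holds CpG IDs. Empty cells become missing values.
#' Values outside \[0, 1\] are rejected. A first column that itself looks like
#' CpG identifiers (`cg` followed by digits) triggers an error suggesting the
#' file is transposed.
#'
#' @param path Path to a CSV or TSV file.
#' @param dialect `"csv"` or `"tsv"`; default guesses from the file extension.
#' @return A [methylation_matrix()].
#' @seealso [write_methylation()]
#' @export
read_methylation <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- dialect_sep(path, dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  if (ncol(df) < 2) stop("expected a sample-ID column plus at least one CpG column")
  ids <- df[[1]]
  if (all(grepl("^cg\\d+$", ids[!is.na(ids)])) && length(ids) > 0) {
    stop("first column contains CpG identifiers (cg...); the file appears ",
         "to be transposed - expected samples in rows and CpGs in columns")
  }
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L)
  for (j in seq_len(ncol(df) - 1L)) {
    cell <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row %d (sample '%s'), column '%s'",
                   cell[bad[1]], bad[1], ids[bad[1]], colnames(df)[j + 1L]))
    }
    vals[, j] <- num
  }
  methylation_matrix(vals, sample_ids = ids, cpg_ids = colnames(df)[-1])
}

#' Write a methylation matrix to delimited text
#'
#' Inverse of [read_methylation()]: first column `sample_id`, one column per
#' CpG. Round-trips losslessly up to numeric print precision (15 significant
#' digits).
#'
#' @param m A [methylation_matrix()] (or plain named matrix).
#' @param path Output file path.
#' @param dialect `"csv"` or `"tsv"`; default guesses from the extension.
#' @export
write_methylation <- function(m, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- dialect_sep(path, dialect)
  df <- data.frame(sample_id = rownames(m),
                   format_reals(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

format_reals <- function(x) {
  out <- apply(x, 2, function(col) {
    s <- formatC(col, digits = 15, format = "g")
    s[is.na(col)] <- NA_character_
    s
  })
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- colnames(x)
  out
}

dialect_sep <- function(path, dialect) {
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (dialect == "tsv") "\t" else ","
}

#' Read a phenotype table from delimited text
#'
#' The table must contain a `sample_id` column with unique values; typical
#' further columns are `age` (years), `female` (0/1), `time` (follow-up
#' years), `event` (0/1 death indicator), plasma analytes (e.g. `CRP` in
#' mg/L, `A1C` in %), `packyrs` (smoking pack-years) and arbitrary covariate
#' or stratum columns. Basic integrity constraints are checked.
#'
#' @param path Path to a CSV or TSV file.
#' @param dialect `"csv"` or `"tsv"`; default guesses from the extension.
#' @return A `data.frame` with one row per sample.
#' @export
read_phenotypes <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- dialect_sep(path, dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  validate_phenotypes(df)
}

#' Validate a phenotype table
#'
#' @param p A `data.frame` with a `sample_id` column.
#' @return The validated `data.frame` (invisibly unchanged).
#' @export
validate_phenotypes <- function(p) {
  if (!"sample_id" %in% names(p)) stop("phenotype table needs a 'sample_id' column")
  p$sample_id <- as.character(p$sample_id)
  check_unique(p$sample_id, "sample ID")
  if ("female" %in% names(p)) {
    ok <- is.na(p$female) | p$female %in% c(0, 1)
    if (!all(ok)) stop("'female' must be 0/1; offending sample: ",
                       p$sample_id[which(!ok)[1]])
  }
  if ("age" %in% names(p) && any(!is.na(p$age) & p$age <= 0)) {
    stop("'age' must be positive")
  }
  if (all(c("time", "event") %in% names(p))) {
    bad <- !is.na(p$event) & p$event == 1 & (!is.na(p$time) & p$time <= 0)
    if (any(bad)) stop("event = 1 requires time > 0; offending sample: ",
                       p$sample_id[which(bad)[1]])
  }
  p
}

#' Write a phenotype table to delimited text
#'
#' @inheritParams write_methylation
#' @param p Phenotype `data.frame` with a `sample_id` column.
#' @export
write_phenotypes <- function(p, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- dialect_sep(path, dialect)
  utils::write.table(p, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Align a methylation matrix and phenotype table on shared samples
#'
#' Restricts both inputs to the intersection of their sample IDs, in the
#' order the shared IDs appear in the methylation matrix, and reports how
#' many samples were dropped from each side.
#'
#' @param m A [methylation_matrix()].
#' @param p Phenotype `data.frame` with a `sample_id` column.
#' @return A list with elements `m` and `p`, row-aligned.
#' @export
align_samples <- function(m, p) {
  p <- validate_phenotypes(p)
  shared <- intersect(rownames(m), p$sample_id)
  if (length(shared) == 0) {
    stop("no shared sample IDs between methylation matrix and phenotype table")
  }
  dropped_m <- nrow(m) - length(shared)
  dropped_p <- nrow(p) - length(shared)
  if (dropped_m > 0 || dropped_p > 0) {
    message(sprintf("align_samples: dropped %d methylation and %d phenotype sample(s)",
                    dropped_m, dropped_p))
  }
  m2 <- m[shared, , drop = FALSE]
  class(m2) <- class(m)
  list(m = m2, p = p[match(shared, p$sample_id), , drop = FALSE])
}

#' Mask extreme values at six standard deviations
#'
#' Sets to missing every value lying more than `z_max` standard deviations
#' from the mean, with mean and SD computed once over the non-missing input
#' (single pass; the moments are not recomputed after masking). Used to
#' drop per-CpG methylation outliers before EWAS. If the input SD is zero
#' the vector is returned unchanged.
#'
#' @param x Numeric vector (missing values allowed; at least 3 non-missing).
#' @param z_max Threshold in SD units; default 6.
#' @return `x` with extreme entries set to `NA`.
#' @export
mask_extreme_values <- function(x, z_max = 6) {
  obs <- x[!is.na(x)]
  if (length(obs) < 3) stop("need at least 3 non-missing values")
  s <- stats::sd(obs)
  if (is.na(s) || s == 0) return(x)
  m <- mean(obs)
  x[!is.na(x) & abs(x - m) / s > z_max] <- NA
  x
}
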