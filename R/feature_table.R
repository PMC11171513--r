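#' Two-class feature table
#'
#' The central data container: a samples x features numeric matrix with a
#' binary outcome label and per-feature metadata. Categorical features are
#' stored as integer level codes (1..L); missing cells are `NA`, and the
#' missing mask is exactly `is.na(values)`.
#'
#' @param values numeric matrix (samples x features) with column names.
#' @param labels integer/numeric vector of 0/1 outcome labels, one per row.
#' @param meta data frame with one row per feature and columns `name`,
#'   `kind` (one of `"numeric"`, `"categorical"`, `"binary"`) and
#'   `n_levels` (number of levels for categorical features, `NA` otherwise).
#' @param label_name name of the outcome column used in CSV output.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, labels, meta, label_name = "label") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.integer(labels)
  if (nrow(values) != length(labels)) {
    stop("`labels` must have one entry per row of `values`")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("name", "kind")
  if (!all(required %in% names(meta))) {
    stop("`meta` needs columns `name` and `kind`")
  }
  if (!"n_levels" %in% names(meta)) meta$n_levels <- NA_integer_
  if (nrow(meta) != ncol(values)) {
    stop("`meta` must have one row per feature column")
  }
  if (anyDuplicated(meta$name)) stop("feature names must be unique")
  if (!all(meta$kind %in% c("numeric", "categorical", "binary"))) {
    stop("feature kind must be numeric, categorical or binary")
  }
  colnames(values) <- meta$name
  structure(
    list(values = values, labels = labels, meta = meta,
         label_name = label_name),
    class = "feature_table"
  )
}

#' @method print feature_table
#' @export
print.feature_table <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf(
    "<feature_table> %d samples x %d features (%d/%d labels 0/1, %d missing cells)\n",
    nrow(x$values), ncol(x$values),
    sum(x$labels == 0L), sum(x$labels == 1L), n_miss
  ))
  kinds <- table(x$meta$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Missing-value mask of a feature table
#'
#' @param table a [feature_table()].
#' @return logical matrix, `TRUE` exactly where a cell is missing.
#' @export
missing_mask <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  is.na(table$values)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- as.data.frame(x$values)
  df[[x$label_name]] <- x$labels
  df
}

feature_names <- function(table) table$meta$name

numeric_features <- function(table) {
  table$meta$name[table$meta$kind == "numeric"]
}

# Subset the feature columns of a table, keeping labels and metadata aligned.
select_features <- function(table, features) {
  stopifnot(all(features %in% feature_names(table)))
  idx <- match(features, table$meta$name)
  feature_table(table$values[, idx, drop = FALSE], table$labels,
                table$meta[idx, , drop = FALSE], table$label_name)
}

#' Write a cohort to CSV with a JSON metadata sidecar
#'
#' Writes the table as plain CSV (header row, `NA` missing token, `.`
#' decimal separator, UTF-8) plus `<path>.meta.json` describing each
#' feature's kind so the table round-trips through [read_cohort()].
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(
    list(label_name = table$label_name, meta = table$meta),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV path; `<path>.meta.json` must sit next to it.
#' @return a [feature_table()].
#' @export
read_cohort <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path)
  }
  side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, na.strings = "NA", check.names = FALSE)
  label_name <- side$label_name
  if (!label_name %in% names(df)) {
    stop("label column `", label_name, "` not present in ", path)
  }
  labels <- df[[label_name]]
  df[[label_name]] <- NULL
  meta <- as.data.frame(side$meta, stringsAsFactors = FALSE)
  feature_table(as.matrix(df[, meta$name, drop = FALSE]), labels, meta,
                label_name)
}
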