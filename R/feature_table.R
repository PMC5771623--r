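#' Samples-by-features table with explicit missing-value sentinels
#'
#' A thin matrix wrapper shared by the vegetation-index and fluorescence
#' feature computations. Missing / undefined entries are `NA` and are
#' never silently imputed; downstream model assembly drops rows with
#' sentinels in the selected feature subset only.
#'
#' @param values Numeric matrix, samples in rows, features in columns
#'   (column names = feature names).
#' @param sample_ids Character vector, one id per row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, sample_ids) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            length(sample_ids) == nrow(values))
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature names", call. = FALSE)
  }
  structure(list(sample_ids = as.character(sample_ids),
                 feature_names = colnames(values),
                 values = values),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d samples x %d features, %d missing>\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Column-bind feature tables over the same samples
#'
#' @param ... `feature_table` objects with identical sample ids in order.
#' @return A combined `feature_table`.
#' @export
cbind_features <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  ids <- tabs[[1L]]$sample_ids
  for (t in tabs[-1L]) {
    if (!identical(t$sample_ids, ids)) {
      stop("feature tables cover different samples", call. = FALSE)
    }
  }
  feature_table(do.call(cbind, lapply(tabs, function(t) t$values)), ids)
}

#' Write a feature table as delimited text
#'
#' First column `sample_id`, then one column per feature; the `NA`
#' sentinel is serialized as an empty cell.
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(sample_id = ft$sample_ids, ft$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  feature_table(m, ids)
}
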