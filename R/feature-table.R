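#' Construct and validate a feature table
#'
#' A feature table is the unit of all community analysis: a samples x taxa
#' matrix of non-negative integer counts (ASV counts for one amplicon
#' marker), with unique sample identifiers as row names and unique taxon
#' identifiers as column names.
#'
#' @param counts Numeric matrix, samples in rows, taxa in columns. Row and
#'   column names are required and must be unique.
#' @return An integer matrix of class `feature_table`.
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("Feature tables need sample ids as rownames and taxon ids as colnames.")
  }
  dup_s <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_s)) {
    abort(sprintf("Duplicated sample id(s): %s", paste(unique(dup_s), collapse = ", ")))
  }
  dup_t <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_t)) {
    abort(sprintf("Duplicated taxon id(s): %s", paste(unique(dup_t), collapse = ", ")))
  }
  if (anyNA(counts)) abort("Feature table counts must not contain missing values.")
  if (any(counts < 0)) abort("Feature table counts must be non-negative.")
  if (any(counts != round(counts))) abort("Feature table counts must be integers.")
  storage.mode(counts) <- "integer"
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d taxa, total count %s\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read a feature table from TSV
#'
#' Expects a header row of taxon ids and a first column of sample ids;
#' lines starting with `#` are ignored.
#'
#' @param path Path to a tab-separated file.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- read_plain_tsv(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("Feature table counts must be numeric.")
  rownames(m) <- ids
  feature_table(m)
}

#' Write a feature table to TSV
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param seed Optional integer recorded in the file header.
#' @export
write_feature_table <- function(table, path, seed = NULL) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  write_stamped_tsv(df, path, seed = seed)
}

#' Tidy a feature table into long form
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `taxon_id`, `count`.
#' @exportS3Method generics::tidy
tidy.feature_table <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "taxon_id",
                        values_to = "count")
}
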