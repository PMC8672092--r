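#' Fuse two feature matrices column-wise
#'
#' Binds the columns of `a` then `b` for the same rows, the fusion step that
#' joins selected k-mer composition features with the 188D block (260 + 188 =
#' 448 columns in the default k = 3 configuration). Row ids must match in
#' order; column names must not collide (use the prefixes to namespace).
#'
#' @param a,b Numeric matrices with identical rownames in identical order.
#' @param prefix_a,prefix_b Optional strings prepended to the respective
#'   column names before binding.
#'
#' @return Numeric matrix with `ncol(a) + ncol(b)` columns.
#' @export
combine_features <- function(a, b, prefix_a = NULL, prefix_b = NULL) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b))) {
    stop("row ids of the two matrices must match in order", call. = FALSE)
  }
  if (!is.null(prefix_a) && ncol(a)) colnames(a) <- paste0(prefix_a, colnames(a))
  if (!is.null(prefix_b) && ncol(b)) colnames(b) <- paste0(prefix_b, colnames(b))
  clash <- intersect(colnames(a), colnames(b))
  if (length(clash)) {
    stop("column name collision: ", paste(utils::head(clash, 5), collapse = ", "),
         "; namespace with prefixes", call. = FALSE)
  }
  cbind(a, b)
}

#' Write a feature matrix as TSV
#'
#' The shared dialect of all encoder and selection stages: a header row, a
#' leading `id` column, one column per feature, and an optional trailing
#' `label` column.
#'
#' @param x Numeric matrix with rownames (ids) and colnames (feature names).
#' @param path Output path.
#' @param labels Optional 0/1 integer vector aligned to rows.
#' @export
write_feature_tsv <- function(x, path, labels = NULL) {
  stopifnot(is.matrix(x))
  df <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x), all(labels %in% c(0L, 1L)))
    df$label <- as.integer(labels)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_tsv()]
#'
#' @param path Input path.
#' @return List with `x` (numeric matrix, ids as rownames) and `labels`
#'   (integer vector or `NULL` when the file has no label column).
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("feature TSV must start with an id column", call. = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df$id
  storage.mode(x) <- "double"
  list(x = x, labels = labels)
}
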