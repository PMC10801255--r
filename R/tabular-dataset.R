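#' Construct a tabular classification dataset
#'
#' The core data container: a numeric feature matrix, an integer label vector
#' coded 0..K-1, and zero or more named categorical attribute columns (sex,
#' race, outcome, ...) coded as contiguous integers starting at 0. Attributes
#' define the groups over which performance uniformity is enforced.
#'
#' @param features numeric matrix, n rows by d feature columns.
#' @param labels integer vector of length n with values in 0..K-1.
#' @param attributes named list of integer vectors (length n each), every
#'   column coded 0..(n_values-1) with all codes contiguous from 0.
#' @param feature_names optional character vector of feature names.
#' @param attribute_value_labels optional named list mapping each attribute
#'   to the text labels of its codes.
#' @return An object of class `tabular_dataset`.
#' @export
tabular_dataset <- function(features, labels, attributes = list(),
                            feature_names = NULL,
                            attribute_value_labels = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(labels) != n) stop("labels must have one entry per feature row")
  if (anyNA(features) || anyNA(labels)) stop("missing values are not allowed")
  if (min(labels) < 0L) stop("labels must be coded 0..K-1")
  K <- max(labels) + 1L
  if (K < 2L) stop("need at least 2 classes (K >= 2)")
  if (!is.list(attributes)) stop("attributes must be a named list")
  if (length(attributes) > 0 &&
      (is.null(names(attributes)) || any(names(attributes) == ""))) {
    stop("every attribute column must be named")
  }
  attributes <- lapply(attributes, function(a) {
    a <- as.integer(a)
    if (length(a) != n) stop("attribute columns must have n entries")
    if (anyNA(a)) stop("missing attribute values are not allowed")
    vals <- sort(unique(a))
    if (!identical(vals, seq(0L, max(a)))) {
      stop("attribute codes must be contiguous integers starting at 0")
    }
    a
  })
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- paste0("x", seq_len(ncol(features)))
    }
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels, attributes = attributes,
         n = n, d = ncol(features), n_classes = K,
         feature_names = feature_names,
         attribute_value_labels = attribute_value_labels),
    class = "tabular_dataset"
  )
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d rows, %d features, %d classes\n",
              x$n, x$d, x$n_classes))
  if (length(x$attributes)) {
    cat("attributes:",
        paste(sprintf("%s(%d)", names(x$attributes),
                      vapply(x$attributes, function(a) max(a) + 1L, 1L)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load a delimited table as a tabular dataset
#'
#' Reads a CSV/TSV file, label-encodes the label column and any categorical
#' attribute columns to contiguous 0-based integer codes, and returns a
#' [tabular_dataset()]. Feature columns must be numeric (one-hot encode
#' categorical features upstream, as is conventional for tabular clinical
#' extracts).
#'
#' @param path path to a delimited text file with a header row.
#' @param label_col name of the label column.
#' @param attribute_cols character vector of attribute column names (may be
#'   empty).
#' @param feature_cols character vector of feature column names; default all
#'   remaining columns.
#' @param sep field separator; `","` for CSV, `"\t"` for TSV.
#' @return A `tabular_dataset`.
#' @export
read_tabular_csv <- function(path, label_col, attribute_cols = character(),
                             feature_cols = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_col %in% names(df)) stop("unknown label column: ", label_col)
  missing_attr <- setdiff(attribute_cols, names(df))
  if (length(missing_attr)) {
    stop("unknown attribute column(s): ", paste(missing_attr, collapse = ", "))
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(df), c(label_col, attribute_cols))
  }
  encode <- function(x) {
    f <- factor(x)
    list(codes = as.integer(f) - 1L, levels = levels(f))
  }
  y <- encode(df[[label_col]])
  attrs <- lapply(df[attribute_cols], function(col) encode(col))
  names(attrs) <- attribute_cols
  X <- as.matrix(df[feature_cols])
  if (!is.numeric(X)) stop("feature columns must all be numeric")
  tabular_dataset(
    features = X,
    labels = y$codes,
    attributes = lapply(attrs, `[[`, "codes"),
    feature_names = feature_cols,
    attribute_value_labels = c(
      stats::setNames(list(y$levels), label_col),
      lapply(attrs, `[[`, "levels")
    )
  )
}
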