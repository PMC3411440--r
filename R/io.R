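#' Read a numeric feature matrix from delimited text or ARFF
#'
#' Reads CSV/TSV (delimiter sniffed from the first line unless forced) or,
#' for `.arff` files, the Weka ARFF dialect via \pkg{foreign}. A header
#' row is detected automatically. A class-label column can be stripped on
#' load by name or index.
#'
#' @param path Input file.
#' @param sep Field delimiter; `NULL` sniffs `\t` vs `,` vs whitespace.
#' @param label_col Column name or index to strip (e.g. `"label"` or the
#'   class attribute of a labelled benchmark); `NULL` keeps all columns.
#' @param drop_nonnumeric Silently drop remaining non-numeric columns
#'   instead of erroring.
#' @param drop_na_rows Drop rows containing missing values instead of
#'   erroring.
#' @return A numeric matrix; stripped labels, if any, are attached as
#'   attribute `"labels"`.
#' @export
read_data_matrix <- function(path, sep = NULL, label_col = NULL,
                             drop_nonnumeric = FALSE, drop_na_rows = FALSE) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  if (grepl("\\.arff$", path, ignore.case = TRUE)) {
    if (!requireNamespace("foreign", quietly = TRUE))
      stopf("reading ARFF requires the 'foreign' package")
    df <- foreign::read.arff(path)
  } else {
    first <- readLines(path, n = 1)
    if (is.null(sep))
      sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
    fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(fields))))
    df <- utils::read.table(path, sep = sep, header = header,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  labels <- NULL
  if (!is.null(label_col)) {
    idx <- if (is.character(label_col)) match(label_col, names(df)) else
      as.integer(label_col)
    if (is.na(idx) || idx < 1 || idx > ncol(df))
      stopf("label column '%s' not found", label_col)
    labels <- df[[idx]]
    df <- df[, -idx, drop = FALSE]
  }
  numeric_cols <- vapply(df, is.numeric, logical(1))
  if (!all(numeric_cols)) {
    if (!drop_nonnumeric)
      stopf("non-numeric columns: %s (set drop_nonnumeric = TRUE or name a label_col)",
            paste(names(df)[!numeric_cols], collapse = ", "))
    df <- df[, numeric_cols, drop = FALSE]
  }
  x <- as.matrix(df)
  if (anyNA(x)) {
    if (!drop_na_rows) stopf("input contains missing values (set drop_na_rows = TRUE to drop them)")
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[keep]
  }
  if (!is.null(labels)) attr(x, "labels") <- labels
  x
}

#' Read a criterion weight file
#'
#' Auto-detects the two supported layouts: a single row of
#' already-normalized weights (all entries in `[0, 1]`, summing to about
#' 1) or an experts x criteria block of importance scores on the 0-10
#' scale, which is averaged and normalized via
#' [normalize_expert_weights()].
#'
#' @param path Delimited text file (comma, tab or whitespace separated).
#' @param n_criteria Expected number of criteria (default 10).
#' @return A `weight_vector`.
#' @export
read_weight_file <- function(path, n_criteria = length(criterion_directions)) {
  if (!file.exists(path)) stopf("weight file not found: %s", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  header <- any(is.na(suppressWarnings(as.numeric(
    strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]))))
  m <- as.matrix(utils::read.table(path, sep = sep, header = header))
  if (ncol(m) != n_criteria)
    stopf("weight file has %d columns; expected %d (one per criterion)",
          ncol(m), n_criteria)
  if (nrow(m) == 1 && all(m >= 0 & m <= 1) && abs(sum(m) - 1) < 1e-6)
    as_weight_vector(drop(m))
  else
    normalize_expert_weights(m)
}
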