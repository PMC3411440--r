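#' Count correct cluster-number determinations across datasets
#'
#' Given per-dataset estimates of the number of clusters from several
#' methods or indices, counts for each column how many datasets were
#' estimated correctly. A tied estimate (several k values with identical
#' index values, written `"9/10"`) counts as correct when the true count
#' is in the tied set.
#'
#' @param estimates Data frame or matrix, one row per dataset and one
#'   column per method/index; entries are integers, integer vectors in a
#'   list column, or strings like `"9/10"` for tied sets.
#' @param truth Integer vector of true class counts, aligned with the
#'   rows of `estimates`.
#' @return A named integer vector of correct counts, one per column.
#' @examples
#' est <- data.frame(dunn = c("2", "9/10"), sil = c("2", "2"))
#' summarize_correct(est, truth = c(2, 10))  # dunn 2, sil 1
#' @export
summarize_correct <- function(estimates, truth) {
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) != length(truth))
    stopf("estimates has %d rows but truth has %d entries",
          nrow(estimates), length(truth))
  truth <- as.integer(truth)
  vapply(estimates, function(col) {
    sets <- parse_estimate_sets(col)
    sum(mapply(function(set, tr) tr %in% set, sets, truth))
  }, numeric(1)) |> as.integer() |> stats::setNames(names(estimates))
}

parse_estimate_sets <- function(col) {
  if (is.list(col)) return(lapply(col, as.integer))
  lapply(as.character(col), function(s) {
    v <- suppressWarnings(as.integer(strsplit(s, "/", fixed = TRUE)[[1]]))
    if (anyNA(v)) stopf("unparseable estimate entry: '%s'", s)
    v
  })
}

#' Published benchmark estimates bundled with the package
#'
#' Reported results from a published comparative evaluation of this
#' estimator on fifteen UCI benchmark datasets: the best k chosen by each
#' of the ten validity indices alone (`"indices"`), the best k chosen by
#' each of the three MCDM methods (`"mcdm"`), and the full value/order
#' ranking table for the yeast dataset (`"yeast"`). Tied index estimates
#' appear as `"9/10"`. Both estimate tables carry the true class count in
#' column `n_classes`. These tables exercise the reporting logic
#' ([summarize_correct()], [flag_close_ties()]) without re-running the
#' fifteen external datasets.
#'
#' @param which One of `"indices"`, `"mcdm"`, `"yeast"`.
#' @return A data frame.
#' @export
benchmark_estimates <- function(which = c("indices", "mcdm", "yeast")) {
  which <- match.arg(which)
  file <- c(indices = "benchmark_index_estimates.tsv",
            mcdm = "benchmark_mcdm_estimates.tsv",
            yeast = "benchmark_yeast_rankings.tsv")[which]
  path <- system.file("extdata", file, package = "mcdmk")
  if (path == "") stopf("bundled table '%s' not found", file)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character") |>
    utils::type.convert(as.is = TRUE)
}
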