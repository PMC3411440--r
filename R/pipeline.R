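#' Estimate the number of clusters by multi-criteria ranking
#'
#' End-to-end pipeline: sweep k-means over the candidate range, score
#' every solution with the ten relative validity indices, and rank the
#' candidate k values with WSM, PROMETHEE II and TOPSIS under a shared
#' weight vector. Each method's recommended k is its rank-1 alternative;
#' near-tied top ranks are flagged so the scores accompany the order.
#'
#' @param x Numeric matrix (rows = objects), `mixture_data`, or a file
#'   path accepted by [read_data_matrix()].
#' @param k_range Candidate cluster counts, default 2:10 (must stay below
#'   the number of objects).
#' @param weights Criterion weights: a `weight_vector`, a numeric vector,
#'   an experts x criteria 0-10 score matrix, or a file path for
#'   [read_weight_file()]; uniform when `NULL`.
#' @param methods Subset of `c("wsm", "promethee2", "topsis")`.
#' @param restarts,seed,max_iter,tol,init,standardize,partitions Passed to
#'   [criteria_matrix()].
#' @param scale_criteria WSM scaling mode, `"minmax"` or `"raw"`.
#' @param tie_threshold Close-tie score gap (default 0.01).
#' @param dataset_id Free-text identifier recorded in the report.
#' @return An object of class `k_estimate`: the decision matrix
#'   (`criteria`), `best_k_per_index`, the per-method `rankings`,
#'   `recommended` (named vector, rank-1 k per method), and the resolved
#'   run `config`.
#' @examples
#' d <- generate_mixture(mixture_spec(4, 50, 2, center_separation = 10,
#'                                    sigma = 1, seed = 3))
#' est <- estimate_k(d, k_range = 2:8, seed = 3)
#' est$recommended
#' @export
estimate_k <- function(x, k_range = 2:10, weights = NULL,
                       methods = c("wsm", "promethee2", "topsis"),
                       restarts = 10L, seed = 0L, max_iter = 100L,
                       tol = 1e-6, init = "random", standardize = FALSE,
                       scale_criteria = c("minmax", "raw"),
                       tie_threshold = 0.01, partitions = NULL,
                       dataset_id = "dataset") {
  scale_criteria <- match.arg(scale_criteria)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.character(x) && length(x) == 1) x <- read_data_matrix(x)
  if (is.character(weights) && length(weights) == 1)
    weights <- read_weight_file(weights)
  if (is.matrix(weights) || is.data.frame(weights))
    weights <- normalize_expert_weights(weights)

  cm <- criteria_matrix(x, k_range = k_range, restarts = restarts,
                        seed = seed, max_iter = max_iter, tol = tol,
                        init = init, standardize = standardize,
                        partitions = partitions)
  w <- check_weights(cm, weights)

  rankers <- list(
    wsm = function() wsm_rank(cm, w, scale = scale_criteria,
                              tie_threshold = tie_threshold),
    promethee2 = function() promethee2_rank(cm, w,
                                            tie_threshold = tie_threshold),
    topsis = function() topsis_rank(cm, w, tie_threshold = tie_threshold)
  )
  rankings <- lapply(rankers[methods], function(f) f())

  structure(
    list(dataset_id = dataset_id,
         k_range = cm$alternatives,
         criteria = cm,
         best_k_per_index = best_k_per_index(cm),
         rankings = rankings,
         recommended = vapply(rankings, `[[`, integer(1), "best"),
         config = list(seed = as.integer(seed),
                       restarts = as.integer(restarts),
                       max_iter = as.integer(max_iter), tol = tol,
                       init = init, standardize = standardize,
                       scale_criteria = scale_criteria,
                       tie_threshold = tie_threshold,
                       weights = as.numeric(w),
                       injected_partitions = !is.null(partitions))),
    class = "k_estimate"
  )
}

#' @export
print.k_estimate <- function(x, ...) {
  cat(sprintf("Cluster-number estimate for '%s' (k = %s)\n", x$dataset_id,
              paste(range(x$k_range), collapse = "..")))
  cat("Recommended k per method:\n")
  for (m in names(x$rankings)) {
    r <- x$rankings[[m]]
    tie <- if (nrow(r$ties)) sprintf("  [close ties: %s]",
      paste(sprintf("k=%d~k=%d gap %.4g", r$ties$k_a, r$ties$k_b,
                    r$ties$gap), collapse = "; ")) else ""
    cat(sprintf("  %-11s k = %d (score %.6g)%s\n", m, r$best,
                r$scores[match(r$best, r$alternatives)], tie))
  }
  cat("Best k per validity index:\n")
  for (nm in names(x$best_k_per_index))
    cat(sprintf("  %-11s %s\n", nm,
                paste(x$best_k_per_index[[nm]], collapse = "/")))
  invisible(x)
}

#' Serialize and restore an estimation report
#'
#' `write_report()` writes a `k_estimate` as JSON (full double precision,
#' so reports round-trip exactly) or as a flat TSV of the per-method
#' rankings (`method`, `k`, `score`, `rank`, `tie_flag`, mirroring a
#' value/order table). `read_report()` restores a JSON report to an
#' identical `k_estimate`.
#'
#' @param est A `k_estimate`.
#' @param path Output file.
#' @param format `"json"` (lossless) or `"tsv"` (rankings only).
#' @return `write_report()`: `path` invisibly; `read_report()`: a
#'   `k_estimate`; `report_json()`: the JSON string.
#' @export
write_report <- function(est, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    writeLines(report_json(est), path)
  } else {
    utils::write.table(rankings_table(est), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
report_json <- function(est) {
  stopifnot(inherits(est, "k_estimate"))
  stripped <- unclass(est)
  stripped$criteria <- unclass(stripped$criteria)
  stripped$criteria$solutions <- lapply(est$criteria$solutions, function(s)
    s[c("labels", "centers", "k", "wcss", "n_iter", "seed", "restart_used")])
  # named object: keeps the per-k solutions from being collapsed on reload
  names(stripped$criteria$solutions) <-
    paste0("k=", est$criteria$alternatives)
  stripped$rankings <- lapply(stripped$rankings, unclass)
  jsonlite::toJSON(stripped, digits = NA, auto_unbox = TRUE,
                   pretty = TRUE, na = "null")
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  crit <- obj$criteria
  for (f in c("values", "raw")) crit[[f]] <- as_matrix_named(crit[[f]], crit)
  crit$degenerate <- matrix(as.logical(crit$degenerate),
                            length(crit$alternatives),
                            length(crit$criteria),
                            dimnames = dimnames(crit$values))
  crit$alternatives <- as.integer(crit$alternatives)
  crit$directions <- unlist(crit$directions)
  crit$solutions <- unname(lapply(crit$solutions, function(s) {
    s$labels <- as.integer(s$labels)
    s$centers <- matrix(unlist(s$centers), nrow = s$k)
    s$k <- as.integer(s$k)
    s$n_iter <- as.integer(s$n_iter)
    s$seed <- as.integer(s$seed)
    s$restart_used <- as.integer(s$restart_used)
    s$wcss_trace <- numeric(0)
    structure(s[c("labels", "centers", "k", "wcss", "wcss_trace", "n_iter",
                  "seed", "restart_used")], class = "kmeans_solution")
  }))
  obj$criteria <- structure(crit[c("values", "raw", "degenerate",
                                   "alternatives", "criteria", "directions",
                                   "solutions", "wcss")],
                            class = "criteria_matrix")
  obj$k_range <- as.integer(obj$k_range)
  obj$best_k_per_index <- lapply(obj$best_k_per_index, as.integer)
  obj$rankings <- lapply(obj$rankings, function(r) {
    r$alternatives <- as.integer(r$alternatives)
    r$order <- as.integer(r$order)
    r$rank <- as.integer(r$rank)
    r$best <- as.integer(r$best)
    r$ties <- as.data.frame(r$ties)
    if (!nrow(r$ties))
      r$ties <- data.frame(k_a = integer(), k_b = integer(),
                           score_a = numeric(), score_b = numeric(),
                           gap = numeric())
    else {
      r$ties$k_a <- as.integer(r$ties$k_a)
      r$ties$k_b <- as.integer(r$ties$k_b)
    }
    structure(r, class = "ranking_result")
  })
  obj$recommended <- vapply(obj$rankings, `[[`, integer(1), "best")
  cfg <- obj$config
  for (f in c("seed", "restarts", "max_iter")) cfg[[f]] <- as.integer(cfg[[f]])
  obj$config <- cfg
  structure(obj[c("dataset_id", "k_range", "criteria", "best_k_per_index",
                  "rankings", "recommended", "config")],
            class = "k_estimate")
}

as_matrix_named <- function(m, crit) {
  m <- matrix(unlist(m), length(crit$alternatives), length(crit$criteria))
  dimnames(m) <- list(paste0("k=", crit$alternatives), unlist(crit$criteria))
  m
}

#' Per-method ranking table
#'
#' Flattens a `k_estimate` into a long data frame with columns `method`,
#' `k`, `score`, `rank` and `tie_flag` (TRUE for alternatives involved in
#' a flagged close tie among the top three).
#'
#' @param est A `k_estimate`.
#' @return A data frame.
#' @export
rankings_table <- function(est) {
  stopifnot(inherits(est, "k_estimate"))
  do.call(rbind, lapply(est$rankings, function(r) {
    tied_k <- unique(c(r$ties$k_a, r$ties$k_b))
    data.frame(method = r$method, k = r$alternatives, score = r$scores,
               rank = r$rank, tie_flag = r$alternatives %in% tied_k,
               row.names = NULL)
  }))
}
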