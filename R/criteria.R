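#' Build the decision matrix over a sweep of candidate cluster counts
#'
#' Runs [kmeans_fit()] (best of `restarts`) for each candidate k, scores
#' every solution with the ten validity indices, and assembles the
#' alternatives x criteria decision matrix used by the MCDM rankers.
#'
#' Degenerate index evaluations (non-finite values from divisions by zero)
#' are replaced, per criterion, by the worst finite value observed across
#' the sweep plus a 10% sentinel margin in the unfavourable direction, and
#' flagged in the `degenerate` component; this keeps the matrix finite
#' without rewarding degenerate partitions. A criterion degenerate at
#' every k aborts with a diagnostic naming it. The SD index's balancing
#' weight is `Dis` of the largest-k solution, making SD sweep-dependent by
#' construction.
#'
#' @param x Numeric matrix (rows = objects) or a `mixture_data` object.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param restarts,seed,max_iter,tol,init Passed to [kmeans_fit()]; the
#'   same seed stream is used for every k.
#' @param standardize Z-score the columns of `x` before clustering.
#' @param partitions Optional list of precomputed label vectors, one per
#'   entry of `k_range`, which bypasses k-means (injected-partition mode).
#' @return An object of class `criteria_matrix`: `values` (finite
#'   decision matrix, rows = k, columns = criteria in canonical order),
#'   `raw` (pre-resolution values), `degenerate` (logical matrix),
#'   `alternatives`, `criteria`, `directions`, `solutions` (the per-k
#'   clustering solutions), `wcss` (per-k WCSS).
#' @examples
#' d <- generate_mixture(mixture_spec(3, 30, 2, 10, 0.5, seed = 1))
#' cm <- criteria_matrix(d, k_range = 2:5, restarts = 5, seed = 1)
#' best_k_per_index(cm)
#' @export
criteria_matrix <- function(x, k_range = 2:10, restarts = 10L, seed = 0L,
                            max_iter = 100L, tol = 1e-6, init = "random",
                            standardize = FALSE, partitions = NULL) {
  if (inherits(x, "mixture_data")) x <- x$x
  x <- as.matrix(x)
  if (length(k_range) < 1) stopf("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(x) - 1)
    stopf(paste("k_range max (%d) must be below n (%d);",
                "choose a smaller k_max"), max(k_range), nrow(x))
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- scale(x, scale = sds)[, , drop = FALSE]
  }
  if (!is.null(partitions) && length(partitions) != length(k_range))
    stopf("partitions must have one label vector per k in k_range")

  sols <- lapply(seq_along(k_range), function(i) {
    if (is.null(partitions))
      kmeans_fit(x, k_range[i], seed = seed, restarts = restarts,
                 max_iter = max_iter, tol = tol, init = init)
    else as_solution(x, partitions[[i]])
  })
  P <- as.matrix(stats::dist(x))
  alpha <- dis_of(sols[[length(sols)]]$centers)

  crit <- names(criterion_directions)
  raw <- matrix(NA_real_, length(k_range), length(crit),
                dimnames = list(paste0("k=", k_range), crit))
  for (i in seq_along(k_range)) {
    s <- sols[[i]]
    raw[i, ] <- c(
      dunn        = dunn_index(x, s, P),
      silhouette  = as.numeric(silhouette_index(x, s, P)),
      pbm         = pbm_index(x, s, P),
      hubert      = hubert_gamma(x, s, P),
      norm_hubert = normalized_hubert(x, s, P),
      db          = davies_bouldin(x, s, P),
      sd          = sd_index(x, s, P, alpha = alpha),
      s_dbw       = s_dbw(x, s, P),
      cs          = cs_measure(x, s, P),
      c_index     = c_index(x, s, P)
    )
  }

  degenerate <- !is.finite(raw)
  values <- raw
  for (j in seq_along(crit)) {
    bad <- degenerate[, j]
    if (!any(bad)) next
    if (all(bad))
      stopf("criterion '%s' is degenerate for every k in the sweep", crit[j])
    fin <- raw[!bad, j]
    margin <- 0.1 * diff(range(fin))
    if (margin == 0) margin <- 1
    values[bad, j] <- if (criterion_directions[j] == "benefit")
      min(fin) - margin else max(fin) + margin
  }

  structure(
    list(values = values, raw = raw, degenerate = degenerate,
         alternatives = k_range, criteria = crit,
         directions = criterion_directions,
         solutions = sols,
         wcss = vapply(sols, `[[`, numeric(1), "wcss")),
    class = "criteria_matrix"
  )
}

#' @export
print.criteria_matrix <- function(x, ...) {
  cat(sprintf("Decision matrix: %d alternatives (k = %s) x %d criteria\n",
              length(x$alternatives),
              paste(range(x$alternatives), collapse = ".."),
              length(x$criteria)))
  print(round(x$values, 4))
  if (any(x$degenerate))
    cat("Degenerate entries (resolved to worst-of-sweep):",
        sum(x$degenerate), "\n")
  invisible(x)
}

#' Best k according to each validity index alone
#'
#' The argmax over alternatives for benefit criteria and argmin for cost
#' criteria, computed on the raw (pre-resolution) index values so that an
#' infinite Dunn value counts as best. Ties are reported as the full tied
#' set.
#'
#' @param cm A [criteria_matrix()].
#' @param tol Absolute tolerance within which values count as tied.
#' @return A named list, one integer vector of k values per criterion
#'   (length > 1 on ties).
#' @export
best_k_per_index <- function(cm, tol = 0) {
  stopifnot(inherits(cm, "criteria_matrix"))
  out <- lapply(seq_along(cm$criteria), function(j) {
    v <- cm$raw[, j]
    v[is.nan(v)] <- if (cm$directions[j] == "benefit") -Inf else Inf
    opt <- if (cm$directions[j] == "benefit") max(v) else min(v)
    cm$alternatives[abs(v - opt) <= tol | v == opt]
  })
  names(out) <- cm$criteria
  out
}

#' Write or read a decision matrix as TSV
#'
#' The TSV (alternatives as rows under a `k` column, criteria as labelled
#' columns) is the auditable intermediate of the pipeline.
#'
#' @param cm A [criteria_matrix()].
#' @param path File path.
#' @return `write_criteria_tsv()` returns `path` invisibly;
#'   `read_criteria_tsv()` returns a `criteria_matrix` (without clustering
#'   solutions).
#' @export
write_criteria_tsv <- function(cm, path) {
  df <- data.frame(k = cm$alternatives, cm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_criteria_tsv
#' @export
read_criteria_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  crit <- names(criterion_directions)
  missing <- setdiff(crit, names(df))
  if (length(missing))
    stopf("criteria TSV lacks columns: %s", paste(missing, collapse = ", "))
  vals <- as.matrix(df[, crit])
  rownames(vals) <- paste0("k=", df$k)
  structure(
    list(values = vals, raw = vals,
         degenerate = matrix(FALSE, nrow(vals), ncol(vals)),
         alternatives = as.integer(df$k), criteria = crit,
         directions = criterion_directions, solutions = NULL,
         wcss = NULL),
    class = "criteria_matrix"
  )
}
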