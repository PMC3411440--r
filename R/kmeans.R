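#' Lloyd k-means with restarts
#'
#' Minimizes the within-cluster sum of squared errors (WCSS) by alternating
#' nearest-center assignment and mean updates. Initial centers are k
#' distinct rows chosen uniformly at random (k-means++ seeding is available
#' via `init`). With `restarts > 1` the run with the smallest WCSS is kept.
#' A cluster that empties during iteration is reseeded with the point
#' farthest from its currently assigned center, so the solution always has
#' exactly k non-empty clusters.
#'
#' @param x Numeric matrix (rows = objects) or a `mixture_data` object.
#' @param k Number of clusters, 1 <= k <= nrow(x).
#' @param seed Integer seed; results are deterministic in
#'   `(x, k, seed, restarts)`. Restart r uses seed `seed + r - 1`.
#' @param restarts Number of random restarts (>= 1).
#' @param max_iter Iteration cap per restart.
#' @param tol Convergence threshold on the largest centroid displacement.
#' @param init `"random"` (uniform choice of k distinct rows) or
#'   `"plusplus"` (k-means++ seeding).
#' @return An object of class `kmeans_solution`: `labels` (1..k per
#'   object), `centers` (k x d), `k`, `wcss`, `wcss_trace` (per-iteration
#'   WCSS of the winning restart, non-increasing), `n_iter`, `seed`,
#'   `restart_used`.
#' @examples
#' fx <- fixture_two_clusters_1d()
#' kmeans_fit(fx$x, 2, seed = 1, restarts = 5)$wcss  # 1.0, global optimum
#' @export
kmeans_fit <- function(x, k, seed = 0L, restarts = 1L, max_iter = 100L,
                       tol = 1e-6, init = c("random", "plusplus")) {
  if (inherits(x, "mixture_data")) x <- x$x
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  init <- match.arg(init)
  n <- nrow(x)
  if (anyNA(x)) stopf("x contains missing values")
  if (k < 1 || k > n) stopf("k must satisfy 1 <= k <= n (n = %d), got %s", n, k)
  if (restarts < 1) stopf("restarts must be >= 1")

  best <- NULL
  for (r in seq_len(restarts)) {
    sol <- local_seed(seed + r - 1L, lloyd_once(x, k, max_iter, tol, init))
    if (is.null(best) || sol$wcss < best$wcss - 1e-12) {
      best <- sol
      best$restart_used <- r
    }
  }
  best$seed <- as.integer(seed)
  structure(best, class = "kmeans_solution")
}

# One Lloyd run from a random initialization; assumes RNG already seeded.
lloyd_once <- function(x, k, max_iter, tol, init) {
  n <- nrow(x)
  centers <- if (init == "plusplus") init_plusplus(x, k) else
    x[sample.int(n, k), , drop = FALSE]
  labels <- integer(n)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- rowwise_sqdist(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    # farthest-point reseeding keeps all k clusters populated
    for (empty in setdiff(seq_len(k), unique(labels))) {
      assigned <- d2[cbind(seq_len(n), labels)]
      movable <- which(tabulate(labels, k)[labels] > 1L)
      far <- movable[which.max(assigned[movable])]
      labels[far] <- empty
    }
    new_centers <- update_means(x, labels, k)
    trace <- c(trace, wcss_of(x, labels, new_centers))
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol || iter >= max_iter) break
  }
  list(labels = labels, centers = centers, k = as.integer(k),
       wcss = trace[length(trace)], wcss_trace = trace, n_iter = iter)
}

init_plusplus <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- rowwise_sqdist(x, x[idx, , drop = FALSE])
    mind2 <- apply(d2, 1, min)
    mind2[idx] <- 0
    idx <- c(idx, if (sum(mind2) > 0) sample.int(n, 1, prob = mind2) else
      sample(setdiff(seq_len(n), idx), 1))
  }
  x[idx, , drop = FALSE]
}

update_means <- function(x, labels, k) {
  m <- matrix(0, k, ncol(x))
  for (i in seq_len(k)) {
    m[i, ] <- colMeans(x[labels == i, , drop = FALSE])
  }
  m
}

wcss_of <- function(x, labels, centers) {
  sum((x - centers[labels, , drop = FALSE])^2)
}

#' @export
print.kmeans_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, n = %d, WCSS = %.6g (%d iterations, restart %d)\n",
              x$k, length(x$labels), x$wcss, x$n_iter, x$restart_used))
  invisible(x)
}

# Coerce external labellings (injected partitions) to a kmeans_solution so
# the validity indices can score any partition, not just k-means output.
as_solution <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(as.factor(labels))
  k <- max(labels)
  if (!all(seq_len(k) %in% labels)) stopf("labels must use every cluster id")
  centers <- update_means(x, labels, k)
  structure(list(labels = labels, centers = centers, k = k,
                 wcss = wcss_of(x, labels, centers),
                 wcss_trace = numeric(0), n_iter = 0L, seed = NA_integer_,
                 restart_used = NA_integer_),
            class = "kmeans_solution")
}
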