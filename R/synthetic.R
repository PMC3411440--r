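#' Specify a labelled Gaussian-mixture benchmark dataset
#'
#' Describes an isotropic Gaussian mixture with a guaranteed minimum
#' pairwise distance between component centers, used to generate data with
#' a known number of clusters for benchmarking the estimator.
#'
#' @param n_clusters Number of mixture components (>= 1).
#' @param points_per_cluster Points drawn per component; a single count or
#'   a vector of length `n_clusters`.
#' @param dim Dimensionality of the feature space (>= 1).
#' @param center_separation Minimum pairwise Euclidean distance between
#'   component centers, in feature units.
#' @param sigma Isotropic within-component standard deviation (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An object of class `mixture_spec`.
#' @seealso [generate_mixture()]
#' @export
mixture_spec <- function(n_clusters, points_per_cluster, dim,
                         center_separation, sigma, seed = 0L) {
  if (n_clusters < 1) stopf("n_clusters must be >= 1, got %s", n_clusters)
  if (dim < 1) stopf("dim must be >= 1, got %s", dim)
  if (sigma < 0) stopf("sigma must be >= 0, got %s", sigma)
  if (!is.finite(center_separation) || center_separation < 0)
    stopf("center_separation must be finite and >= 0")
  if (length(points_per_cluster) == 1)
    points_per_cluster <- rep(points_per_cluster, n_clusters)
  if (length(points_per_cluster) != n_clusters)
    stopf("points_per_cluster must have length 1 or n_clusters")
  if (any(points_per_cluster < 1))
    stopf("every points_per_cluster must be >= 1")
  structure(
    list(n_clusters = as.integer(n_clusters),
         points_per_cluster = as.integer(points_per_cluster),
         dim = as.integer(dim),
         center_separation = as.numeric(center_separation),
         sigma = as.numeric(sigma),
         seed = as.integer(seed)),
    class = "mixture_spec"
  )
}

# Centers on an axis-aligned grid with spacing wide enough that the added
# jitter cannot violate the pairwise-separation guarantee.
place_centers <- function(n_clusters, dim, separation) {
  jitter_amp <- 0.05 * separation / sqrt(dim)
  spacing <- separation + 2 * jitter_amp * sqrt(dim) + 1e-9
  if (n_clusters == 1) {
    centers <- matrix(0, 1, dim)
  } else {
    per_axis <- ceiling(n_clusters^(1 / dim))
    grid <- as.matrix(expand.grid(rep(list(seq_len(per_axis) - 1), dim)))
    centers <- grid[seq_len(n_clusters), , drop = FALSE] * spacing
  }
  centers + matrix(stats::runif(n_clusters * dim, -jitter_amp, jitter_amp),
                   n_clusters, dim)
}

#' Generate a labelled Gaussian-mixture dataset
#'
#' Draws points from the mixture described by a [mixture_spec()]. Component
#' centers are placed on a scaled grid and jittered, so the pairwise
#' center separation is guaranteed deterministically.
#'
#' @param spec A [mixture_spec()].
#' @return A list of class `mixture_data` with components `x` (numeric
#'   matrix, one row per point), `labels` (integer generating component,
#'   1-based), `centers` (true component centers) and `spec`.
#' @examples
#' d <- generate_mixture(mixture_spec(3, 50, dim = 2,
#'                                    center_separation = 10, sigma = 1,
#'                                    seed = 7))
#' table(d$labels)
#' @export
generate_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  local_seed(spec$seed, {
    centers <- place_centers(spec$n_clusters, spec$dim,
                             spec$center_separation)
    n <- sum(spec$points_per_cluster)
    labels <- rep(seq_len(spec$n_clusters), spec$points_per_cluster)
    x <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$dim, sd = spec$sigma), n, spec$dim)
    colnames(x) <- paste0("V", seq_len(spec$dim))
    structure(list(x = x, labels = labels, centers = centers, spec = spec),
              class = "mixture_data")
  })
}

#' Four-point one-dimensional worked-example dataset
#'
#' The fixture \{0, 1, 10, 11\} with two planted clusters \{0, 1\} and
#' \{10, 11\}, small enough that every validity index can be verified by
#' hand (within-cluster distances \{1, 1\}; between-cluster distances
#' \{9, 10, 10, 11\}).
#'
#' @return A `mixture_data` list with a 4 x 1 matrix `x` and `labels`
#'   `c(1, 1, 2, 2)` (named "A", "A", "B", "B").
#' @export
fixture_two_clusters_1d <- function() {
  x <- matrix(c(0, 1, 10, 11), ncol = 1, dimnames = list(NULL, "V1"))
  labels <- structure(c(1L, 1L, 2L, 2L), names = c("A", "A", "B", "B"))
  structure(list(x = x, labels = labels,
                 centers = matrix(c(0.5, 10.5), ncol = 1), spec = NULL),
            class = "mixture_data")
}

#' Write a generated dataset to CSV
#'
#' Writes the feature columns plus, optionally, a final `label` column, in
#' a form [read_data_matrix()] can round-trip.
#'
#' @param data A `mixture_data` object (or any list with `x` and `labels`).
#' @param path Output file path.
#' @param include_labels Append the generating labels as a `label` column.
#' @return `path`, invisibly.
#' @export
write_mixture_csv <- function(data, path, include_labels = TRUE) {
  df <- as.data.frame(data$x)
  if (include_labels) df$label <- as.integer(data$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
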