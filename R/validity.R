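#' @name validity-indices
#' @title Relative cluster validity indices
#'
#' @description
#' Ten relative validity indices, each a pure function of the data and a
#' partition. All use Euclidean distance. Every function accepts either a
#' [kmeans_fit()] solution or a plain label vector in `sol`, so partitions
#' from any clustering algorithm can be scored.
#'
#' Degenerate evaluations (division by zero, e.g. coincident centroids or
#' zero-diameter clusters) return `NaN` — or `Inf` for the Dunn index when
#' every cluster is a point multiset, since that is the index's own limit —
#' and are resolved by the sweep-level policy in [criteria_matrix()].
#'
#' @param x Numeric matrix, rows = objects; or a `mixture_data` object.
#' @param sol A `kmeans_solution` or an integer/factor label vector.
#' @param P Optional precomputed proximity matrix (`as.matrix(dist(x))`);
#'   pass it when scoring many partitions of the same data.
#' @return A single numeric index value.
NULL

# Normalize (x, sol, P) into one evaluation context shared by all indices.
validity_ctx <- function(x, sol, P = NULL) {
  if (inherits(x, "mixture_data")) x <- x$x
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!inherits(sol, "kmeans_solution")) sol <- as_solution(x, sol)
  if (is.null(P)) P <- as.matrix(stats::dist(x))
  list(x = x, labels = sol$labels, centers = sol$centers, k = sol$k, P = P,
       n = nrow(x))
}

upper_pairs <- function(M) M[upper.tri(M)]

#' @rdname validity-indices
#' @details `hubert_gamma()`: the (unnormalized) Hubert Gamma statistic,
#' `(1/M) * sum_{i<j} P(i,j) * Q(i,j)` over the `M = n(n-1)/2` object
#' pairs, where `P` is the proximity matrix and `Q(i,j)` is the distance
#' between the centroids of the clusters containing objects i and j (zero
#' for co-clustered pairs). Measures the agreement between the proximity
#' structure and the partition.
#' @export
hubert_gamma <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$n < 2) stopf("hubert_gamma needs n >= 2")
  Q <- as.matrix(stats::dist(ctx$centers))[ctx$labels, ctx$labels]
  mean(upper_pairs(ctx$P) * upper_pairs(Q))
}

#' @rdname validity-indices
#' @details `normalized_hubert()`: the Pearson-normalized Gamma,
#' `[(1/M) sum P*Q - mu_P mu_Q] / (sigma_P sigma_Q)` over pairs, in
#' `[-1, 1]`. `NaN` when either pair vector is constant (e.g. k = 1).
#' @export
normalized_hubert <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$n < 2) stopf("normalized_hubert needs n >= 2")
  Q <- as.matrix(stats::dist(ctx$centers))[ctx$labels, ctx$labels]
  p <- upper_pairs(ctx$P)
  q <- upper_pairs(Q)
  sp <- sqrt(mean(p^2) - mean(p)^2)
  sq <- sqrt(mean(q^2) - mean(q)^2)
  if (sp == 0 || sq == 0) return(NaN)
  (mean(p * q) - mean(p) * mean(q)) / (sp * sq)
}

#' @rdname validity-indices
#' @details `dunn_index()`: minimum between-cluster distance (closest
#' member pair) divided by the maximum cluster diameter; values above 1
#' indicate compact, well-separated clusters. Benefit criterion.
#' @export
dunn_index <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$k < 2) stopf("dunn_index needs k >= 2")
  same <- upper_pairs(outer(ctx$labels, ctx$labels, "=="))
  p <- upper_pairs(ctx$P)
  max_diam <- if (any(same)) max(p[same]) else 0
  min_sep <- min(p[!same])
  if (max_diam == 0) return(Inf)
  min_sep / max_diam
}

#' @rdname validity-indices
#' @details `davies_bouldin()`: mean over clusters of the worst-case
#' similarity `R_ij = (s_i + s_j) / d(m_i, m_j)`, where `s_i` is the mean
#' member-to-centroid distance. Cost criterion; `NaN` on coincident
#' centroids.
#' @export
davies_bouldin <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$k < 2) stopf("davies_bouldin needs k >= 2")
  s <- vapply(seq_len(ctx$k), function(i) {
    members <- ctx$x[ctx$labels == i, , drop = FALSE]
    mean(sqrt(rowSums((members - matrix(ctx$centers[i, ], nrow(members),
                                        ncol(members), byrow = TRUE))^2)))
  }, numeric(1))
  dcent <- as.matrix(stats::dist(ctx$centers))
  if (any(dcent[upper.tri(dcent)] == 0)) return(NaN)
  R <- outer(s, s, "+") / dcent
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' @rdname validity-indices
#' @details `cs_measure()`: ratio of the average within-cluster
#' farthest-neighbour distance to the summed nearest-centroid separations
#' (Chou-Su-Lai). Cost criterion; `NaN` when all centroids coincide.
#' @export
cs_measure <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$k < 2) stopf("cs_measure needs k >= 2")
  num <- sum(vapply(seq_len(ctx$k), function(i) {
    idx <- which(ctx$labels == i)
    if (length(idx) == 1) return(0)
    mean(apply(ctx$P[idx, idx, drop = FALSE], 1, max))
  }, numeric(1)))
  dcent <- as.matrix(stats::dist(ctx$centers))
  diag(dcent) <- Inf
  den <- sum(apply(dcent, 1, min))
  if (den == 0) return(NaN)
  num / den
}

# Per-cluster variance-vector norms and the dataset variance norm
# (population variances, per the scattering definition).
scat_parts <- function(ctx) {
  pop_var <- function(m) colMeans(m^2) - colMeans(m)^2
  total <- sqrt(sum(pop_var(ctx$x)^2))
  per_cluster <- vapply(seq_len(ctx$k), function(i)
    sqrt(sum(pop_var(ctx$x[ctx$labels == i, , drop = FALSE])^2)),
    numeric(1))
  list(per_cluster = per_cluster, total = total)
}

scat_of <- function(ctx) {
  sp <- scat_parts(ctx)
  mean(sp$per_cluster) / sp$total
}

# Total-separation term of the SD index for one partition.
dis_of <- function(centers) {
  dcent <- as.matrix(stats::dist(centers))
  offdiag <- dcent[upper.tri(dcent)]
  if (min(offdiag) == 0) return(NaN)
  (max(offdiag) / min(offdiag)) * sum(1 / rowSums(dcent))
}

#' @rdname validity-indices
#' @details `sd_index()`: `alpha * Scat(k) + Dis(k)` (Halkidi-Vazirgiannis),
#' where `Scat` is the mean cluster variance-vector norm relative to the
#' dataset's and `Dis` weighs the spread of centroid distances. The
#' balancing weight `alpha` is `Dis` evaluated at the largest k of the
#' sweep; standalone calls default to `alpha = Dis(k)` of the given
#' solution. Cost criterion.
#' @param alpha Balancing weight for the scattering term of `sd_index()`;
#'   in a sweep, `Dis` of the largest-k solution (supplied by
#'   [criteria_matrix()]), default `Dis` of `sol` itself.
#' @export
sd_index <- function(x, sol, P = NULL, alpha = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$k < 2) stopf("sd_index needs k >= 2")
  dis <- dis_of(ctx$centers)
  if (is.null(alpha)) alpha <- dis
  alpha * scat_of(ctx) + dis
}

#' @rdname validity-indices
#' @details `s_dbw()`: `Scat(k) + Dens_bw(k)` (Halkidi-Vazirgiannis).
#' `Dens_bw` compares the point density in the neighbourhood of each
#' cluster-pair midpoint to the denser of the two cluster centers, where a
#' point is "near" `u` when `d(x, u) <= stdev`, with
#' `stdev = (1/k) * sqrt(sum_i ||sigma(C_i)||)`. Cost criterion; `NaN`
#' when both centers of some pair have empty neighbourhoods.
#' @export
s_dbw <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$k < 2) stopf("s_dbw needs k >= 2")
  sp <- scat_parts(ctx)
  stdev <- sqrt(sum(sp$per_cluster)) / ctx$k
  density_at <- function(u, members) {
    d <- sqrt(rowSums((members - matrix(u, nrow(members), ncol(members),
                                        byrow = TRUE))^2))
    sum(d <= stdev)
  }
  total <- 0
  for (i in seq_len(ctx$k - 1)) {
    for (j in seq(i + 1, ctx$k)) {
      members <- ctx$x[ctx$labels %in% c(i, j), , drop = FALSE]
      di <- density_at(ctx$centers[i, ], members)
      dj <- density_at(ctx$centers[j, ], members)
      if (max(di, dj) == 0) return(NaN)
      mid <- (ctx$centers[i, ] + ctx$centers[j, ]) / 2
      total <- total + density_at(mid, members) / max(di, dj)
    }
  }
  dens_bw <- 2 * total / (ctx$k * (ctx$k - 1))
  sp_scat <- mean(sp$per_cluster) / sp$total
  sp_scat + dens_bw
}

#' @rdname validity-indices
#' @details `silhouette_index()`: mean over objects of
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, with `a(i)` the mean
#' within-cluster dissimilarity and `b(i)` the mean dissimilarity to the
#' nearest other cluster; singletons score 0. Benefit criterion, in
#' `[-1, 1]`. Per-object values are attached as attribute `"widths"`.
#' @export
silhouette_index <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$k < 2) stopf("silhouette_index needs k >= 2")
  sizes <- tabulate(ctx$labels, ctx$k)
  s <- numeric(ctx$n)
  for (i in seq_len(ctx$n)) {
    if (sizes[ctx$labels[i]] == 1) next  # singleton: s(i) = 0
    sums <- vapply(seq_len(ctx$k), function(cl)
      sum(ctx$P[i, ctx$labels == cl]), numeric(1))
    a <- sums[ctx$labels[i]] / (sizes[ctx$labels[i]] - 1)
    b <- min((sums / sizes)[-ctx$labels[i]])
    s[i] <- (b - a) / max(a, b)
  }
  structure(mean(s), widths = s)
}

#' @rdname validity-indices
#' @details `pbm_index()`: `((1/K) * (E_1 / E_K) * D_K)^2`
#' (Pakhira-Bandyopadhyay-Maulik), where `E_1` sums distances to the
#' global centroid, `E_K` sums member-to-centroid distances and `D_K` is
#' the largest inter-centroid distance (0 when k = 1). Benefit criterion;
#' `NaN` when `E_K = 0` with k > 1.
#' @export
pbm_index <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  gmean <- colMeans(ctx$x)
  e1 <- sum(sqrt(rowSums((ctx$x - matrix(gmean, ctx$n, ncol(ctx$x),
                                         byrow = TRUE))^2)))
  ek <- sum(sqrt(rowSums((ctx$x - ctx$centers[ctx$labels, , drop = FALSE])^2)))
  dk <- if (ctx$k == 1) 0 else max(stats::dist(ctx$centers))
  if (ek == 0) {
    if (ctx$k == 1) return(0)  # E_K = E_1 = 0 only for identical points
    return(NaN)
  }
  ((e1 / ek) * dk / ctx$k)^2
}

#' @rdname validity-indices
#' @details `c_index()`: `(S - S_min) / (S_max - S_min)`, where `S` sums
#' the within-cluster pairwise distances (`l` pairs) and `S_min`/`S_max`
#' sum the `l` smallest/largest of all pairwise distances. Cost criterion,
#' in `[0, 1]`; `NaN` when all pairwise distances are equal.
#' @export
c_index <- function(x, sol, P = NULL) {
  ctx <- validity_ctx(x, sol, P)
  if (ctx$k < 2) stopf("c_index needs k >= 2")
  p <- upper_pairs(ctx$P)
  within <- upper_pairs(outer(ctx$labels, ctx$labels, "=="))
  l <- sum(within)
  if (l < 1 || l >= length(p))
    stopf("c_index needs at least one within pair and one between pair")
  srt <- sort(p)
  s <- sum(p[within])
  smin <- sum(srt[seq_len(l)])
  smax <- sum(srt[seq(length(srt) - l + 1, length(srt))])
  if (smax == smin) return(NaN)
  (s - smin) / (smax - smin)
}
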