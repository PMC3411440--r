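# Independent naive-loop oracles for every validity index, written
# directly from the index definitions with explicit loops and no shared
# code with the package implementation.

o_dist <- function(a, b) sqrt(sum((a - b)^2))

o_centroids <- function(x, labels) {
  k <- max(labels)
  cent <- matrix(0, k, ncol(x))
  for (i in seq_len(k)) cent[i, ] <- colMeans(x[labels == i, , drop = FALSE])
  cent
}

o_hubert <- function(x, labels) {
  n <- nrow(x)
  cent <- o_centroids(x, labels)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + o_dist(x[i, ], x[j, ]) *
      o_dist(cent[labels[i], ], cent[labels[j], ])
  }
  tot / (n * (n - 1) / 2)
}

o_norm_hubert <- function(x, labels) {
  n <- nrow(x)
  cent <- o_centroids(x, labels)
  p <- q <- numeric(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    p <- c(p, o_dist(x[i, ], x[j, ]))
    q <- c(q, o_dist(cent[labels[i], ], cent[labels[j], ]))
  }
  sp <- sqrt(mean(p^2) - mean(p)^2)
  sq <- sqrt(mean(q^2) - mean(q)^2)
  (mean(p * q) - mean(p) * mean(q)) / (sp * sq)
}

o_dunn <- function(x, labels) {
  k <- max(labels)
  sep <- Inf
  diam <- 0
  for (i in seq_len(nrow(x) - 1)) for (j in seq(i + 1, nrow(x))) {
    d <- o_dist(x[i, ], x[j, ])
    if (labels[i] == labels[j]) diam <- max(diam, d) else sep <- min(sep, d)
  }
  sep / diam
}

o_db <- function(x, labels) {
  k <- max(labels)
  cent <- o_centroids(x, labels)
  s <- sapply(seq_len(k), function(i) {
    idx <- which(labels == i)
    mean(sapply(idx, function(r) o_dist(x[r, ], cent[i, ])))
  })
  tot <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) if (j != i)
      best <- max(best, (s[i] + s[j]) / o_dist(cent[i, ], cent[j, ]))
    tot <- tot + best
  }
  tot / k
}

o_cs <- function(x, labels) {
  k <- max(labels)
  cent <- o_centroids(x, labels)
  num <- 0
  for (i in seq_len(k)) {
    idx <- which(labels == i)
    tot <- 0
    for (r in idx) tot <- tot + max(sapply(idx, function(s2)
      o_dist(x[r, ], x[s2, ])))
    num <- num + tot / length(idx)
  }
  den <- 0
  for (i in seq_len(k)) {
    best <- Inf
    for (j in seq_len(k)) if (j != i)
      best <- min(best, o_dist(cent[i, ], cent[j, ]))
    den <- den + best
  }
  num / den
}

o_varnorm <- function(m) {
  v <- sapply(seq_len(ncol(m)), function(j) {
    mu <- mean(m[, j]); mean((m[, j] - mu)^2)
  })
  sqrt(sum(v^2))
}

o_scat <- function(x, labels) {
  k <- max(labels)
  mean(sapply(seq_len(k), function(i)
    o_varnorm(x[labels == i, , drop = FALSE]))) / o_varnorm(x)
}

o_dis <- function(cent) {
  k <- nrow(cent)
  ds <- c()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    ds <- c(ds, o_dist(cent[i, ], cent[j, ]))
  tot <- 0
  for (i in seq_len(k))
    tot <- tot + 1 / sum(sapply(seq_len(k), function(j)
      o_dist(cent[i, ], cent[j, ])))
  (max(ds) / min(ds)) * tot
}

o_sd <- function(x, labels, alpha = NULL) {
  cent <- o_centroids(x, labels)
  dis <- o_dis(cent)
  if (is.null(alpha)) alpha <- dis
  alpha * o_scat(x, labels) + dis
}

o_sdbw <- function(x, labels) {
  k <- max(labels)
  cent <- o_centroids(x, labels)
  stdev <- sqrt(sum(sapply(seq_len(k), function(i)
    o_varnorm(x[labels == i, , drop = FALSE])))) / k
  dens <- function(u, idx) sum(sapply(idx, function(r)
    o_dist(x[r, ], u) <= stdev))
  tot <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    idx <- which(labels %in% c(i, j))
    mx <- max(dens(cent[i, ], idx), dens(cent[j, ], idx))
    if (mx == 0) return(NaN)  # same degenerate signal as the implementation
    tot <- tot + dens((cent[i, ] + cent[j, ]) / 2, idx) / mx
  }
  o_scat(x, labels) + tot / (k * (k - 1))
}

o_silhouette <- function(x, labels) {
  n <- nrow(x)
  k <- max(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) o_dist(x[i, ], x[j, ])))
    b <- Inf
    for (cl in setdiff(seq_len(k), labels[i])) {
      others <- which(labels == cl)
      b <- min(b, mean(sapply(others, function(j) o_dist(x[i, ], x[j, ]))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

o_pbm <- function(x, labels) {
  k <- max(labels)
  cent <- o_centroids(x, labels)
  g <- colMeans(x)
  e1 <- sum(sapply(seq_len(nrow(x)), function(i) o_dist(x[i, ], g)))
  ek <- sum(sapply(seq_len(nrow(x)), function(i)
    o_dist(x[i, ], cent[labels[i], ])))
  dk <- 0
  for (i in seq_len(k)) for (j in seq_len(k))
    dk <- max(dk, o_dist(cent[i, ], cent[j, ]))
  ((1 / k) * (e1 / ek) * dk)^2
}

o_cindex <- function(x, labels) {
  n <- nrow(x)
  all_d <- c()
  within <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- o_dist(x[i, ], x[j, ])
    all_d <- c(all_d, d)
    within <- c(within, labels[i] == labels[j])
  }
  l <- sum(within)
  srt <- sort(all_d)
  (sum(all_d[within]) - sum(srt[1:l])) /
    (sum(rev(srt)[1:l]) - sum(srt[1:l]))
}

# Exhaustive global k-means optimum by enumerating all full partitions.
o_best_partition_wcss <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) == k) {
      cent <- o_centroids(x, labels)
      w <- sum(sapply(seq_len(n), function(i)
        sum((x[i, ] - cent[labels[i], ])^2)))
      best <- min(best, w)
    }
    i <- n
    while (i >= 1 && labels[i] == k) { labels[i] <- 1L; i <- i - 1 }
    if (i == 0) break
    labels[i] <- labels[i] + 1L
  }
  best
}

# A random labelled dataset where every cluster id is used.
random_instance <- function(n, k, d = 2) {
  x <- matrix(rnorm(n * d), n, d)
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  list(x = x, labels = sample(labels))
}

random_criteria_matrix <- function(m = 5, seed = NULL) {
  vals <- matrix(runif(m * 10, 0, 5), m, 10,
                 dimnames = list(paste0("k=", seq(2, m + 1)),
                                 names(mcdmk::criterion_directions)))
  structure(
    list(values = vals, raw = vals,
         degenerate = matrix(FALSE, m, 10),
         alternatives = seq(2L, m + 1L),
         criteria = names(mcdmk::criterion_directions),
         directions = mcdmk::criterion_directions,
         solutions = NULL, wcss = NULL),
    class = "criteria_matrix")
}
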