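#' Turn expert importance scores into a criterion weight vector
#'
#' Experts score each criterion on a 0-10 scale of increasing importance
#' (0 = irrelevant, 5 = moderate, 10 = extreme). Scores are averaged over
#' experts per criterion and normalized to sum to one.
#'
#' @param scores Numeric matrix or data frame, experts x criteria, all
#'   entries in `[0, 10]`; a single expert may pass a vector.
#' @return A numeric weight vector (class `weight_vector`), nonnegative,
#'   summing to 1, named by criterion when `scores` has column names.
#' @examples
#' normalize_expert_weights(rbind(c(8, 2), c(6, 4)))  # 0.7 0.3
#' @export
normalize_expert_weights <- function(scores) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1)
  scores <- as.matrix(scores)
  if (anyNA(scores) || any(scores < 0) || any(scores > 10))
    stopf("expert scores must all lie in [0, 10]")
  m <- colMeans(scores)
  if (sum(m) == 0) stopf("expert scores are all zero; weights undefined")
  as_weight_vector(m / sum(m))
}

#' @rdname normalize_expert_weights
#' @param w A nonnegative numeric vector; renormalized to sum to 1.
#' @export
as_weight_vector <- function(w) {
  w <- as.numeric(unlist(w))
  if (anyNA(w) || any(w < 0)) stopf("weights must be nonnegative")
  if (sum(w) == 0) stopf("weights sum to zero")
  structure(w / sum(w), class = "weight_vector")
}

uniform_weights <- function(n) as_weight_vector(rep(1, n))

check_weights <- function(cm, w) {
  if (is.null(w)) w <- uniform_weights(length(cm$criteria))
  if (!inherits(w, "weight_vector")) w <- as_weight_vector(w)
  if (length(w) != length(cm$criteria))
    stopf("need %d weights (one per criterion), got %d",
          length(cm$criteria), length(w))
  if (abs(sum(w) - 1) > 1e-12) stopf("weights must sum to 1")
  w
}

# Common RankingResult constructor: rank by score descending, breaking
# exact score ties toward the smaller k (parsimony).
ranking_result <- function(method, alternatives, scores,
                           tie_threshold = 0.01, extra = NULL) {
  ord <- order(-scores, alternatives)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  res <- structure(
    c(list(method = method, alternatives = alternatives,
           scores = unname(scores), order = alternatives[ord], rank = rank,
           best = alternatives[ord[1]], tie_threshold = tie_threshold,
           ties = NULL),
      extra),
    class = "ranking_result"
  )
  flag_close_ties(res, tie_threshold)
}

#' Rank alternatives with the weighted sum model (benefit minus cost)
#'
#' Each criterion column is min-max scaled to `[0, 1]` across alternatives
#' (raw-scale mode via `scale = "raw"`), then the score of an alternative
#' is its weighted sum over benefit criteria minus its weighted sum over
#' cost criteria; the best alternative has the largest score. The min-max
#' scaling makes criteria of very different magnitudes (e.g. Hubert Gamma
#' vs silhouette) commensurable.
#'
#' @param cm A [criteria_matrix()].
#' @param w Criterion weights ([as_weight_vector()]); uniform by default.
#' @param scale `"minmax"` (default) or `"raw"`.
#' @param tie_threshold Score gap below which top-ranked alternatives are
#'   flagged as ties (see [flag_close_ties()]).
#' @return A `ranking_result` with per-alternative `scores` (WSM
#'   importance), `order` (alternatives best-first), `rank`, `best`, and
#'   any close-tie flags in `ties`.
#' @export
wsm_rank <- function(cm, w = NULL, scale = c("minmax", "raw"),
                     tie_threshold = 0.01) {
  stopifnot(inherits(cm, "criteria_matrix"))
  scale <- match.arg(scale)
  w <- check_weights(cm, w)
  v <- cm$values
  if (scale == "minmax") {
    v <- apply(v, 2, function(col) {
      rng <- diff(range(col))
      if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
    })
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)  # single alternative
  }
  sgn <- ifelse(cm$directions == "benefit", 1, -1)
  scores <- drop(v %*% (as.numeric(w) * sgn))
  ranking_result("wsm", cm$alternatives, scores, tie_threshold,
                 extra = list(scale = scale))
}

#' Rank alternatives with PROMETHEE II net outranking flows
#'
#' For every ordered pair of alternatives the aggregated preference index
#' `pi(a, b)` sums the weights of the criteria on which `a` strictly beats
#' `b` (the usual, parameter-free preference function; cost criteria
#' compare in reverse). The positive flow `phi+` averages how much an
#' alternative outranks the others, the negative flow `phi-` how much it
#' is outranked, and alternatives are ranked by the net flow
#' `phi = phi+ - phi-`, which sums to zero and lies in `[-1, 1]`.
#'
#' @inheritParams wsm_rank
#' @return A `ranking_result`; `scores` are net flows, with `phi_plus` and
#'   `phi_minus` attached.
#' @export
promethee2_rank <- function(cm, w = NULL, tie_threshold = 0.01) {
  stopifnot(inherits(cm, "criteria_matrix"))
  if (length(cm$alternatives) < 2)
    stopf("PROMETHEE II needs at least two alternatives")
  w <- check_weights(cm, w)
  m <- length(cm$alternatives)
  sgn <- ifelse(cm$directions == "benefit", 1, -1)
  pi_mat <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      d <- sgn * (cm$values[a, ] - cm$values[b, ])
      pi_mat[a, b] <- sum(as.numeric(w)[d > 0])
    }
  }
  phi_plus <- rowSums(pi_mat) / (m - 1)
  phi_minus <- colSums(pi_mat) / (m - 1)
  ranking_result("promethee2", cm$alternatives, phi_plus - phi_minus,
                 tie_threshold,
                 extra = list(phi_plus = phi_plus, phi_minus = phi_minus))
}

#' Rank alternatives with TOPSIS
#'
#' Columns containing negative entries are shifted to be nonnegative, then
#' vector-normalized (`r_ij = x_ij / sqrt(sum_i x_ij^2)`) and weighted.
#' The ideal solution takes the per-criterion best (max for benefit, min
#' for cost) and the negative-ideal the worst; alternatives are ranked by
#' the relative closeness `C* = S- / (S+ + S-)` of their Euclidean
#' separations from the two, so `C*` lies in `[0, 1]` and larger is
#' better.
#'
#' @inheritParams wsm_rank
#' @return A `ranking_result`; `scores` are closeness ratios `C*`, with
#'   separations `s_plus` and `s_minus` attached.
#' @export
topsis_rank <- function(cm, w = NULL, tie_threshold = 0.01) {
  stopifnot(inherits(cm, "criteria_matrix"))
  if (length(cm$alternatives) < 2)
    stopf("TOPSIS needs at least two alternatives")
  w <- check_weights(cm, w)
  v <- cm$values
  v <- apply(v, 2, function(col) if (min(col) < 0) col - min(col) else col)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  norms <- sqrt(colSums(v^2))
  zero <- norms == 0
  if (any(zero))
    stopf("criterion '%s' is identically zero after the positivity shift",
          cm$criteria[which(zero)[1]])
  v <- sweep(v, 2, norms, "/")
  v <- sweep(v, 2, as.numeric(w), "*")
  benefit <- cm$directions == "benefit"
  ideal <- ifelse(benefit, apply(v, 2, max), apply(v, 2, min))
  nadir <- ifelse(benefit, apply(v, 2, min), apply(v, 2, max))
  s_plus <- sqrt(rowSums(sweep(v, 2, ideal)^2))
  s_minus <- sqrt(rowSums(sweep(v, 2, nadir)^2))
  closeness <- ifelse(s_plus + s_minus == 0, 0.5,
                      s_minus / (s_plus + s_minus))
  ranking_result("topsis", cm$alternatives, closeness, tie_threshold,
                 extra = list(s_plus = s_plus, s_minus = s_minus))
}

#' Flag near-tied top-ranked alternatives
#'
#' Among the top three ranked alternatives, any pair whose scores differ
#' by strictly less than `threshold` is flagged, so reports always carry
#' the scores alongside the rank order when the decision is close.
#'
#' @param r A `ranking_result`.
#' @param threshold Score-gap threshold (default 0.01).
#' @return `r` with its `ties` component set to a data frame
#'   (`k_a`, `k_b`, `score_a`, `score_b`, `gap`), empty when no pair is
#'   close.
#' @export
flag_close_ties <- function(r, threshold = 0.01) {
  stopifnot(inherits(r, "ranking_result"))
  top <- r$order[seq_len(min(3, length(r$order)))]
  sc <- r$scores[match(top, r$alternatives)]
  ties <- data.frame(k_a = integer(), k_b = integer(),
                     score_a = numeric(), score_b = numeric(),
                     gap = numeric())
  if (length(top) > 1) {
    for (i in seq_len(length(top) - 1)) {
      for (j in seq(i + 1, length(top))) {
        gap <- abs(sc[i] - sc[j])
        if (gap < threshold)
          ties[nrow(ties) + 1, ] <- list(top[i], top[j], sc[i], sc[j], gap)
      }
    }
  }
  r$ties <- ties
  r$tie_threshold <- threshold
  r
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("%s ranking (best k = %d)\n", toupper(x$method), x$best))
  df <- data.frame(k = x$alternatives, score = signif(x$scores, 6),
                   rank = x$rank)
  print(df[order(df$rank), ], row.names = FALSE)
  if (nrow(x$ties))
    cat(sprintf("Close ties (|gap| < %g): %s\n", x$tie_threshold,
                paste(sprintf("k=%d~k=%d (gap %.4g)", x$ties$k_a,
                              x$ties$k_b, x$ties$gap), collapse = "; ")))
  invisible(x)
}
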