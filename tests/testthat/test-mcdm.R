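single_criterion_cm <- function(values, direction = "benefit",
                                k = seq(2, length.out = length(values))) {
  structure(
    list(values = matrix(values, ncol = 1, dimnames = list(NULL, "crit")),
         raw = matrix(values, ncol = 1),
         degenerate = matrix(FALSE, length(values), 1),
         alternatives = as.integer(k), criteria = "crit",
         directions = c(crit = direction), solutions = NULL, wcss = NULL),
    class = "criteria_matrix")
}

two_criterion_cm <- function(vals, directions) {
  structure(
    list(values = vals, raw = vals,
         degenerate = matrix(FALSE, nrow(vals), 2),
         alternatives = seq(2L, length.out = nrow(vals)),
         criteria = colnames(vals), directions = directions,
         solutions = NULL, wcss = NULL),
    class = "criteria_matrix")
}

test_that("expert 0-10 scores average and normalize to weights", {
  expect_equal(as.numeric(normalize_expert_weights(c(5, 5))), c(0.5, 0.5))
  expect_equal(as.numeric(normalize_expert_weights(rbind(c(10, 0),
                                                         c(0, 10)))),
               c(0.5, 0.5))
  expect_equal(as.numeric(normalize_expert_weights(rbind(c(8, 2),
                                                         c(6, 4)))),
               c(0.7, 0.3))
  expect_error(normalize_expert_weights(c(11, 0)), "\\[0, 10\\]")
  expect_error(normalize_expert_weights(rbind(c(0, 0))), "all zero")
})

test_that("WSM follows criterion direction and the benefit-minus-cost score", {
  up <- wsm_rank(single_criterion_cm(c(0.2, 0.8), "benefit"), w = 1)
  expect_equal(up$best, 3L)
  down <- wsm_rank(single_criterion_cm(c(0.2, 0.8), "cost"), w = 1)
  expect_equal(down$best, 2L)
  vals <- cbind(b = c(1, 0), c = c(0, 1))
  cm <- two_criterion_cm(vals, c(b = "benefit", c = "cost"))
  r <- wsm_rank(cm, w = c(0.5, 0.5), scale = "minmax")
  expect_equal(r$scores, c(0.5, -0.5))
})

test_that("PROMETHEE II reproduces the hand-enumerated flows and invariants", {
  r <- promethee2_rank(single_criterion_cm(c(1, 2, 3), "benefit"), w = 1)
  expect_equal(r$scores, c(-1, 0, 1))
  expect_equal(r$best, 4L)
  set.seed(8)
  for (i in 1:20) {
    cm <- random_criteria_matrix(sample(3:9, 1))
    r <- promethee2_rank(cm)
    expect_equal(sum(r$scores), 0, tolerance = 1e-9)
    expect_true(all(r$scores >= -1 - 1e-12 & r$scores <= 1 + 1e-12))
  }
  # a dominating alternative attains phi = +1
  cm <- random_criteria_matrix(4)
  best <- ifelse(criterion_directions == "benefit",
                 apply(cm$values, 2, max) + 1, apply(cm$values, 2, min) - 1)
  cm$values[1, ] <- best
  cm$raw <- cm$values
  r <- promethee2_rank(cm)
  expect_equal(r$scores[1], 1)
  expect_equal(r$best, cm$alternatives[1])
})

test_that("TOPSIS closeness matches hand arithmetic and stays in [0, 1]", {
  r <- topsis_rank(single_criterion_cm(c(3, 4), "benefit"), w = 1)
  expect_equal(r$scores, c(0, 1))
  vals <- cbind(a = c(1, 0), b = c(0, 1))
  cm <- two_criterion_cm(vals, c(a = "benefit", b = "benefit"))
  r2 <- topsis_rank(cm, w = c(0.5, 0.5))
  expect_equal(r2$scores, c(0.5, 0.5))
  expect_equal(r2$best, 2L)  # exact tie broken toward the smaller k
  set.seed(9)
  for (i in 1:20) {
    r3 <- topsis_rank(random_criteria_matrix(sample(3:9, 1)))
    expect_true(all(r3$scores >= -1e-12 & r3$scores <= 1 + 1e-12))
  }
  zero <- two_criterion_cm(cbind(a = c(0, 0), b = c(1, 2)),
                           c(a = "benefit", b = "benefit"))
  expect_error(topsis_rank(zero), "identically zero")
})

test_that("an alternative dominating on every criterion ranks first everywhere", {
  set.seed(10)
  for (i in 1:30) {
    cm <- random_criteria_matrix(sample(3:8, 1))
    eps <- matrix(runif(length(cm$criteria), 0.01, 0.5), 1)
    winner <- sample(length(cm$alternatives), 1)
    loser <- sample(setdiff(seq_along(cm$alternatives), winner), 1)
    sgn <- ifelse(criterion_directions == "benefit", 1, -1)
    cm$values[winner, ] <- cm$values[loser, ] + sgn * eps
    cm$raw <- cm$values
    w <- as_weight_vector(runif(10, 0.1, 1))
    for (r in list(wsm_rank(cm, w), promethee2_rank(cm, w),
                   topsis_rank(cm, w)))
      expect_lt(r$rank[winner], r$rank[loser])
  }
})

test_that("permuting criteria together with weights leaves scores unchanged", {
  set.seed(11)
  cm <- random_criteria_matrix(6)
  w <- as_weight_vector(runif(10, 0.1, 1))
  perm <- sample(10)
  cm2 <- cm
  cm2$values <- cm$values[, perm]
  cm2$raw <- cm2$values
  cm2$criteria <- cm$criteria[perm]
  cm2$directions <- cm$directions[perm]
  w2 <- as_weight_vector(as.numeric(w)[perm])
  expect_equal(wsm_rank(cm2, w2)$scores, wsm_rank(cm, w)$scores,
               tolerance = 1e-12)
  expect_equal(promethee2_rank(cm2, w2)$scores,
               promethee2_rank(cm, w)$scores, tolerance = 1e-12)
  expect_equal(topsis_rank(cm2, w2)$scores, topsis_rank(cm, w)$scores,
               tolerance = 1e-12)
})

test_that("PROMETHEE flows depend only on the sign of criterion differences", {
  set.seed(12)
  cm <- random_criteria_matrix(5)
  w <- as_weight_vector(runif(10, 0.1, 1))
  cm2 <- cm
  cm2$values[, 3] <- cm$values[, 3] * 1000
  cm2$raw <- cm2$values
  expect_equal(promethee2_rank(cm2, w)$scores, promethee2_rank(cm, w)$scores,
               tolerance = 1e-12)
})

test_that("with one criterion all three methods agree with a plain sort", {
  set.seed(13)
  for (dir in c("benefit", "cost")) {
    vals <- runif(6, 0, 3)
    cm <- single_criterion_cm(vals, dir)
    expected <- cm$alternatives[order(if (dir == "benefit") -vals else vals)]
    expect_equal(wsm_rank(cm, 1)$order, expected)
    expect_equal(promethee2_rank(cm, 1)$order, expected)
    expect_equal(topsis_rank(cm, 1)$order, expected)
  }
})

test_that("close ties among the top three are flagged with their scores", {
  r <- structure(list(method = "wsm", alternatives = c(9L, 10L, 3L),
                      scores = c(-0.1827, -0.185, -0.5),
                      order = c(9L, 10L, 3L), rank = c(1L, 2L, 3L),
                      best = 9L, tie_threshold = 0.01, ties = NULL),
                 class = "ranking_result")
  flagged <- flag_close_ties(r, 0.01)
  expect_equal(nrow(flagged$ties), 1)
  expect_equal(flagged$ties$gap, 0.0023, tolerance = 1e-12)
  expect_equal(sort(c(flagged$ties$k_a, flagged$ties$k_b)), c(9, 10))
  expect_equal(nrow(flag_close_ties(r, 0)$ties), 0)
  wide <- r
  wide$scores <- c(0.9, 0.1, 0)
  expect_equal(nrow(flag_close_ties(wide, 0.01)$ties), 0)
})
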