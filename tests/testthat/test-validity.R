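# Frozen hand/oracle values for the 1-D fixture {0,1,10,11} | {A,A,B,B}:
# pairwise P = (1,10,11,9,10,1), Q = (0,10,10,10,10,0);
# Gamma = 400/6; normalized Gamma = cor(P,Q) = 0.99086735 (Pearson oracle);
# silhouette mean = (9.5/10.5 + 8.5/9.5)/2.
fx <- fixture_two_clusters_1d()
fx_sol <- kmeans_fit(fx$x, 2, seed = 1, restarts = 5)

test_that("every index reproduces its hand-derived fixture value", {
  expect_equal(dunn_index(fx$x, fx_sol), 9, tolerance = 1e-6)
  expect_equal(davies_bouldin(fx$x, fx_sol), 0.1, tolerance = 1e-6)
  expect_equal(cs_measure(fx$x, fx_sol), 0.1, tolerance = 1e-6)
  expect_equal(c_index(fx$x, fx_sol), 0, tolerance = 1e-6)
  expect_equal(pbm_index(fx$x, fx_sol), 2500, tolerance = 1e-6)
  expect_equal(as.numeric(silhouette_index(fx$x, fx_sol)),
               (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-6)
  expect_equal(hubert_gamma(fx$x, fx_sol), 400 / 6, tolerance = 1e-6)
  expect_equal(normalized_hubert(fx$x, fx_sol),
               cor(c(1, 10, 11, 9, 10, 1), c(0, 10, 10, 10, 10, 0)),
               tolerance = 1e-9)
  # SD against its independent oracle (alpha defaults to Dis of this k)
  expect_equal(sd_index(fx$x, fx_sol), o_sd(fx$x, fx_sol$labels),
               tolerance = 1e-9)
})

test_that("all ten indices match naive-loop oracles on random instances", {
  set.seed(20)
  for (rep in 1:25) {
    inst <- random_instance(n = sample(10:30, 1), k = sample(2:5, 1))
    sol <- mcdmk:::as_solution(inst$x, inst$labels)
    expect_equal(hubert_gamma(inst$x, sol), o_hubert(inst$x, sol$labels),
                 tolerance = 1e-9)
    expect_equal(normalized_hubert(inst$x, sol),
                 o_norm_hubert(inst$x, sol$labels), tolerance = 1e-9)
    expect_equal(dunn_index(inst$x, sol), o_dunn(inst$x, sol$labels),
                 tolerance = 1e-9)
    expect_equal(davies_bouldin(inst$x, sol), o_db(inst$x, sol$labels),
                 tolerance = 1e-9)
    expect_equal(cs_measure(inst$x, sol), o_cs(inst$x, sol$labels),
                 tolerance = 1e-9)
    expect_equal(sd_index(inst$x, sol), o_sd(inst$x, sol$labels),
                 tolerance = 1e-9)
    expect_equal(s_dbw(inst$x, sol), o_sdbw(inst$x, sol$labels),
                 tolerance = 1e-9)
    expect_equal(as.numeric(silhouette_index(inst$x, sol)),
                 o_silhouette(inst$x, sol$labels), tolerance = 1e-9)
    expect_equal(pbm_index(inst$x, sol), o_pbm(inst$x, sol$labels),
                 tolerance = 1e-9)
    expect_equal(c_index(inst$x, sol), o_cindex(inst$x, sol$labels),
                 tolerance = 1e-9)
  }
})

test_that("indices are invariant to cluster relabeling and row order", {
  set.seed(31)
  inst <- random_instance(20, 3)
  sol <- mcdmk:::as_solution(inst$x, inst$labels)
  perm_lab <- c(2L, 3L, 1L)[inst$labels]
  rows <- sample(20)
  indices <- list(hubert_gamma, normalized_hubert, dunn_index,
                  davies_bouldin, cs_measure, s_dbw,
                  function(x, s, ...) as.numeric(silhouette_index(x, s)),
                  pbm_index, c_index,
                  function(x, s, ...) sd_index(x, s, alpha = 1))
  for (f in indices) {
    base <- f(inst$x, sol)
    expect_equal(f(inst$x, mcdmk:::as_solution(inst$x, perm_lab)), base,
                 tolerance = 1e-9)
    expect_equal(f(inst$x[rows, ],
                   mcdmk:::as_solution(inst$x[rows, ], inst$labels[rows])),
                 base, tolerance = 1e-9)
  }
})

test_that("indices stay in their documented ranges", {
  set.seed(5)
  for (rep in 1:20) {
    inst <- random_instance(sample(8:25, 1), sample(2:4, 1))
    sol <- mcdmk:::as_solution(inst$x, inst$labels)
    expect_gte(as.numeric(silhouette_index(inst$x, sol)), -1)
    expect_lte(as.numeric(silhouette_index(inst$x, sol)), 1)
    nh <- normalized_hubert(inst$x, sol)
    expect_gte(nh, -1); expect_lte(nh, 1)
    ci <- c_index(inst$x, sol)
    expect_gte(ci, -1e-12); expect_lte(ci, 1 + 1e-12)
    vals <- c(dunn_index(inst$x, sol), davies_bouldin(inst$x, sol),
              cs_measure(inst$x, sol), sd_index(inst$x, sol),
              s_dbw(inst$x, sol), pbm_index(inst$x, sol),
              hubert_gamma(inst$x, sol))
    for (v in vals[is.finite(vals)]) expect_gte(v, 0)
  }
})

test_that("separating two fixed-shape clusters moves the indices as expected", {
  set.seed(77)
  base <- matrix(rnorm(60), 30, 2)
  labels <- rep(1:2, each = 15)
  vals <- sapply(c(3, 6, 12, 24), function(sep) {
    x <- base
    x[labels == 2, 1] <- x[labels == 2, 1] + sep
    sol <- mcdmk:::as_solution(x, labels)
    c(dunn = dunn_index(x, sol), pbm = pbm_index(x, sol),
      db = davies_bouldin(x, sol), cs = cs_measure(x, sol))
  })
  expect_true(all(diff(vals["dunn", ]) > 0))
  expect_true(all(diff(vals["pbm", ]) > 0))
  expect_true(all(diff(vals["db", ]) < 0))
  expect_true(all(diff(vals["cs", ]) < 0))
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(13)
  inst <- random_instance(25, 3)
  sol <- mcdmk:::as_solution(inst$x, inst$labels)
  ref <- mean(cluster::silhouette(sol$labels,
                                  dist(inst$x))[, "sil_width"])
  expect_equal(as.numeric(silhouette_index(inst$x, sol)), ref,
               tolerance = 1e-9)
})

test_that("degenerate partitions are flagged, not silently scored", {
  x <- matrix(c(0, 0, 1, 1, 10, 10), ncol = 1)
  dup_sol <- mcdmk:::as_solution(x, c(1, 1, 2, 2, 3, 3))
  # single cluster: Q constant, normalization undefined
  one <- mcdmk:::as_solution(x, rep(1, 6))
  expect_equal(hubert_gamma(x, one), 0)
  expect_true(is.nan(normalized_hubert(x, one)))
  # all clusters are point multisets: Dunn's own limit is +Inf
  expect_equal(dunn_index(x, dup_sol), Inf)
  # coincident "centroids" impossible here, but identical points give CS 0
  expect_equal(cs_measure(x, dup_sol), 0)
  # duplicate-point clusters give a perfect silhouette
  two <- mcdmk:::as_solution(matrix(c(0, 0, 10, 10), ncol = 1),
                             c(1, 1, 2, 2))
  expect_equal(as.numeric(silhouette_index(matrix(c(0, 0, 10, 10), ncol = 1),
                                           two)), 1)
  # k = 1: PBM collapses to 0 by D_1 = 0
  expect_equal(pbm_index(x, one), 0)
})

test_that("two tight, far-apart clusters give S_Dbw equal to its scattering term", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, sd = 0.5), 20, 2),
             matrix(rnorm(40, sd = 0.5), 20, 2) + 50)
  labels <- rep(1:2, each = 20)
  sol <- mcdmk:::as_solution(x, labels)
  expect_equal(s_dbw(x, sol), o_scat(x, labels), tolerance = 1e-9)
})
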