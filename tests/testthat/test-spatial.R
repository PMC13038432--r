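test_that("kNN graph breaks distance ties by ascending spot index", {
  g <- spot_grid(c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 0, 0))
  nn <- build_knn(g, k = 1)
  expect_equal(nn$neighbor_indices[2, ], 1L)  # middle spot: lower-index flank
  expect_equal(nn$distances[2, ], 1)
  expect_error(build_knn(g, k = 3), "k \\+ 1")
})

test_that("kNN graph matches the full-sort oracle and excludes self", {
  g <- random_grid(200, seed = 3)
  nn <- build_knn(g, k = 6)
  expect_identical(nn$neighbor_indices, naive_knn(g$coords, 6))
  for (i in seq_len(200)) expect_false(i %in% nn$neighbor_indices[i, ])
  expect_true(all(diff(t(nn$distances)) >= -1e-12))  # sorted by distance
})

test_that("quantile thresholding uses the strictly-greater rule", {
  g <- spot_grid(paste0("s", 1:4), x = 1:4, y = rep(0, 4),
                 signals = list(v = c(1, 2, 3, 4)))
  expect_equal(threshold_spots(g, "v", 0.75), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(threshold_spots(g, "v", 0), c(FALSE, TRUE, TRUE, TRUE))

  set.seed(8)
  g2 <- random_grid(100, seed = 8)
  mask <- threshold_spots(g2, "sig1", 0.6)
  expect_equal(mask, g2$signals$sig1 > quantile(g2$signals$sig1, 0.6, names = FALSE))

  g3 <- spot_grid(paste0("s", 1:4), x = 1:4, y = rep(0, 4),
                  signals = list(v = rep(2, 4)))
  expect_warning(m3 <- threshold_spots(g3, "v"), "constant")
  expect_false(any(m3))
})

test_that("neighborhood statistic averages neighbor signals over source spots", {
  # constant signal: statistic equals the constant for any mask
  g <- random_grid(50, seed = 2)
  g$signals$const <- rep(3.5, 50)
  graph <- build_knn(g, 6)
  expect_equal(neighborhood_statistic(g, graph, rep(TRUE, 50), "const"), 3.5)

  # single source with neighbor signals {0,0,0,0,0,6}: mean 1
  g1 <- spot_grid(paste0("s", 1:8),
                  x = c(0, 1, -1, 0, 0, 1, -1, 5), y = c(0, 0, 0, 1, -1, 1, -1, 5),
                  signals = list(v = c(9, 0, 0, 0, 0, 6, 0, 100)))
  gr1 <- build_knn(g1, 6)
  src <- c(TRUE, rep(FALSE, 7))
  expect_equal(neighborhood_statistic(g1, gr1, src, "v"), 1.0)

  # random instance equals the double-loop oracle
  g2 <- random_grid(100, seed = 12)
  mask <- threshold_spots(g2, "sig1", 0.7)
  expect_equal(neighborhood_statistic(g2, build_knn(g2, 6), mask, "sig1"),
               naive_neighborhood(g2$coords, mask, g2$signals$sig1, 6),
               tolerance = 1e-12)
  expect_error(neighborhood_statistic(g2, build_knn(g2, 6),
                                      rep(FALSE, 100), "sig1"), "empty source")
})

test_that("nearest-neighbor distance statistic matches the all-pairs oracle", {
  g <- spot_grid(c("a", "b"), x = c(0, 3), y = c(0, 4))
  expect_equal(nn_distance_statistic(g, c(TRUE, FALSE), c(FALSE, TRUE)), 5)

  # source contained in target: zero
  g2 <- random_grid(30, seed = 5)
  src <- rep(c(TRUE, FALSE), 15)
  expect_equal(nn_distance_statistic(g2, src, rep(TRUE, 30)), 0)

  g3 <- random_grid(120, seed = 6)
  a <- threshold_spots(g3, "sig1", 0.7)
  b <- threshold_spots(g3, "sig1", 0.2)
  expect_equal(nn_distance_statistic(g3, a, !b),
               naive_nn_distance(g3$coords, a, !b), tolerance = 1e-12)
  expect_error(nn_distance_statistic(g3, a, rep(FALSE, 120)), "empty target")
})

test_that("spatial statistics are invariant under rigid motions and scale correctly", {
  g <- random_grid(80, seed = 9)
  mask <- threshold_spots(g, "sig1", 0.75)
  tgt <- g$signals$sig1 < 0
  s0 <- neighborhood_statistic(g, build_knn(g, 6), mask, "sig1")
  d0 <- nn_distance_statistic(g, mask, tgt)
  theta <- 0.7
  rot <- g$coords %*% matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  g2 <- spot_grid(g$spot_ids, rot[, 1] + 100, rot[, 2] - 50,
                  signals = g$signals)
  expect_equal(neighborhood_statistic(g2, build_knn(g2, 6), mask, "sig1"), s0,
               tolerance = 1e-10)
  expect_equal(nn_distance_statistic(g2, mask, tgt), d0, tolerance = 1e-10)
  # scaling: neighborhood invariant (same neighbor sets), distance linear
  g3 <- spot_grid(g$spot_ids, 3 * g$coords[, 1], 3 * g$coords[, 2],
                  signals = g$signals)
  expect_equal(neighborhood_statistic(g3, build_knn(g3, 6), mask, "sig1"), s0,
               tolerance = 1e-10)
  expect_equal(nn_distance_statistic(g3, mask, tgt), 3 * d0, tolerance = 1e-10)
})

test_that("permutation p-values carry the +1 correction and are seed-deterministic", {
  g <- simulate_spot_grid(n_side = 8, pattern = "null", seed = 14)
  src <- threshold_spots(g, "marker")

  # constant immune signal: every null draw equals the observed, p = 1
  g$signals$flat <- rep(2, length(g$spot_ids))
  pt <- permutation_test(g, "neighborhood", source_mask = src, signal = "flat",
                         B = 50, alternative = "less", seed = 1)
  expect_equal(pt$pval, 1)

  # +1 floor at B = 10
  pt10 <- permutation_test(g, "neighborhood", source_mask = src,
                           signal = "immune", B = 10, alternative = "less",
                           seed = 2)
  expect_gte(pt10$pval, 1 / 11)

  # identical runs with the same seed; matches a naive loop on the same stream
  run <- function() permutation_test(g, "neighborhood", source_mask = src,
                                     signal = "immune", B = 99,
                                     alternative = "less", seed = 77)
  p1 <- run()
  p2 <- run()
  expect_identical(p1$pval, p2$pval)
  expect_identical(p1$null_draws, p2$null_draws)

  graph <- build_knn(g, 6)
  v <- g$signals$immune
  n <- length(v)
  set.seed(77)
  naive_draws <- vapply(1:99, function(i) {
    vp <- v[sample.int(n)]
    naive_neighborhood(g$coords, src, vp, 6)
  }, numeric(1))
  expect_equal(p1$null_draws, naive_draws, tolerance = 1e-12)
  obs <- naive_neighborhood(g$coords, src, v, 6)
  expect_equal(p1$pval, (1 + sum(naive_draws <= obs)) / 100)

  expect_error(permutation_test(g, "neighborhood", source_mask = src,
                                signal = "immune", B = 0, seed = 1), "B")
  expect_error(permutation_test(g, "neighborhood", source_mask = src,
                                signal = "immune", B = 10, seed = 1,
                                alternative = "sideways"), "less")
})

test_that("label permutation drives the nn-distance null", {
  g <- simulate_spot_grid(n_side = 10, pattern = "exclusion", seed = 4)
  src <- threshold_spots(g, "marker")
  tgt <- threshold_spots(g, "immune")
  pt <- permutation_test(g, "nn_distance", source_mask = src,
                         target_mask = tgt, B = 99, alternative = "greater",
                         seed = 5)
  # null draws preserve the number of target spots
  expect_equal(pt$observed, nn_distance_statistic(g, src, tgt))
  set.seed(5)
  naive <- vapply(1:99, function(i)
    naive_nn_distance(g$coords, src, sample(tgt)), numeric(1))
  expect_equal(pt$null_draws, naive, tolerance = 1e-12)
  expect_gte(pt$pval, 1 / 100)
  expect_lte(pt$pval, 1)
})

test_that("the exclusion report flags planted exclusion and not co-localization", {
  g <- simulate_spot_grid(n_side = 16, pattern = "exclusion", effect = 2,
                          noise_sd = 0.5, seed = 19)
  rep <- exclusion_report(g, "marker", "immune", B = 499, seed = 19)
  expect_lte(rep$neighborhood$pval, 0.05)
  expect_lte(rep$nn_distance$pval, 0.05)

  gc <- simulate_spot_grid(n_side = 16, pattern = "colocalized", effect = 2,
                           noise_sd = 0.5, seed = 19)
  repc <- exclusion_report(gc, "marker", "immune", B = 499, seed = 19)
  expect_gte(repc$neighborhood$pval, 0.9)  # opposite tail under "less"
})

test_that("planted exclusion effect sizes yield monotone power", {
  mean_p <- vapply(c(0.5, 1, 2), function(e) {
    mean(vapply(1:25, function(s) {
      g <- simulate_spot_grid(n_side = 12, pattern = "exclusion", effect = e,
                              seed = s)
      permutation_test(g, "neighborhood",
                       source_mask = threshold_spots(g, "marker"),
                       signal = "immune", B = 99, alternative = "less",
                       seed = s + 500)$pval
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_p) <= 0))
})
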