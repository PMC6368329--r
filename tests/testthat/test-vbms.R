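test_that("pre-partitioning uses the exact NND-quantile cutoff", {
  set.seed(91)
  m <- cbind(runif(1000, 0, 5000), runif(1000, 0, 5000))
  part <- preclust_partition(m)
  # brute-force NND + manual linear-interpolation quantile
  nnd <- sort(oracle_nnd(m, m, exclude_self = TRUE))
  h <- (length(nnd) - 1) * 0.999
  lo <- floor(h)
  expected <- nnd[lo + 1] + (h - lo) * (nnd[lo + 2 - (lo == length(nnd) - 1)] -
                                          nnd[lo + 1])
  expect_equal(part$eps, expected, tolerance = 1e-12)
  # the subsets plus removed points partition the input
  expect_setequal(c(unlist(part$subsets), part$removed), seq_len(1000))
  expect_error(preclust_partition(m[1, , drop = FALSE]), "at least 2")
})

test_that("isolated points are removed and tight sets stay together", {
  blob <- cbind(rnorm(50, 0, 10), rnorm(50, 0, 10))
  lone <- c(10000, 10000)   # far beyond any NND-based cutoff
  part <- preclust_partition(rbind(blob, lone))
  expect_equal(part$removed, 51L)
  expect_length(part$subsets, 1)
  expect_setequal(part$subsets[[1]], 1:50)
})

test_that("bandwidth estimation honors fixed and degenerate cases", {
  set.seed(92)
  m <- cbind(rnorm(200, 0, 100), rnorm(200, 0, 100))
  h <- estimate_bandwidths(m, "fixed", fixed_h = 250)
  expect_true(all(h == 250))

  # isotropic data: per-axis auto bandwidths nearly equal
  ha <- estimate_bandwidths(m, "auto", k = 50)
  expect_lt(median(abs(ha[, 1] - ha[, 2]) / ha[, 1]), 0.2)

  # degenerate axis: floored, no division by zero downstream
  line <- cbind(rep(5, 60), rnorm(60, 0, 100))
  hl <- estimate_bandwidths(line, "auto", k = 20)
  expect_true(all(hl[, 1] >= 1))
  expect_true(all(is.finite(mean_shift(line, hl)$modes)))

  # too few points: falls back to fixed with a warning
  expect_warning(hf <- estimate_bandwidths(m[1:10, ], "auto", k = 50),
                 "falling back")
  expect_true(all(hf == 250))
})

test_that("mean-shift climbs to the density mode", {
  one <- mean_shift(cbind(100, 200), 250)
  expect_equal(one$modes, cbind(100, 200))

  set.seed(93)
  blob <- cbind(rnorm(1000, 5000, 30), rnorm(1000, 5000, 30))
  ms <- mean_shift(blob, 250)
  # all trajectories merge into one mode near the sample mean
  spread <- max(dist(ms$modes))
  expect_lt(spread, 1)
  expect_lt(sqrt(sum((ms$modes[1, ] - colMeans(blob))^2)), 5)
})

test_that("kernel truncation is exact and inactive on compact data", {
  set.seed(94)
  blob <- cbind(rnorm(200, 0, 50), rnorm(200, 0, 50))  # diameter << 4h
  t4 <- mean_shift(blob, 250, trunc_factor = 4)
  tinf <- mean_shift(blob, 250, trunc_factor = Inf)
  expect_equal(t4$modes, tinf$modes, tolerance = 1e-9)
})

test_that("untruncated uniform-bandwidth mean-shift matches a naive oracle", {
  set.seed(95)
  m <- cbind(runif(400, 0, 3000), runif(400, 0, 3000))
  ms <- mean_shift(m, 150, trunc_factor = Inf)
  expect_equal(ms$modes, oracle_mean_shift(m, 150), tolerance = 1e-9)
})

test_that("mode grouping enforces the minimum cluster size", {
  # 4-point cluster retained, 3-point cluster discarded
  modes <- rbind(matrix(rep(c(0, 0), 4), ncol = 2, byrow = TRUE),
                 matrix(rep(c(5000, 0), 3), ncol = 2, byrow = TRUE))
  coords <- modes + matrix(rnorm(14, 0, 20), ncol = 2)
  res <- modes_to_clusters(modes, coords = coords, merge_tol = 125)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_locs, 4)
  expect_true(all(is.na(res$assignment[5:7])))

  # two modes 1 nm apart merge into one cluster
  m2 <- rbind(matrix(rep(c(0, 0), 3), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE))
  res2 <- modes_to_clusters(m2, coords = m2 + rnorm(12, 0, 10),
                            merge_tol = 125)
  expect_equal(nrow(res2$clusters), 1)
  expect_equal(res2$clusters$n_locs, 6)

  # density x area = n_locs identically for retained clusters
  ok <- !is.na(res2$clusters$density)
  expect_equal(res2$clusters$density[ok] * res2$clusters$area[ok],
               res2$clusters$n_locs[ok])
})

test_that("the VBMS pipeline recovers planted Thomas clusters", {
  # two nearby parents can merge under the 250 nm bandwidth, so the
  # parent-recovery rate is assessed in aggregate over ten seeds while
  # the cluster count stays within +/-2 of the planted 12 on every seed
  sq <- unit_square_um(10000)
  hit_rates <- vapply(101:110, function(s) {
    sc <- simulate_thomas(sq, 12, 80, 60, seed = s)
    res <- vbms_cluster(sc$locs)
    expect_lte(abs(nrow(res$clusters) - 12), 2)
    d <- nearest_neighbor_distances(as.matrix(sc$parents[, c("x", "y")]),
                                    res$mode_centers)
    mean(d < 100)
  }, numeric(1))
  expect_gte(mean(hit_rates), 0.9)
})

test_that("the pipeline is invariant to input point order", {
  sq <- unit_square_um(6000)
  sc <- simulate_thomas(sq, 6, 50, 50, seed = 111)
  res <- vbms_cluster(sc$locs)
  set.seed(112)
  perm <- sample(nrow(sc$locs))
  shuffled <- sc$locs[perm, , drop = FALSE]
  res_p <- vbms_cluster(shuffled)
  sets <- function(r) lapply(r$members, sort)
  expect_setequal(sets(res_p), sets(res))
})

test_that("well-separated partitions cluster the same alone or together", {
  # with truncated kernels, points farther apart than 4h never interact,
  # so mean-shift on each separated blob alone must reproduce the modes
  # found when both blobs are processed together
  set.seed(113)
  # two blobs ~8 um apart: far beyond 2 * (4h + merge_tol) with h = 250
  b1 <- cbind(rnorm(60, 0, 60), rnorm(60, 0, 60))
  b2 <- cbind(rnorm(60, 8000, 60), rnorm(60, 8000, 60))
  both <- rbind(b1, b2)
  joint <- mean_shift(both, 250)
  alone <- rbind(mean_shift(b1, 250)$modes, mean_shift(b2, 250)$modes)
  expect_equal(joint$modes, alone, tolerance = 1e-9)

  cj <- modes_to_clusters(joint$modes, coords = both, merge_tol = 125)
  c1 <- modes_to_clusters(mean_shift(b1, 250)$modes, coords = b1,
                          merge_tol = 125)
  c2 <- modes_to_clusters(mean_shift(b2, 250)$modes, coords = b2,
                          merge_tol = 125)
  sets <- function(r, offset = 0) lapply(r$members, function(m) sort(m + offset))
  expect_setequal(sets(cj), c(sets(c1), sets(c2, offset = 60)))
})
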