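test_that("DBSCAN handles the canonical configurations", {
  # two triplets of mutually-close points, far apart
  m <- rbind(cbind(c(0, 5, 10), c(0, 5, 0)),
             cbind(c(500, 505, 510), c(0, 5, 0)))
  labels <- dbscan(m, eps = 20, min_pts = 3)
  expect_equal(labels, c(1, 1, 1, 2, 2, 2))

  # everything isolated
  m2 <- cbind(c(0, 100, 200), c(0, 0, 0))
  expect_equal(dbscan(m2, eps = 50, min_pts = 2), c(0, 0, 0))
  expect_error(dbscan(m2, eps = -1, min_pts = 2), "eps")
})

test_that("DBSCAN matches a brute-force oracle on random scenes", {
  set.seed(51)
  for (rep in 1:10) {
    m <- cbind(runif(300, 0, 2000), runif(300, 0, 2000))
    expect_identical(dbscan(m, eps = 50, min_pts = 3),
                     oracle_dbscan(m, eps = 50, min_pts = 3))
    expect_identical(dbscan(m, eps = 120, min_pts = 5),
                     oracle_dbscan(m, eps = 120, min_pts = 5))
  }
})

test_that("per-channel size thresholds define a true cluster", {
  mk <- function(n, channel) {
    # one tight blob of n points
    tab <- loc_table(seq_len(n) * 2, rep(0, n), channel)
    labels <- rep(1L, n)
    make_clusters(labels, tab, channel)
  }
  expect_length(mk(5, "5-LO"), 1)    # >= 5 retained for 5-LO
  expect_length(mk(4, "5-LO"), 0)
  expect_length(mk(9, "FLAP"), 0)    # 9 < 10 discarded for FLAP
  expect_length(mk(10, "FLAP"), 1)
  expect_error(mk(10, "unknown"), "config error")
})

test_that("interaction classes follow the interacting-member count", {
  coords <- cbind(c(0, 10, 20, 0, 10, 15), c(0, 0, 0, 10, 10, 5))
  cl <- as_cluster_record(coords)
  mk_doc <- function(scores) structure(
    data.frame(id = 0:5, channel = "5-LO", direction = "5-LO->FLAP",
               score = scores, nnd = 0, colocalized = scores >= 0.4),
    params = list(threshold = 0.4), class = c("doc_result", "data.frame"))
  expect_equal(classify_interaction(cl, mk_doc(rep(0, 6)))$class, "NIC")
  cl4 <- classify_interaction(cl, mk_doc(c(0.4, 0.5, 0.6, 0.7, 0, 0)))
  expect_equal(cl4$n_interacting, 4)
  expect_equal(cl4$class, "LIC")
  cl5 <- classify_interaction(cl, mk_doc(c(0.4, 0.5, 0.6, 0.7, 0.8, 0)))
  expect_equal(cl5$n_interacting, 5)
  expect_equal(cl5$class, "HIC")
  # a member without a score is a validation error
  bad <- mk_doc(rep(1, 6)); bad <- bad[bad$id != 3, ]
  expect_error(classify_interaction(cl, bad), "lack a DoC score")
})

test_that("convex-hull areas match independent computations", {
  tri <- cluster_area(cbind(c(0, 4, 0), c(0, 0, 3)))
  expect_equal(tri$area, 6)
  expect_false(tri$degenerate)

  sqr <- cluster_area(cbind(c(0, 1000, 1000, 0, 500),
                            c(0, 0, 1000, 1000, 500)))
  expect_equal(sqr$area, 1e6)
  expect_equal(nrow(sqr$contour), 4)   # interior point not on the hull
  # counterclockwise contour: positive shoelace sum
  cx <- sqr$contour[, 1]; cy <- sqr$contour[, 2]
  j <- c(nrow(sqr$contour), seq_len(nrow(sqr$contour) - 1))
  expect_gt(sum(cx[j] * cy - cx * cy[j]), 0)

  coll <- cluster_area(cbind(c(0, 10, 20), c(0, 10, 20)))
  expect_equal(coll$area, 0)
  expect_true(coll$degenerate)

  set.seed(52)
  for (rep in 1:10) {
    m <- cbind(runif(100, 0, 800), runif(100, 0, 800))
    expect_equal(cluster_area(m)$area, oracle_hull_area(m),
                 tolerance = 1e-12)
  }
})

test_that("cluster members lie inside or on their contour", {
  set.seed(53)
  sq <- unit_square_um(4000)
  sc <- simulate_thomas(sq, 8, 40, 40, seed = 54, channel = "5-LO")
  labels <- dbscan(sc$locs, eps = 100, min_pts = 3)
  cls <- make_clusters(labels, sc$locs, "5-LO")
  expect_gt(length(cls), 0)
  for (cl in cls) {
    hull <- roi_polygon(cl$contour[, 1], cl$contour[, 2])
    expect_true(all(points_in_polygon(cl$coords[, 1], cl$coords[, 2],
                                      hull)))
  }
})

test_that("relative density matches a longhand evaluation", {
  # 6 points in two tight triads 420 nm apart, evaluated by hand:
  # each point has its 2 triad partners within 20 nm and nothing else
  pts <- cbind(c(0, 10, 0, 300, 310, 300), c(0, 0, 10, 300, 300, 310))
  cl <- as_cluster_record(pts)
  # hull: (0,0),(10,0),(310,300),(300,310),(0,10) -> shoelace longhand
  hand_area <- oracle_hull_area(pts)
  expect_equal(cl$area, hand_area)
  rho_i <- rep(2 / (pi * 400), 6)          # 2 neighbors each, self excluded
  hand <- mean(rho_i) / (6 / hand_area)
  expect_equal(relative_density(cl)$relative_density, hand)
})

test_that("relative density is ~1 for uniform discs and >> 1 for hotspots", {
  set.seed(55)
  th <- runif(2000, 0, 2 * pi); r <- 1000 * sqrt(runif(2000))
  disc <- as_cluster_record(cbind(r * cos(th), r * sin(th)))
  expect_lt(abs(relative_density(disc)$relative_density - 1), 0.1)

  # all mass in one 20 nm blob plus 3 far satellites spanning a big hull
  blob <- cbind(rnorm(200, 0, 5), rnorm(200, 0, 5))
  spread <- rbind(blob, c(3000, 0), c(0, 3000), c(3000, 3000))
  hot <- as_cluster_record(spread)
  expect_gt(relative_density(hot)$relative_density, 10)

  degen <- as_cluster_record(cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_warning(out <- relative_density(degen), "degenerate")
  expect_true(is.na(out$relative_density))
})

test_that("roi summaries count classes and interacting members", {
  mk_cl <- function(id, class, channel = "5-LO", members = 0:4)
    structure(list(id = id, channel = channel, members = members,
                   coords = cbind(members * 10, 0 * members),
                   area = 100, n_locs = length(members),
                   n_interacting = if (class == "NIC") 0L else 5L,
                   class = class, density = length(members) / 100,
                   relative_density = 1, degenerate = FALSE),
              class = "cluster_record")
  doc <- structure(
    data.frame(id = 0:9, channel = "5-LO", direction = "5-LO->FLAP",
               score = c(rep(0.5, 7), 0.1, 0.1, 0.1), nnd = 0,
               colocalized = c(rep(TRUE, 7), FALSE, FALSE, FALSE)),
    params = list(threshold = 0.4), class = c("doc_result", "data.frame"))
  clusters <- list(mk_cl(1, "NIC"), mk_cl(2, "HIC"),
                   mk_cl(3, "HIC", members = 5:6))
  s <- roi_summary(clusters, doc)
  pc <- s$per_class
  expect_equal(pc$n_clusters[pc$class == "NIC"], 1)
  expect_equal(pc$n_clusters[pc$class == "LIC"], 0)
  expect_equal(pc$n_clusters[pc$class == "HIC"], 2)
  # interacting ids 0..6 (7 of them); members cover ids 0..6 -> 100%;
  # restrict members to check the ratio: ids 0:4 and 5:6 hold all 7
  expect_equal(unname(s$percent_interacting_in_clusters["5-LO"]), 100)

  # 10 interacting, 7 in clusters -> 70%
  doc2 <- doc; doc2$score <- rep(0.5, 10)
  s2 <- roi_summary(clusters, doc2)
  expect_equal(unname(s2$percent_interacting_in_clusters["5-LO"]), 70)

  # no interacting localizations: undefined, not zero
  doc3 <- doc; doc3$score <- rep(0, 10)
  s3 <- roi_summary(clusters, doc3)
  expect_true(is.na(s3$percent_interacting_in_clusters["5-LO"]))
})

test_that("classes with too few contributing ROIs are flagged", {
  mk_sum <- function(nic, hic) {
    pc <- data.frame(class = c("NIC", "LIC", "HIC"),
                     n_clusters = c(nic, 0, hic), mean_area = NA)
    structure(list(per_class = pc,
                   percent_interacting_in_clusters = c("5-LO" = NA)),
              class = "roi_summary")
  }
  agg <- aggregate_roi_summaries(list(mk_sum(1, 1), mk_sum(2, 0),
                                      mk_sum(1, 0), mk_sum(3, 1)))
  expect_false(agg$excluded[agg$class == "NIC"])  # 4 contributing ROIs
  expect_true(agg$excluded[agg$class == "HIC"])   # only 2
  expect_equal(agg$mean_clusters_per_roi[agg$class == "NIC"], 7 / 4)
})

test_that("trimer estimates floor the localization count over three", {
  expect_equal(estimate_trimers(450), 150L)
  expect_equal(estimate_trimers(250), 83L)
  expect_equal(estimate_trimers(2), 0L)
  expect_equal(estimate_trimers(c(0, 3, 7)), c(0L, 1L, 2L))
  expect_error(estimate_trimers(-1), ">= 0")
})

test_that("classification is exhaustive and exclusive on a full scene", {
  sq <- unit_square_um(4000)
  sc <- simulate_two_channel(sq, channel_params(10, 30, 40, 50),
                             channel_params(10, 30, 40, 50),
                             coloc_fraction = 0.5, blink_mean = 2,
                             sigma_loc = 10, seed = 61)
  doc <- compute_doc(sc$locs)
  cls <- c(detect_clusters(sc$locs, doc, "5-LO"),
           detect_clusters(sc$locs, doc, "FLAP"))
  expect_gt(length(cls), 0)
  for (cl in cls) {
    expect_true(cl$class %in% c("NIC", "LIC", "HIC"))
    expect_lte(cl$n_interacting, cl$n_locs)
    expect_equal(cl$class,
                 c("NIC", "LIC", "HIC")[1 + (cl$n_interacting >= 1) +
                                          (cl$n_interacting >= 5)])
  }
})

test_that("planted Thomas clusters are recovered by the DBSCAN track", {
  sq <- unit_square_um(10000)
  hits <- numeric(0)
  for (s in 71:73) {
    sc <- simulate_thomas(sq, 20, 60, 50, seed = s, channel = "5-LO")
    bg <- simulate_csr(sq, round(nrow(sc$locs) * 0.1), seed = s + 100,
                       channel = "5-LO")
    tab <- loc_table(c(sc$locs$x, bg$locs$x), c(sc$locs$y, bg$locs$y),
                     "5-LO")
    labels <- dbscan(tab, eps = 50, min_pts = 3)
    cls <- make_clusters(labels, tab, "5-LO")
    cent <- t(vapply(cls, function(cl) colMeans(cl$coords), numeric(2)))
    d <- nearest_neighbor_distances(
      as.matrix(sc$parents[, c("x", "y")]), cent)
    hits <- c(hits, mean(d < 100))
  }
  expect_gte(min(hits), 0.9)
})

test_that("full colocalization yields more HIC than independence", {
  sq <- unit_square_um(4000)
  for (s in 81:83) {
    hic <- vapply(c(1, 0), function(cf) {
      sc <- simulate_two_channel(sq, channel_params(15, 40, 50, 100),
                                 channel_params(15, 40, 50, 100),
                                 coloc_fraction = cf, blink_mean = 4,
                                 sigma_loc = 10, seed = s)
      doc <- compute_doc(sc$locs)
      cls <- c(detect_clusters(sc$locs, doc, "5-LO"),
               detect_clusters(sc$locs, doc, "FLAP"))
      sum(vapply(cls, `[[`, character(1), "class") == "HIC")
    }, numeric(1))
    expect_gt(hic[1], hic[2])
  }
})
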