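test_that("ROI segmentation finds connected blobs and filters small ones", {
  set.seed(1)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 40), rnorm(n, cy, 40))
  one <- as.data.frame(blob(1000, 1000, 500))
  names(one) <- c("x_nm", "y_nm")
  expect_length(segment_rois(one), 1)

  two <- as.data.frame(rbind(blob(1000, 1000, 300), blob(6000, 1000, 300)))
  names(two) <- c("x_nm", "y_nm")
  rois <- segment_rois(two, linkage = 200)
  expect_length(rois, 2)
  expect_s3_class(rois[[1]], "point_pattern")

  small <- as.data.frame(blob(0, 0, 20))
  names(small) <- c("x_nm", "y_nm")
  expect_length(segment_rois(small, min_locs = 50), 0)
  expect_length(segment_rois(data.frame(x_nm = numeric(0),
                                        y_nm = numeric(0))), 0)
})

test_that("pair-distance histogram counts unordered pairs in bins", {
  p <- point_pattern(rbind(c(0, 0), c(70, 0)),
                     region = list(shape = "rect", xlim = c(0, 100),
                                   ylim = c(0, 100)))
  h <- pair_distance_histogram(p, bin_width = 10, max_dist = 100)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$dist_lo == 70], 1)

  tri <- point_pattern(100 * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                       region = list(shape = "rect", xlim = c(-50, 150),
                                     ylim = c(-50, 150)))
  ht <- pair_distance_histogram(tri, bin_width = 10, max_dist = 200)
  expect_equal(ht$count[ht$dist_lo == 100], 3)
  expect_equal(sum(ht$count), 3)

  set.seed(2)
  n <- 40
  rp <- point_pattern(cbind(runif(n, 0, 500), runif(n, 0, 500)))
  expect_lte(sum(pair_distance_histogram(rp, 10)$count), n * (n - 1) / 2)
  expect_error(pair_distance_histogram(point_pattern(cbind(1, 1))), "2 points")
})

test_that("CSR normalization is self-consistent for uniform patterns", {
  set.seed(7)
  region <- list(shape = "rect", xlim = c(0, 2000), ylim = c(0, 2000))
  p <- point_pattern(cbind(runif(300, 0, 2000), runif(300, 0, 2000)), region)
  h <- pair_distance_histogram(p, bin_width = 50)
  nh <- csr_normalize(h, p, n_rand = 100, seed = 3)
  ok <- !is.na(nh$normalized) & nh$expected_sd > 0
  z <- abs(nh$count[ok] - nh$expected[ok]) / nh$expected_sd[ok]
  # all bins within 3 Monte-Carlo SDs of the CSR expectation, allowing a
  # single marginal excursion over ~80 bins
  expect_lte(sum(z > 3), 1)
  # ratio means are only stable where the expectation is well populated
  solid <- ok & nh$expected >= 50
  expect_equal(mean(nh$normalized[solid]), 1, tolerance = 0.1)
})

test_that("coincident points blow up the first bin", {
  set.seed(8)
  region <- list(shape = "rect", xlim = c(0, 1000), ylim = c(0, 1000))
  p <- point_pattern(cbind(500 + runif(50, -0.5, 0.5),
                           500 + runif(50, -0.5, 0.5)), region)
  h <- pair_distance_histogram(p, bin_width = 10)
  nh <- csr_normalize(h, p, n_rand = 50, seed = 1)
  expect_gt(nh$normalized[1], 50)
})

test_that("CSR normalization is scale-invariant", {
  set.seed(9)
  xy <- cbind(rnorm(200, 500, 60), rnorm(200, 500, 60))
  region <- list(shape = "rect", xlim = c(0, 1000), ylim = c(0, 1000))
  p1 <- point_pattern(xy, region)
  h1 <- csr_normalize(pair_distance_histogram(p1, 20, 800), p1,
                      n_rand = 40, seed = 5)
  k <- 3.5
  p2 <- point_pattern(xy * k, list(shape = "rect", xlim = c(0, 1000 * k),
                                   ylim = c(0, 1000 * k)))
  h2 <- csr_normalize(pair_distance_histogram(p2, 20 * k, 800 * k), p2,
                      n_rand = 40, seed = 5)
  expect_equal(h1$normalized, h2$normalized, tolerance = 1e-10)
})

test_that("cluster radius tracks the generating cluster scale", {
  region <- list(shape = "rect", xlim = c(0, 2000), ylim = c(0, 2000))
  set.seed(10)
  p30 <- point_pattern(cbind(rnorm(400, 1000, 30), rnorm(400, 1000, 30)),
                       region)
  r30 <- cluster_radius(p30, seed = 2)
  expect_gte(r30$radius, 20)
  expect_lte(r30$radius, 80)
  expect_true(r30$reliable)

  p100 <- point_pattern(cbind(rnorm(400, 1000, 100), rnorm(400, 1000, 100)),
                        region)
  r100 <- cluster_radius(p100, seed = 2)
  expect_gt(r100$radius, r30$radius)

  # uniform pattern: flat histogram, flagged unreliable
  pu <- point_pattern(cbind(runif(400, 0, 2000), runif(400, 0, 2000)), region)
  expect_false(cluster_radius(pu, seed = 2)$reliable)

  expect_error(cluster_radius(point_pattern(cbind(1:5, 1:5))), "at least 10")
})

test_that("cluster radius is invariant under rigid motions", {
  set.seed(11)
  xy <- cbind(rnorm(300, 0, 40), rnorm(300, 0, 40))
  region <- list(shape = "disc", center = c(0, 0), radius = 500)
  r0 <- cluster_radius(point_pattern(xy, region), seed = 4)
  # translation
  rt <- cluster_radius(point_pattern(xy + 1e4,
                                     list(shape = "disc",
                                          center = c(1e4, 1e4),
                                          radius = 500)), seed = 4)
  expect_equal(rt$radius, r0$radius)
  # rotation by 63 degrees about the region center
  th <- 63 * pi / 180
  rot <- xy %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rr <- cluster_radius(point_pattern(rot, region), seed = 4)
  expect_equal(rr$radius, r0$radius)
})

test_that("radius estimates grow with the generator cluster-scale setting", {
  means <- vapply(c(20, 40, 80), function(s) {
    locs <- generate_synaptosome_locs(seed = 9, preset = "clustered",
                                      cluster_sigma_nm = s,
                                      n_synaptosomes = 3)
    mean(vapply(segment_rois(locs),
                function(p) cluster_radius(p, seed = 9)$radius, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("radius comparison uses a Welch t-test with degenerate shortcut", {
  same <- compare_radii(c(50, 50, 50), c(50, 50, 50))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)

  set.seed(12)
  a <- rnorm(20, 60, 5)
  b <- rnorm(20, 120, 5)
  cmp <- compare_radii(a, b)
  expect_lt(cmp$p_value, 0.001)
  expect_lt(cmp$mean_diff, 0)

  # unbalanced group sizes are accepted as-is
  cmp2 <- compare_radii(rnorm(22, 60, 5), rnorm(30, 120, 5))
  expect_identical(c(cmp2$n_a, cmp2$n_b), c(22L, 30L))
})
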