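# Point-pattern analytics: linkage clustering, centroid NND and CSR null,
# pairwise-distance peaks, and binomial thinning.

test_that("point patterns validate membership and compute areas", {
  reg <- rect_region(50, 50)
  expect_equal(polygon_area <- pattern_area(point_pattern(numeric(0), numeric(0), reg)),
               2500)
  expect_error(point_pattern(60000, 100, reg), "inside")
  # boundary points count as inside
  pp <- point_pattern(c(0, 50000), c(0, 50000), reg)
  expect_equal(nrow(pp), 2)
  # degenerate polygons are rejected
  expect_error(point_pattern(0, 0, cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
  # non-rectangular region: right triangle of legs 1000 nm -> 0.5 um^2
  tri <- cbind(c(0, 1000, 0), c(0, 0, 1000))
  expect_equal(pattern_area(point_pattern(10, 10, tri)), 0.5)
})

test_that("single linkage chains points and respects the exact cutoff", {
  reg <- rect_region(1, 1)
  # three collinear points spaced 0.9 * cutoff: one chain of 3
  pp <- point_pattern(c(100, 118, 136), c(500, 500, 500), reg)
  cl <- link_clusters(pp, cutoff = 20)
  expect_equal(cl$sizes, 3L)
  # spacing 1.1 * cutoff: singletons
  pp2 <- point_pattern(c(100, 122), c(500, 500), reg)
  expect_equal(link_clusters(pp2, cutoff = 20)$sizes, c(1L, 1L))
  # exactly at the cutoff: links
  pp3 <- point_pattern(c(100, 120), c(500, 500), reg)
  expect_equal(link_clusters(pp3, cutoff = 20)$sizes, 2L)
  # centroid of a singleton is the point itself
  expect_equal(unname(link_clusters(pp2, cutoff = 20)$centroids[1, ]),
               c(100, 500))
})

test_that("linkage matches the O(N^2) transitive-closure oracle", {
  set.seed(12)
  for (i in 1:4) {
    n <- 200
    x <- runif(n, 0, 2000)
    y <- runif(n, 0, 2000)
    pp <- point_pattern(x, y, rect_region(2.001, 2.001))
    cl <- link_clusters(pp, cutoff = 60)
    oracle <- brute_force_linkage(x, y, 60)
    # same partition: membership vectors equal up to relabeling
    expect_equal(sizes_of(cl$membership), sizes_of(oracle))
    tab <- table(cl$membership, oracle)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("clustering is invariant under rigid motions", {
  set.seed(8)
  x <- runif(100, 1000, 4000)
  y <- runif(100, 1000, 4000)
  cl1 <- link_clusters(point_pattern(x, y, rect_region(5, 5)), cutoff = 75)
  th <- 0.7
  xr <- 2500 + cos(th) * (x - 2500) - sin(th) * (y - 2500) + 120
  yr <- 2500 + sin(th) * (x - 2500) + cos(th) * (y - 2500) - 60
  cl2 <- link_clusters(point_pattern(xr, yr, rect_region(5, 5)), cutoff = 75)
  expect_equal(sizes_of(cl1$membership), sizes_of(cl2$membership))
})

test_that("cluster size distributions count clusters per area", {
  reg <- rect_region(sqrt(5), sqrt(5))  # 5 um^2
  pp <- point_pattern(seq(100, 1000, length.out = 10), rep(100, 10), reg)
  cl <- link_clusters(pp, cutoff = 10)  # spacing 100 nm: all singletons
  d <- cluster_size_distribution(cl)
  expect_equal(d$n, 1L)
  expect_equal(d$density, 2)
  expect_equal(total_concentration(d), nrow(pp) / pattern_area(pp))
})

test_that("planted synthetic sizes are recovered exactly at full efficiency", {
  cfg <- synth_config("hots", params_hl1(), ctot = 2,
                      region = rect_region(30, 30))
  set.seed(71)
  sizes <- sample_sizes(cfg)
  pat <- place_clusters(sizes, cfg)
  cl <- link_clusters(pat, cutoff = 20)
  expect_equal(sizes_of(cl$membership), sort(sizes, decreasing = TRUE))
})

test_that("centroid nearest-neighbor distances match the all-pairs oracle", {
  reg <- rect_region(10, 10)
  # two well-separated triangles: both NNDs equal the centroid separation
  t1 <- cbind(c(0, 10, 5), c(0, 0, 8)) + 1000
  t2 <- cbind(c(0, 10, 5), c(0, 0, 8)) + 4000
  pp <- point_pattern(c(t1[, 1], t2[, 1]), c(t1[, 2], t2[, 2]), reg)
  cl <- link_clusters(pp, cutoff = 15)
  nn <- nnd_centroids(cl, min_size = 3)
  expect_length(nn, 2)
  expect_equal(nn[1], nn[2])
  expect_equal(nn[1], sqrt(2) * 3000, tolerance = 1e-12)
  # min_size filters; fewer than two qualifying clusters warns
  expect_warning(empty <- nnd_centroids(cl, min_size = 4), "fewer than 2")
  expect_length(empty, 0)
  # random patterns against a dist()-based oracle
  set.seed(14)
  x <- runif(40, 0, 9000)
  y <- runif(40, 0, 9000)
  singles <- link_clusters(point_pattern(x, y, reg), cutoff = 1e-6)
  nn2 <- nnd_centroids(singles, min_size = 1)
  dm <- as.matrix(dist(cbind(x, y)))
  diag(dm) <- Inf
  expect_equal(nn2, unname(apply(dm, 1, min)))
})

test_that("CSR null is seeded and matches the 2D Poisson NND law", {
  reg <- rect_region(100, 100)
  s1 <- csr_null(reg, n_clusters = 300, n_reps = 3, seed = 99)
  s2 <- csr_null(reg, n_clusters = 300, n_reps = 3, seed = 99)
  expect_identical(s1, s2)
  expect_length(s1, 900)
  # closed-form CDF: 1 - exp(-pi * lambda * r^2), lambda in nm^-2
  lambda <- 300 / (1e5 * 1e5)
  ks <- suppressWarnings(ks.test(s1, function(r) 1 - exp(-pi * lambda * r^2)))
  expect_gt(ks$p.value, 0.01)
  # two points in a square: mean NND equals the mean segment length
  # E|P1 - P2| = L * (2 + sqrt(2) + 5 asinh(1)) / 15 (quadrature constant)
  s3 <- csr_null(rect_region(1, 1), n_clusters = 2, n_reps = 4000, seed = 5)
  const <- (2 + sqrt(2) + 5 * asinh(1)) / 15
  expect_equal(mean(s3), 1000 * const, tolerance = 0.02)
})

test_that("pairwise distance histograms enumerate short pairs exactly", {
  reg <- rect_region(1, 1)
  # equilateral triangle, side 5 nm
  pp <- point_pattern(500 + c(0, 5, 2.5), 500 + c(0, 0, 5 * sqrt(3) / 2), reg)
  h <- pairwise_distance_histogram(pp, max_distance = 10)
  expect_length(h$distances, 3)
  expect_equal(h$distances, rep(5, 3), tolerance = 1e-12)
  # against the brute-force all-pairs oracle on a random pattern
  set.seed(21)
  x <- runif(150, 0, 900)
  y <- runif(150, 0, 900)
  pp2 <- point_pattern(x, y, reg)
  h2 <- pairwise_distance_histogram(pp2, max_distance = 120)
  dm <- dist(cbind(x, y))
  expect_equal(sort(h2$distances), sort(dm[dm <= 120]))
  # precision filter keeps only well-localized points
  pp3 <- point_pattern(c(100, 104, 108), rep(100, 3), reg,
                       precision = c(0.5, 0.5, 3))
  h3 <- pairwise_distance_histogram(pp3, max_distance = 20,
                                    precision_filter = 1)
  expect_length(h3$distances, 1)
})

test_that("gaussian peak fitting recovers planted peaks and flags problems", {
  mid <- seq(0.25, 19.75, by = 0.5)
  gauss <- function(a, mu, sg) a * exp(-(mid - mu)^2 / (2 * sg^2))
  h <- list(mid = mid, counts = gauss(400, 5.2, 0.8))
  f <- fit_gaussian_peak(h)
  expect_equal(f$mean, 5.2, tolerance = 1e-6)
  expect_equal(f$sd, 0.8, tolerance = 1e-6)
  expect_false(f$multimodal)
  # monotone histogram: no interior peak
  expect_error(fit_gaussian_peak(list(mid = mid, counts = rev(sort(runif(40))))),
               "no interior peak")
  # bimodal: fits the taller mode, flags the other
  h2 <- list(mid = mid, counts = gauss(300, 5, 0.7) + gauss(200, 14, 0.7))
  f2 <- fit_gaussian_peak(h2)
  expect_equal(f2$mean, 5, tolerance = 0.05)
  expect_true(f2$multimodal)
})

test_that("synthetic packed clusters show the planted spacing as the main peak", {
  cfg <- synth_config("hots", params_hl1(), ctot = 3,
                      region = rect_region(40, 40), packing_jitter = 0.3)
  set.seed(5)
  pp <- simulate_point_pattern(cfg)
  h <- pairwise_distance_histogram(pp, max_distance = 30)
  f <- fit_gaussian_peak(h)
  expect_lt(abs(f$mean - 5.2), 0.3)
})

test_that("binomial thinning behaves like independent label loss", {
  reg <- rect_region(20, 20)
  set.seed(9)
  pp <- point_pattern(runif(1e4, 0, 2e4), runif(1e4, 0, 2e4), reg)
  expect_identical(thin_labels(pp, 1), pp)
  th <- thin_labels(pp, 0.5, seed = 2)
  # retained count within the binomial 99% interval around 5000
  expect_lt(abs(nrow(th) - 5000), qnorm(0.995) * sqrt(1e4 * 0.25))
  # a size-n cluster thins to Binomial(n, p): check the mean over repeats
  cfg <- synth_config("hots", params_hl1(), ctot = 1, region = reg)
  clus <- place_clusters(rep(20L, 50), cfg, seed = 3)
  kept <- vapply(1:30, function(i) nrow(thin_labels(clus, 0.3, seed = i)),
                 numeric(1))
  expect_lt(abs(mean(kept) / 50 - 20 * 0.3), 0.5)
})
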