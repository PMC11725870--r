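# Synthetic-data generator: model-faithful size sampling, CSR centroid
# placement with hexagonal intra-cluster packing, and the observation model.

test_that("monomer model yields only singletons at the requested density", {
  cfg <- synth_config("monomers", ctot = 2, region = rect_region(20, 20))
  sizes <- sample_sizes(cfg, seed = 1)
  expect_true(all(sizes == 1L))
  # expected count 800; within 5 sigma
  expect_lt(abs(length(sizes) - 800), 5 * sqrt(800))
})

test_that("supercritical requests are refused with a critical-density message", {
  cfg <- synth_config("hots", params_hl1(), ctot = 9)  # critical total 8.66
  expect_error(sample_sizes(cfg), "critical_total_concentration")
})

test_that("sampled sizes match the model law (chi-square) and total density", {
  cfg <- synth_config("hots", params_hl1(), ctot = 4.3,
                      region = rect_region(sqrt(3000), sqrt(3000)))
  sizes <- sample_sizes(cfg, seed = 6)
  area <- 3000
  # total labels per area within 3 sigma of ctot (Poisson-sum oracle)
  expected_total <- 4.3 * area
  expect_lt(abs(sum(sizes) - expected_total), 3 * sqrt(expected_total))
  # per-size counts against the expected Poisson means where mean >= 5
  cm <- solve_monomer_from_total(params_hl1(), 4.3, 4096)
  mu <- nmer_density(params_hl1(), cm, 1:50) * area
  obs <- tabulate(sizes, nbins = 50)
  keep <- mu >= 5
  cs <- sum((obs[keep] - mu[keep])^2 / mu[keep])
  expect_gt(pchisq(cs, df = sum(keep), lower.tail = FALSE), 0.01)
})

test_that("attractor sampling also matches its generating law", {
  ap <- attractor_params(Ka = 200, mtot = 5)
  cfg <- synth_config("attractor", ap, ctot = 12,
                      region = rect_region(sqrt(2000), sqrt(2000)))
  sizes <- sample_sizes(cfg, seed = 16)
  d <- attractor_distribution(ap, 12, nmax = 50)
  mu <- d$density * 2000
  obs <- tabulate(sizes, nbins = 50)
  keep <- mu >= 5
  cs <- sum((obs[keep] - mu[keep])^2 / mu[keep])
  expect_gt(pchisq(cs, df = sum(keep), lower.tail = FALSE), 0.01)
})

test_that("hexagonal packing places clusters at the requested spacing", {
  cfg <- synth_config("hots", params_hl1(), ctot = 1,
                      region = rect_region(10, 10), packing_jitter = 0)
  pat <- place_clusters(c(1L, 7L), cfg, seed = 4)
  expect_equal(nrow(pat), 8)
  expect_equal(sort(unique(pat$channel)), 1:2)
  seven <- pat[pat$channel == 2, ]
  dm <- as.matrix(dist(cbind(seven$x, seven$y)))
  diag(dm) <- Inf
  # hexagonal shell: every point's nearest neighbor at exactly the spacing
  expect_equal(unname(apply(dm, 1, min)), rep(5.2, 7), tolerance = 1e-9)
  # center of the shell has 6 neighbors at the spacing
  expect_equal(sort(dm[dm < 5.3]), rep(5.2, 24), tolerance = 1e-9)
})

test_that("all generated points fall inside the region", {
  tri <- cbind(c(0, 3e4, 0), c(0, 0, 3e4))
  cfg <- synth_config("hots", params_hl1(), ctot = 2, region = tri)
  pp <- simulate_point_pattern(cfg, seed = 10)
  expect_true(all(hots:::points_in_polygon(pp$x, pp$y, tri)))
})

test_that("the observation model thins and adds uniform background", {
  cfg0 <- synth_config("hots", params_hl1(), ctot = 2,
                       region = rect_region(10, 10))
  set.seed(2)
  pat <- place_clusters(sample_sizes(cfg0), cfg0)
  # efficiency 1, background 0: identity on coordinates
  out <- apply_observation_model(pat, cfg0, seed = 1)
  expect_equal(out$x, pat$x)
  expect_true(all(out$channel == "signal"))
  # background density 0.5 on 100 um^2: about 50 extra points
  cfg_bg <- synth_config("hots", params_hl1(), ctot = 2,
                         region = rect_region(10, 10),
                         background_density = 0.5)
  out2 <- apply_observation_model(pat, cfg_bg, seed = 3)
  n_bg <- sum(out2$channel == "background")
  expect_lt(abs(n_bg - 50), 4 * sqrt(50))
  # blind mode strips the annotation
  out3 <- apply_observation_model(pat, cfg_bg, seed = 3, blind = TRUE)
  expect_null(out3$channel)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config("hots", params_cho(), ctot = 1.5,
                      region = rect_region(20, 20),
                      labeling_efficiency = 0.8, background_density = 0.2)
  p1 <- simulate_point_pattern(cfg, seed = 123)
  p2 <- simulate_point_pattern(cfg, seed = 123)
  expect_identical(p1, p2)
})

test_that("distribution panels share the cohesion energy and hit their totals", {
  set.seed(50)
  panel <- make_distribution_panel(-1.82, 0.08, ctots = c(1, 2, 4), area = 2500)
  expect_length(panel, 3)
  for (i in 1:3) {
    ct <- c(1, 2, 4)[i]
    expect_lt(abs(attr(panel[[i]], "ctot") - ct), 3 * sqrt(ct * 2500) / 2500)
  }
  # with huge areas the empirical densities converge on the exact law
  big <- make_distribution_panel(-1.5, 0.3, ctots = 2, area = 4e5)[[1]]
  p <- aggregation_params(-1.5, 0.3)
  cm <- solve_monomer_from_total(p, 2, 4096)
  expect_equal(density_at(big, 1:10), nmer_density(p, cm, 1:10),
               tolerance = 0.05)
})

test_that("centroids are CSR: their nearest-neighbor spacing matches theory", {
  cfg <- synth_config("hots", params_hl1(), ctot = 3,
                      region = rect_region(60, 60))
  pp <- simulate_point_pattern(cfg, seed = 77)
  cl <- link_clusters(pp, cutoff = 20)
  nn <- nnd_centroids(cl, min_size = 3)
  lambda <- sum(cl$sizes >= 3) / (6e4 * 6e4)   # qualifying clusters per nm^2
  # 2D Poisson mean NND = 1 / (2 sqrt(lambda)); 5% tolerance for edge effects
  expect_lt(abs(mean(nn) - 1 / (2 * sqrt(lambda))) / (1 / (2 * sqrt(lambda))),
            0.05)
})
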