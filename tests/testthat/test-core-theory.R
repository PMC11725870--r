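# Closed-form reversible-aggregation model: n-mer densities, critical
# concentrations, phase-transition series, mass-balance inversion.

test_that("parameter validation rejects unphysical inputs", {
  expect_error(aggregation_params(-1, A0 = 0), "A0")
  expect_error(aggregation_params(-1, A0 = -2), "A0")
  expect_error(aggregation_params(NaN, A0 = 1))
  expect_error(aggregation_params(-1, 1, boundary_exponent = 1), "boundary_exponent")
  expect_silent(aggregation_params(-1, 1, boundary_exponent = 0))
})

test_that("nmer_density matches hand evaluation and the n = 1 identity", {
  p <- params_hl1()
  # n = 1: boundary exponent term vanishes, density is cmon itself
  expect_identical(nmer_density(p, cmon = 0.45, n = 1), 0.45)
  # dG = 0: pure configurational factor (A0 c)^n / A0
  expect_equal(nmer_density(aggregation_params(0, 1), cmon = 0.3, n = 3), 0.027)
  # direct arithmetic oracle: (1/A0) (A0 c)^2 exp((sqrt(2)-2) dG)
  expect_equal(nmer_density(p, cmon = 0.45, n = 2), 0.242836382561,
               tolerance = 1e-10)
  expect_equal(nmer_density(p, cmon = 0, n = 1:5), rep(0, 5))
  expect_error(nmer_density(p, cmon = 0.4, n = 0), "positive integers")
})

test_that("critical monomer concentration follows 1/A0 * exp(dG)", {
  expect_equal(critical_monomer_concentration(params_hl1()),
               0.498938306791, tolerance = 1e-10)
  expect_equal(critical_monomer_concentration(aggregation_params(0, 1)), 1.0)
  # expression-series parameter set, direct arithmetic oracle
  expect_equal(critical_monomer_concentration(params_cho()),
               2.02532188667, tolerance = 1e-10)
  # strictly decreasing in |dG| for cohesive proteins
  cc <- vapply(seq(-0.5, -3, by = -0.5),
               function(g) critical_monomer_concentration(aggregation_params(g, 0.58)),
               numeric(1))
  expect_true(all(diff(cc) < 0))
})

test_that("critical distribution is the n-mer law at the critical point", {
  p <- params_hl1()
  d <- critical_distribution(p, nmax = 30)
  expect_s3_class(d, "size_distribution")
  expect_equal(d$density[1], critical_monomer_concentration(p))
  expect_true(all(diff(d$density) < 0))
  expect_equal(d$density[4], 0.144384871711, tolerance = 1e-10)
  # algebraic identity with nmer_density evaluated at cmon_crit
  cc <- critical_monomer_concentration(p)
  expect_equal(d$density, nmer_density(p, cc, 1:30), tolerance = 1e-12)
})

test_that("delta_g_nmer implements the thermodynamic cycle", {
  expect_identical(delta_g_nmer(params_hl1(), 1), 0)
  expect_equal(delta_g_nmer(aggregation_params(-2, 1), 4), -4)
  expect_equal(delta_g_nmer(params_hl1(), 10), -8.47877570139, tolerance = 1e-10)
})

test_that("critical total concentration matches brute-force summation", {
  p <- params_hl1()
  ct <- critical_total_concentration(p)
  # brute-force partial sum to n = 1e6 (independent oracle)
  n <- seq_len(1e6)
  expect_equal(ct, sum(n * exp(-1.24 * sqrt(n))) / 0.58, tolerance = 1e-9)
  expect_gt(ct, critical_monomer_concentration(p))
  # strongly cohesive limit: vanishing critical totals
  expect_lt(critical_total_concentration(aggregation_params(-40, 0.58)), 1e-15)
})

test_that("the phase-transition series diverges without cohesion or boundary growth", {
  expect_error(critical_total_concentration(aggregation_params(0.5, 1)),
               "no finite critical")
  expect_error(critical_total_concentration(aggregation_params(0, 1)),
               "no finite critical")
  # linear aggregates (boundary energy independent of n) are non-critical
  linear <- aggregation_params(-1.5, 1, boundary_exponent = 0)
  expect_false(is_phase_transition_capable(linear))
  expect_error(critical_total_concentration(linear), "linear aggregates")
  expect_true(is_phase_transition_capable(params_hl1()))
})

test_that("solve_monomer_from_total agrees with an independent bisection oracle", {
  p <- params_hl1()
  cm <- solve_monomer_from_total(p, ctot = 4.3, nmax = 50)
  # frozen value from a 2000-step bisection on the direct formula
  expect_equal(cm, 0.462768492835, tolerance = 1e-9)
  expect_equal(sum(1:50 * nmer_density(p, cm, 1:50)), 4.3, tolerance = 1e-9)
  # monomer-only limit: vanishing A0 at dG = 0 leaves everything monomeric
  cm2 <- solve_monomer_from_total(aggregation_params(0, 1e-6), ctot = 2, nmax = 50)
  expect_equal(cm2, 2, tolerance = 1e-4)
})

test_that("total_concentration sums n-weighted densities", {
  expect_equal(total_concentration(size_distribution(1:3, c(2, 0, 0))), 2)
  expect_equal(total_concentration(size_distribution(1:3, c(1, 0.5, 0.2))), 2.6)
  # partial sums of the critical distribution approach the series value
  p <- params_hl1()
  expect_equal(total_concentration(critical_distribution(p, 2000)),
               critical_total_concentration(p), tolerance = 1e-6)
})

test_that("subcritical distributions decrease monotonically (property)", {
  set.seed(42)
  for (i in 1:25) {
    p <- aggregation_params(runif(1, -3, -0.2), runif(1, 0.02, 2),
                            boundary_exponent = runif(1, 0.2, 0.8))
    cmon <- runif(1) * critical_monomer_concentration(p)
    d <- nmer_density(p, cmon, 1:50)
    expect_true(all(diff(d) < 0))
  }
  # at criticality exactly, still monotone
  p <- params_hl1()
  expect_true(all(diff(nmer_density(p, critical_monomer_concentration(p), 1:50)) < 0))
})

test_that("mass-balance inversion round-trips over random parameters (property)", {
  set.seed(7)
  for (i in 1:20) {
    p <- aggregation_params(runif(1, -3, -0.3), runif(1, 0.05, 1))
    cmon <- runif(1) * critical_monomer_concentration(p)
    if (cmon <= 0) next
    n <- 1:60
    ctot <- sum(n * nmer_density(p, cmon, n))
    back <- solve_monomer_from_total(p, ctot, 60)
    expect_equal(back, cmon, tolerance = 1e-9)
  }
})
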