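test_that("driving force follows the (donor - acceptor)/1000 convention", {
  expect_equal(driving_force(-415, -415), 0)
  expect_equal(driving_force(-321, -415), 0.094)
  expect_equal(driving_force(-850, -415), -0.435)
  expect_error(driving_force(NA, -415))
})

test_that("rate law reproduces the contact intercept and worked evaluations", {
  # at contact distance and dG = -lambda both decay terms vanish
  r <- log10_tunneling_rate(3.6, -0.65)
  expect_identical(r$log10_rate, 13.0)
  expect_equal(r$rate, 1e13)
  expect_equal(r$regime, "exergonic")

  # downhill at 14.7 A (oracle: direct evaluation of the exergonic branch)
  expect_equal(log10_tunneling_rate(14.7, -0.435)$log10_rate,
               oracle_log10k(14.7, -0.435), tolerance = 1e-12)
  expect_equal(log10_tunneling_rate(14.7, -0.435)$log10_rate, 6.2083,
               tolerance = 1e-4)

  # uphill at 10 A (oracle: direct evaluation of the endergonic branch)
  up <- log10_tunneling_rate(10, 0.094)
  expect_equal(up$regime, "endergonic")
  expect_equal(up$log10_rate, oracle_log10k(10, 0.094), tolerance = 1e-12)
  expect_equal(up$log10_rate, 6.1702, tolerance = 1e-4)

  expect_warning(log10_tunneling_rate(3.0, -0.5), "contact")
})

test_that("exergonic and endergonic branches are continuous at dG = 0", {
  for (R in c(3.6, 8, 14.7, 20)) {
    lo <- log10_tunneling_rate(R, -1e-300)$log10_rate
    hi <- log10_tunneling_rate(R, 1e-300)$log10_rate
    at <- log10_tunneling_rate(R, 0)$log10_rate
    expect_equal(lo, at, tolerance = 1e-15)
    expect_equal(hi, at, tolerance = 1e-15)
    expect_equal(at, 13 - 0.592 * (R - 3.6) - 3.1 * 0.65, tolerance = 1e-12)
  }
})

test_that("detailed-balance identity links the two branches exactly", {
  set.seed(7)
  dg <- stats::runif(1000, 1e-6, 1)
  R <- stats::runif(1000, 4, 20)
  k_en <- log10_tunneling_rate(R, dg)$log10_rate
  k_ex <- log10_tunneling_rate(R, -dg)$log10_rate
  expect_equal(k_en, k_ex - dg / 0.06, tolerance = 1e-12)
})

test_that("distance decay is -0.592 decades per angstrom in both regimes", {
  for (dg in c(-0.8, -0.2, 0, 0.1, 0.4)) {
    lg <- log10_tunneling_rate(c(5, 6, 13, 14), dg)$log10_rate
    expect_equal(diff(lg)[c(1, 3)], rep(-0.592, 2), tolerance = 1e-12)
  }
  # exergonic branch peaks at dG = -lambda and is symmetric around it
  expect_equal(log10_tunneling_rate(8, -0.65 + 0.2)$log10_rate,
               log10_tunneling_rate(8, -0.65 - 0.2)$log10_rate)
  expect_gt(log10_tunneling_rate(8, -0.65)$log10_rate,
            log10_tunneling_rate(8, -0.5)$log10_rate)
})

test_that("rate grid has the documented shape and matches scalar evaluations", {
  g <- build_rate_grid()
  expect_equal(dim(g), c(33L, 17L))
  expect_equal(attr(g, "potentials"), seq(-1000, -200, 25))
  expect_equal(attr(g, "distances"), 4:20)

  # every row is strictly decreasing in distance with the fixed slope
  steps <- t(apply(unclass(g), 1, diff))
  expect_true(all(abs(steps + 0.592) < 1e-12))

  # spot cells equal standalone evaluations
  for (p in c(-850, -400, -225)) for (d in c(4, 15, 20)) {
    expect_equal(g[as.character(p), as.character(d)],
                 log10_tunneling_rate(d, driving_force(p, -415))$log10_rate)
  }

  df <- as.data.frame(g)
  expect_equal(nrow(df), 33L * 17L)
  expect_equal(df$log10_rate[df$potential_mV == -850 & df$distance_A == 15],
               g["-850", "15"])
})

test_that("threshold solvers scan the discrete grids", {
  expect_equal(max_distance_for_rate(-321, -415, 6), 10)
  expect_true(is.na(max_distance_for_rate(-321, -415, 14)))
  expect_error(max_distance_for_rate(-321, -415, 6, distances = numeric(0)),
               "empty")
  # dG = 0 case has a closed form: 13 - 0.592(R - 3.6) - 2.015 >= 6 at R <= 12.02
  expect_equal(max_distance_for_rate(-415, -415, 6), 12)

  p <- required_potential_for_rate(14.7, -415, 6)
  expect_equal(p, -775)
  expect_lte(p, -750)
  # brute force over the grid as oracle
  grid <- seq(-1000, -200, 25)
  ok <- grid[vapply(grid, function(e)
    oracle_log10k(14.7, (e + 415) / 1000) >= 6, TRUE)]
  expect_equal(p, max(ok))
  expect_true(is.na(required_potential_for_rate(3.6, -415, 13.1)))
  expect_equal(required_potential_for_rate(14.7, -415, -Inf), -200)
  expect_error(required_potential_for_rate(14.7, -415, 6,
                                           potentials = numeric(0)), "empty")
})

test_that("parameter validation rejects unphysical constants", {
  expect_error(tunneling_params(lambda_reorg = -1))
  expect_error(tunneling_params(rho = 1.4))
  p <- tunneling_params(rho = 0.5)
  expect_equal(log10_tunneling_rate(4.6, -0.65, p)$log10_rate, 13 - 0.8)
})
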