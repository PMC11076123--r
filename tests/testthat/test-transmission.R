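test_that("inclusion-exclusion probability matches brute-force enumeration", {
  expect_equal(prob_full_transmission(1, 5), 1)
  expect_equal(prob_full_transmission(c(0.5, 0.5), 2), 0.5)
  # 1 - 0.9^3 - 0.1^3 = 0.270
  expect_equal(prob_full_transmission(c(0.9, 0.1), 3), 0.270,
               tolerance = 1e-12)
  expect_equal(enumerate_full_prob(c(0.9, 0.1), 3), 0.270, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:3, 1)
    n <- sample(k:6, 1)
    p <- random_composition(k)
    expect_equal(prob_full_transmission(p, n), enumerate_full_prob(p, n),
                 tolerance = 1e-10)
  }
})

test_that("analytic probability has the right limits and monotonicity", {
  set.seed(11)
  grid <- seq(500L, 10000L, by = 500L)
  for (i in 1:25) {
    k <- sample(2:10, 1)
    p <- random_composition(k)
    eff <- prob_full_transmission(p, grid)
    expect_true(all(diff(eff) >= -1e-12))
    expect_true(all(eff >= 0 & eff <= 1))
    # fewer draws than groups cannot cover the community
    expect_identical(prob_full_transmission(p, k - 1L), 0)
    expect_gte(prob_full_transmission(p, 1000000L), 1 - 1e-6)
  }
})

test_that("zero-proportion groups force zero under the strict criterion", {
  p <- c(0.6, 0.4, 0)
  expect_equal(prob_full_transmission(p, 100), 0)
  expect_gt(prob_full_transmission(p, 100, require_all = FALSE), 0.99)
  expect_equal(transmission_efficiency(p, 100, iterations = 50, seed = 1), 0)
})

test_that("analytic mode refuses infeasibly large panels", {
  expect_error(prob_full_transmission(rep(1 / 26, 26), 100), "Monte-Carlo")
})

test_that("presence sampling honours determinism and impossible species", {
  p <- c(a = 0.7, b = 0.3, c = 0)
  expect_identical(unname(sample_transmission(p, 0, seed = 1)),
                   rep(FALSE, 3))
  expect_identical(unname(sample_transmission(1, 5, seed = 1)), TRUE)
  draw1 <- sample_transmission(p, 50, seed = 42)
  draw2 <- sample_transmission(p, 50, seed = 42)
  expect_identical(draw1, draw2)
  set.seed(3)
  for (i in 1:25) expect_false(sample_transmission(p, 20)[["c"]])
  expect_error(sample_transmission(p, -1), "non-negative")
})

test_that("Monte-Carlo efficiency agrees with the analytic value", {
  expect_equal(transmission_efficiency(1, 1, iterations = 100, seed = 1), 1)
  # closed form P = 0.5; binomial 4-sigma half-width at I = 5000 is 0.028
  eff <- transmission_efficiency(c(0.5, 0.5), 2, iterations = 5000, seed = 9)
  expect_lt(abs(eff - 0.5), 0.028)
  expect_error(transmission_efficiency(c(0.5, 0.5), 2, iterations = 0),
               "positive integer")
})

test_that("the fitted curve is reproducible and validates its grid", {
  p <- random_composition(5)
  m1 <- transmission_model(p, n_grid = seq(100L, 1000L, 100L),
                           iterations = 300, seed = 5)
  m2 <- transmission_model(p, n_grid = seq(100L, 1000L, 100L),
                           iterations = 300, seed = 5)
  expect_identical(m1$efficiency, m2$efficiency)
  expect_length(m1$efficiency, 10)
  expect_true(all(m1$efficiency >= 0 & m1$efficiency <= 1))
  expect_error(transmission_model(p, n_grid = c(10, 10, 20)), "strictly")
  expect_error(transmission_model(p, n_grid = c(-5, 10)), "strictly")

  a <- transmission_model(c(0.5, 0.5), n_grid = c(1L, 2L), mode = "analytic")
  expect_equal(a$efficiency, c(0, 0.5))
})

test_that("model methods expose composition, predictions and residuals", {
  comp <- default_compositions()$nymph
  m <- transmission_model(comp, n_grid = seq(500L, 3000L, 500L),
                          iterations = 500, seed = 2)
  expect_named(coef(m), comp$species_groups)
  expect_equal(sum(coef(m)), 1, tolerance = 1e-12)
  expect_equal(predict(m, 1500L),
               prob_full_transmission(comp, 1500L))
  expect_equal(residuals(m), m$efficiency - predict(m))
  a <- transmission_model(comp, n_grid = seq(500L, 3000L, 500L),
                          mode = "analytic")
  expect_equal(residuals(a), rep(0, 6))

  pres <- simulate(m, nsim = 8, seed = 4, n_cells = 2000)
  expect_identical(dim(pres), c(8L, 10L))
  expect_identical(pres, simulate(m, nsim = 8, seed = 4, n_cells = 2000))
  expect_type(pres[1, 1], "logical")

  expect_output(print(m), "Transmission-efficiency model")
  expect_output(print(summary(m)), "Analytic reference minimum")
})

test_that("minimum-cells search respects the grid and threshold", {
  m <- transmission_model(1, n_grid = c(100L, 200L), mode = "analytic")
  expect_identical(min_cells(m)$min_cells, 100L)

  # 1 - 0.99^N - 0.01^N: 0.9934 at N = 500, 0.99996 at N = 1000
  m2 <- transmission_model(c(0.99, 0.01), mode = "analytic")
  expect_identical(min_cells(m2, threshold = 0.999)$min_cells, 1000L)

  # not reached on the grid
  m3 <- transmission_model(c(0.999, 0.001), n_grid = c(100L, 200L),
                           mode = "analytic")
  expect_true(is.na(min_cells(m3, threshold = 0.99)$min_cells))

  expect_error(min_cells(m2, threshold = 0), "in \\(0, 1\\]")
  expect_error(min_cells(m2, threshold = 1.5), "in \\(0, 1\\]")
})

test_that("bisection refinement finds the exact analytic boundary", {
  comp <- c(0.99, 0.01)
  m <- transmission_model(comp, mode = "analytic")
  r <- min_cells(m, threshold = 0.999, refine = TRUE)
  expect_gte(prob_full_transmission(comp, r$min_cells), 0.999)
  expect_lt(prob_full_transmission(comp, r$min_cells - 1L), 0.999)
  expect_lte(r$min_cells, 1000L)
  # refinement requires the analytic mode
  mc <- transmission_model(comp, n_grid = c(500L, 1000L), iterations = 50,
                           seed = 1)
  expect_error(min_cells(mc, refine = TRUE), "analytic")
})

test_that("a rarer rarest species never needs fewer cells", {
  qs <- c(0.05, 0.02, 0.01, 0.005, 0.002)
  mins <- vapply(qs, function(q) {
    m <- transmission_model(c(1 - q, q), mode = "analytic")
    min_cells(m, threshold = 0.999, refine = TRUE)$min_cells
  }, integer(1))
  # decreasing min(p) => non-decreasing minimum N
  expect_true(all(diff(mins) >= 0))
})
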