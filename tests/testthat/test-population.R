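# population_sim: seeded sampling, oracle agreement, bimodality, sweeps.

test_that("fixed-component populations are deterministic pass/fail", {
  fx <- function(v) component_dist("fixed", value = v)
  cfg <- population_config(50, fx(1), fx(1), fx(1), fx(1),
                           gate = gate_params(0.5), seed = 1)
  expect_equal(sample_population(cfg)$fraction_initiating, 1)
  cfg2 <- population_config(50, fx(0.9), fx(0.8), fx(0.6), fx(1),
                            gate = gate_params(0.5), seed = 1)
  expect_equal(sample_population(cfg2)$fraction_initiating, 0)  # 0.432 < 0.5
})

test_that("identical configs give bit-identical results", {
  cfg <- population_config(500, gate = gate_params(0.3), seed = 99)
  r1 <- sample_population(cfg)
  r2 <- sample_population(cfg)
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$fraction_initiating, r2$fraction_initiating)
})

test_that("editing one component's distribution leaves other streams alone", {
  cfg1 <- population_config(100, seed = 5)
  cfg2 <- population_config(100,
                            dist_D = component_dist("beta", 5, 1), seed = 5)
  r1 <- sample_population(cfg1); r2 <- sample_population(cfg2)
  expect_identical(r1$cells$A, r2$cells$A)
  expect_identical(r1$cells$C, r2$cells$C)
  expect_false(identical(r1$cells$D, r2$cells$D))
})

test_that("veto propagation: one component fixed at 0 kills initiation", {
  cfg <- population_config(200,
                           dist_C = component_dist("fixed", value = 0),
                           gate = gate_params(0.2), seed = 2)
  expect_equal(sample_population(cfg)$fraction_initiating, 0)
})

test_that("oracle limits and grid-refinement stability", {
  b <- component_dist("beta", 2, 2)
  expect_equal(firing_probability_oracle(b, b, b, 1, 0), 1)
  # threshold above phi is impossible since the product is at most 1
  expect_equal(firing_probability_oracle(b, b, b, 0.4, 0.5), 0)
  p1 <- firing_probability_oracle(b, b, b, 1, 0.25, 200)
  p2 <- firing_probability_oracle(b, b, b, 1, 0.25, 400)
  expect_lt(abs(p1 - p2), 5e-4)
  # one-beta route agrees with the closed-form beta tail
  f <- component_dist("fixed", value = 0.8)
  expect_equal(firing_probability_oracle(f, f, b, 1, 0.3),
               stats::pbeta(0.3 / 0.64, 2, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(firing_probability_oracle(b, b, b, 1, 0.5, 50), ">= 100")
})

test_that("Monte-Carlo fractions agree with the quadrature oracle", {
  b <- component_dist("beta", 2, 2)
  cfg <- population_config(10000, b, b, b,
                           component_dist("fixed", value = 1),
                           gate = gate_params(0.25), seed = 17)
  res <- sample_population(cfg)
  p <- firing_probability_oracle(b, b, b, 1, 0.25)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(res$fraction_initiating - p), 3 * se)
})

test_that("bimodality coefficient follows its moment formula", {
  # explicit two-point mixture: moments known in closed form
  x <- c(rep(0, 50), rep(1, 50))
  n <- length(x)
  # skew 0, excess kurtosis of a balanced Bernoulli is -2
  expected <- (0 + 1) / (-2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  expect_equal(bimodality_coefficient(x), expected)
  expect_gt(bimodality_coefficient(x), BIMODALITY_BENCHMARK)
  # tight clusters at the ends stay firmly bimodal
  set.seed(8)
  y <- c(rnorm(500, 0.05, 0.01), rnorm(500, 0.95, 0.01))
  expect_gt(bimodality_coefficient(y), BIMODALITY_BENCHMARK)
  # one narrow unimodal beta stays below the benchmark
  z <- rbeta(10000, 50, 50)
  expect_lt(bimodality_coefficient(z), BIMODALITY_BENCHMARK)
  expect_error(bimodality_coefficient(c(1, 2, 3)), "at least 4")
  expect_warning(bc <- bimodality_coefficient(rep(0.4, 10)), "degenerate")
  expect_true(is.na(bc))
})

test_that("near-threshold beta populations split into two large groups", {
  b <- component_dist("beta", 2, 2)
  # median of the Beta(2,2)^3 product score places T at the 50% point
  med <- uniroot(function(t)
    firing_probability_oracle(b, b, b, 1, t) - 0.5, c(0.01, 0.9))$root
  cfg <- population_config(4000, b, b, b,
                           component_dist("fixed", value = 1),
                           gate = gate_params(med), seed = 21)
  res <- sample_population(cfg)
  expect_gte(res$fraction_initiating, 0.25)
  expect_gte(1 - res$fraction_initiating, 0.25)
  expect_gt(res$bimodality_coefficient, BIMODALITY_BENCHMARK)
})

test_that("ensemble averages collect sweeps monotonically", {
  b <- component_dist("beta", 2, 2)
  fx1 <- component_dist("fixed", value = 1)
  sweep <- seq(1, 0, by = -0.25)
  results <- lapply(sweep, function(thr) {
    tt <- max(thr, 1e-9)  # gate threshold must stay positive
    sample_population(population_config(2000, b, b, b, fx1,
                                        gate = gate_params(tt), seed = 4))
  })
  names(results) <- sprintf("T=%.2f", sweep)
  tab <- ensemble_average(results)
  expect_identical(nrow(tab), length(sweep))
  # lowering T can only raise the initiating fraction (same seed/draws)
  expect_true(all(diff(tab$fraction_initiating) >= 0))
  # identical config rows are identical; single condition is the identity
  one <- ensemble_average(list(only = results[[1]]))
  expect_equal(one$fraction_initiating, results[[1]]$fraction_initiating)
  expect_identical(
    ensemble_average(results[c(1, 1)])$fraction_initiating,
    rep(results[[1]]$fraction_initiating, 2))
})
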