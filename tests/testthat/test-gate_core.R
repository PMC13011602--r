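# gate_core: state validation, composite score, hard and graded gates,
# normalization, threshold surface, grid classification.

test_that("readiness states validate and the composite score is the product", {
  expect_equal(composite_readiness(readiness_state(1, 1, 0, 1)), 0)
  expect_equal(composite_readiness(readiness_state(1, 1, 1, 1)), 1)
  expect_equal(composite_readiness(readiness_state(0.9, 0.8, 0.7, 0.5)),
               0.252)
  expect_error(readiness_state(1.2, 1, 1), "A")
  expect_error(readiness_state(1, -0.1, 1), "D")
  expect_error(readiness_state(1, 1, NA), "C")
  expect_error(readiness_state(1, 1, 1, 2), "phi")
})

test_that("hard gate is boundary inclusive and vetoed by phi = 0", {
  r <- gate_decision(readiness_state(0.9, 0.8, 0.7, 0.5), gate_params(0.5))
  expect_false(r$fired)
  expect_equal(r$margin, -0.248)
  # score exactly at threshold fires (>= T), including the extreme T = 1
  expect_true(gate_decision(readiness_state(1, 1, 1, 1),
                            gate_params(1))$fired)
  # G0/M veto: phi = 0 blocks firing for any positive threshold
  for (thr in c(1e-6, 0.3, 1))
    expect_false(gate_decision(readiness_state(1, 1, 1, 0),
                               gate_params(thr))$fired)
})

test_that("graded response matches an independent Hill evaluation", {
  ss <- seq(0, 1, by = 0.05)
  for (k in c(1, 4, 8, 32)) {
    expect_equal(hill_response(ss, 0.5, k), oracle_hill(ss, 0.5, k),
                 tolerance = 1e-12)
  }
  # midpoint, zero-veto, hard-gate limit
  expect_equal(hill_response(0.5, 0.5, 8), 0.5)
  expect_equal(hill_response(0.3, 0.3, 200), 0.5)
  expect_equal(hill_response(0, 0.5, 8), 0)
  expect_lt(hill_response(0.45, 0.5, 400), 1e-6)
  expect_gt(hill_response(0.55, 0.5, 400), 1 - 1e-6)
  expect_equal(graded_response(readiness_state(1, 0.75, 1, 1),
                               gate_params(0.5, 8)),
               oracle_hill(0.75, 0.5, 8))
})

test_that("normalization is the stated linear map with clamp semantics", {
  sp <- normalization_spec(10, 30, clamp = TRUE)
  expect_equal(normalize_correlate(10, sp), 0)
  expect_equal(normalize_correlate(20, sp), 0.5)
  expect_equal(normalize_correlate(30, sp), 1)
  expect_equal(normalize_correlate(45, sp), 1)   # clipped
  expect_equal(normalize_correlate(-5, sp), 0)   # clipped
  strict <- normalization_spec(10, 30, clamp = FALSE)
  expect_error(normalize_correlate(31, strict), "outside")
  expect_error(normalization_spec(5, 5), "strictly less")
})

test_that("threshold surface inverts the gate and responds to phi", {
  expect_equal(threshold_surface_C(1, 1, 1, gate_params(0.5))$C_star, 0.5)
  un <- threshold_surface_C(1, 0.4, 1, gate_params(0.5))
  expect_false(un$defined)
  expect_identical(un$reason, "unreachable")
  zv <- threshold_surface_C(0, 1, 1, gate_params(0.5))
  expect_identical(zv$reason, "zero-veto")
  # raising phi strictly lowers C* whenever defined
  cs <- vapply(seq(0.6, 1, by = 0.1), function(p)
    threshold_surface_C(0.95, 0.95, p, gate_params(0.5))$C_star, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("surface consistency: gate fires at C* and not below", {
  set.seed(11)
  n_checked <- 0L
  for (i in 1:300) {
    A <- runif(1); D <- runif(1); phi <- runif(1)
    thr <- runif(1, 0.05, 1)
    gp <- gate_params(thr)
    sp <- threshold_surface_C(A, D, phi, gp)
    if (!sp$defined) next
    n_checked <- n_checked + 1L
    expect_true(gate_decision(readiness_state(A, D, sp$C_star, phi),
                              gp)$fired)
    below <- sp$C_star * (1 - 1e-6)
    expect_false(gate_decision(readiness_state(A, D, below, phi), gp)$fired)
  }
  expect_gt(n_checked, 20)
})

test_that("score properties hold on random states", {
  st <- random_states(1000, seed = 3)
  s <- st$phi * st$A * st$D * st$C
  expect_true(all(s >= 0 & s <= 1))
  # permutation symmetry in (A, D, C)
  perm <- st$phi * st$C * st$A * st$D
  expect_equal(s, perm)
  # monotone in each component, strict when others positive
  for (i in sample.int(1000, 50)) {
    base <- composite_readiness(readiness_state(st$A[i], st$D[i], st$C[i],
                                                st$phi[i]))
    bumped <- composite_readiness(readiness_state(min(1, st$A[i] + 0.1),
                                                  st$D[i], st$C[i],
                                                  st$phi[i]))
    expect_gte(bumped, base)
    if (st$D[i] > 0 && st$C[i] > 0 && st$phi[i] > 0 && st$A[i] < 0.9)
      expect_gt(bumped, base)
  }
  # zero-veto
  expect_equal(composite_readiness(readiness_state(0, 1, 1, 1)), 0)
  expect_equal(composite_readiness(readiness_state(1, 1, 1, 0)), 0)
})

test_that("classify_grid matches exhaustive enumeration and expands with phi", {
  for (r in c(5, 11)) {
    for (phi in c(0.6, 1)) {
      cm <- classify_grid(r, phi, gate_params(0.5))
      expect_identical(cm$n_competent, oracle_grid_count(r, phi, 0.5))
      expect_equal(nrow(cm$grid), r^3)
    }
  }
  # near-zero threshold: all strictly positive lattice points competent
  cm <- classify_grid(11, 1, gate_params(1e-9))
  expect_identical(cm$n_competent, 1000L)
  # phi = 0 vetoes the whole lattice
  expect_identical(classify_grid(7, 0, gate_params(0.3))$n_competent, 0L)
  # competent count nondecreasing in phi
  counts <- vapply(seq(0, 1, by = 0.1), function(p)
    classify_grid(9, p, gate_params(0.4))$n_competent, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(classify_grid(1), "resolution")
})
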