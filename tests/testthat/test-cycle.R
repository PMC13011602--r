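# cycle_dynamics: schedule/permissiveness, once-per-cycle firing,
# checkpoint arrest and recovery, timing order, ODE behavior.

make_origins <- function(n = 30, seed = 1) {
  set.seed(seed)
  origin_frame(A = runif(n, 0.5, 1), D = runif(n, 0.5, 1),
               C = runif(n, 0.3, 1), threshold = 0.5)
}

test_that("phi_at follows the schedule and multiplies event scales", {
  sch <- default_schedule()
  expect_equal(phi_at(sch, 0), 0.3)          # start of the G1 ramp
  expect_equal(phi_at(sch, 10), 1.0)         # late G1/S: permissive
  expect_equal(phi_at(sch, 14), 1.0)         # mid S
  expect_equal(phi_at(sch, 22.5), 0.01)      # mitosis: essentially vetoed
  expect_equal(phi_at(sch, 5), 0.3 + 0.7 * 0.5)  # linear ramp midpoint
  ev <- list(checkpoint_event(12, 16, phi_scale = 0.1))
  expect_equal(phi_at(sch, 14, ev), 0.1)
  expect_equal(phi_at(sch, 11, ev), 1.0)     # outside the window
  zero <- list(checkpoint_event(0, 23, phi_scale = 0))
  expect_equal(phi_at(sch, 14, zero), 0)     # multiplicative veto
  expect_error(phi_at(sch, 25), "outside")
  # G0-only schedule stays at its configured level
  g0 <- phase_schedule("G0", 10, 0)
  expect_equal(phi_at(g0, 5), 0)
})

test_that("a G0 schedule produces no firings and R decays to zero", {
  g0 <- phase_schedule("G0", 10, 0)
  tr <- simulate_cycle(make_origins(), g0, dynamic_params(dt = 0.01))
  expect_identical(nrow(tr$firings), 0L)
  expect_equal(max(tr$R), 0)
})

test_that("once-per-cycle rule: each origin fires at most once", {
  sch <- default_schedule()
  for (seed in 1:10) {
    orig <- make_origins(40, seed)
    tr <- simulate_cycle(orig, sch,
                         dynamic_params(noise_sd = 0.05, seed = seed))
    counts <- table(tr$firings$id)
    expect_true(all(counts <= 1))
    expect_lte(nrow(tr$firings), nrow(orig))
    # fire_time recorded consistently, firings time-ordered
    expect_true(all(!is.na(tr$origins$fire_time[tr$origins$fired])))
    expect_true(!is.unsorted(tr$firings$time))
    # no firings while permissiveness is at the mitotic floor
    m_start <- sum(sch$duration[1:3])
    expect_true(all(tr$firings$time < m_start | tr$firings$time >= 23))
  }
})

test_that("mid-S checkpoint suppresses in-window firing reversibly", {
  sch <- default_schedule()
  # origins whose crossing times spread across the G1 ramp and S
  orig <- origin_frame(A = 1, D = 1, C = seq(0.5, 1, length.out = 20),
                       threshold = 0.5)
  ev <- list(checkpoint_event(13, 15, phi_scale = 0.1, D_scale = 0.8))
  tr_free <- simulate_cycle(orig, sch, dynamic_params())
  tr_cp <- simulate_cycle(orig, sch, dynamic_params(), events = ev)
  # zero firings inside the arrest window
  expect_false(any(tr_cp$firings$time >= 13 & tr_cp$firings$time < 15))
  # arrest delays but does not abolish: same set of ever-firing origins
  expect_setequal(tr_cp$firings$id, tr_free$firings$id)
  # an identity event changes nothing
  tr_id <- simulate_cycle(orig, sch, dynamic_params(),
                          events = list(checkpoint_event(13, 15, 1, 1)))
  expect_identical(tr_id$firings, tr_free$firings)
})

test_that("arrest_report recovers intervals from the score series", {
  sch <- default_schedule()
  orig <- origin_frame(A = 0.95, D = 0.95, C = 0.9, threshold = 0.5)
  ev <- list(checkpoint_event(13, 15, phi_scale = 0.1))
  tr <- simulate_cycle(orig, sch, dynamic_params(), events = ev)
  rep_ <- arrest_report(tr)
  # independent scan of the stored series
  below <- tr$score < tr$gate$threshold
  expect_identical(nrow(rep_), length(rle(below)$values[rle(below)$values]))
  covers <- any(rep_$t_start <= 13 + 1e-9 & rep_$t_end >= 15 - 1e-9)
  expect_true(covers)
  # a permissive stretch with score always above threshold reports nothing
  # (origins with threshold 1 never fire, so no consumption dip)
  flat <- phase_schedule("S", 8, 1)
  quiet <- origin_frame(A = 0.95, D = 0.95, C = 0.9, threshold = 1)
  tr2 <- simulate_cycle(quiet, flat, dynamic_params(),
                        gate = gate_params(0.5))
  expect_identical(nrow(arrest_report(tr2)), 0L)
})

test_that("threshold-crossing times are exact and ordered by readiness", {
  sch <- default_schedule()
  eu <- list(A = 1, D = 0.9, C = 0.7, threshold = 0.5)
  het <- list(A = 0.45, D = 0.9, C = 0.3, threshold = 0.5)
  t_eu <- time_to_threshold(eu, sch)
  t_het <- time_to_threshold(het, sch)
  # closed form on the G1 ramp: 0.3 + 0.07 t = T / (A D C)
  expect_equal(t_eu, (0.5 / (1 * 0.9 * 0.7) - 0.3) / 0.07, tolerance = 1e-9)
  expect_true(is.na(t_het))  # product 0.1215 < T even at full permissiveness
  # monotone: nonincreasing in each component, nondecreasing in threshold
  base <- list(A = 0.9, D = 0.9, C = 0.9, threshold = 0.5)
  t0 <- time_to_threshold(base, sch)
  for (f in c("A", "D", "C")) {
    worse <- base; worse[[f]] <- 0.75
    expect_gte(time_to_threshold(worse, sch), t0)
  }
  higher <- base; higher$threshold <- 0.7
  expect_gte(time_to_threshold(higher, sch), t0)
  # identical origins, identical times; unreachable product gives none
  expect_identical(time_to_threshold(base, sch), t0)
  # simulate_cycle fires within one step of the exact crossing time
  orig <- origin_frame(A = 1, D = 0.9, C = 0.7, threshold = 0.5)
  tr <- simulate_cycle(orig, sch, dynamic_params(dt = 0.01))
  expect_lt(abs(tr$firings$time[1] - t_eu), 0.011)
})

test_that("constant-score integration reaches the closed-form steady state", {
  flat <- phase_schedule("S", 10, 1)
  # origins that never fire (threshold 1 > any sub-unit score)
  orig <- origin_frame(A = 0.9, D = 0.9, C = 0.9, threshold = 1)
  par <- dynamic_params(k_act = 2, gamma = 1, dt = 0.01)
  tr <- simulate_cycle(orig, flat, par, gate = gate_params(0.5, 8))
  s <- 0.9^3
  target <- par$k_act * hill_response(s, 0.5, 8) / par$gamma
  # at t = 10/gamma the transient has decayed to exp(-10)
  expect_equal(tr$R[length(tr$R)], target, tolerance = 0.01)
  expect_true(all(tr$R >= 0 & tr$R <= par$k_act / par$gamma))
})

test_that("noise-free runs are bit-reproducible; noisy runs seed-reproducible", {
  sch <- default_schedule()
  orig <- make_origins(20, 3)
  a <- simulate_cycle(orig, sch, dynamic_params())
  b <- simulate_cycle(orig, sch, dynamic_params())
  expect_identical(a$R, b$R)
  expect_identical(a$firings, b$firings)
  n1 <- simulate_cycle(orig, sch, dynamic_params(noise_sd = 0.05, seed = 9))
  n2 <- simulate_cycle(orig, sch, dynamic_params(noise_sd = 0.05, seed = 9))
  n3 <- simulate_cycle(orig, sch, dynamic_params(noise_sd = 0.05, seed = 10))
  expect_identical(n1$R, n2$R)
  expect_false(identical(n1$R, n3$R))
})

test_that("degenerate inputs are handled", {
  sch <- default_schedule()
  empty <- origin_frame(A = numeric(0), D = numeric(0), C = numeric(0))
  tr <- simulate_cycle(empty, sch, dynamic_params())
  expect_identical(nrow(tr$firings), 0L)
  expect_error(simulate_cycle(make_origins(5), sch,
                              dynamic_params(dt = 0.7)), "divide")
  expect_error(phase_schedule("S", -1, 1), "positive")
  expect_error(checkpoint_event(5, 3), "t_start")
  expect_error(origin_frame(A = 1, D = 1, C = 1, threshold = 0),
               "threshold")
})
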