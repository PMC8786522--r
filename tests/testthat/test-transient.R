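test_that("stability limits reproduce the per-layer bounds from the published constants", {
  ct <- preset_scenario("case1_38C", mode = "transient")
  # rho c h^2 / (6 k + h^2 mb cb) at h = 2 mm: scalp 7.508416, skull 2.4749,
  # CSF 6.379862 s -> the three-layer minimum is the skull's
  expect_equal(stability_limit(ct), 2.4749, tolerance = 1e-6)

  one_layer <- function(p) stability_limit(box_config(
    props = p, shared = shared_constants(TA = 38, Tw = 7)))
  expect_equal(one_layer(tissue_properties(0.342, 1070, 3600)), 7.508416, tolerance = 1e-6)
  expect_equal(one_layer(tissue_properties(0.217, 880, 2360, 300)), 6.379862, tolerance = 1e-6)

  # k -> 0 limit tends to rho c / (mb cb)
  tiny <- one_layer(tissue_properties(1e-9, 1070, 3600))
  expect_equal(tiny, 1070 * 3600 / (6.06e-3 * 4010), tolerance = 1e-4)
})

test_that("explicit stepper refuses unstable steps and keeps weights non-negative at the bound", {
  ct <- preset_scenario("case1_38C", mode = "transient")
  st <- transient_state(initial_field(ct))
  lim <- stability_limit(ct)
  expect_error(ftcs_step(st, lim * 1.01, ct), "stability limit")
  expect_silent(st2 <- ftcs_step(st, lim, ct))
  w <- update_weights(ct, lim)
  expect_true(all(w$self >= -1e-12))
  expect_true(all(w$neighbour >= 0) && all(w$arterial >= 0))
  # just above the bound the binding (skull) self-weight goes negative
  expect_lt(min(update_weights(ct, lim * 1.05)$self), 0)
})

test_that("a uniform equilibrium field is an exact fixed point", {
  cfg <- box_config(props = tissue_properties(k = 0.5, rho = 1000, c = 3000, Qm = 0),
                    shared = shared_constants(mb = 5e-3, TA = 38, Tw = 38, he = 0),
                    deep = "neumann_zero")
  f <- initial_field(cfg); f$T[] <- 38
  st <- ftcs_step(transient_state(f), 1, cfg)
  expect_identical(st$field$T, f$T)
})

test_that("the stencil conserves trapezoid-weighted energy on an insulated grid", {
  cfg <- box_config(props = tissue_properties(k = 0.5, rho = 1000, c = 3000, Qm = 0),
                    shared = shared_constants(mb = 0, TA = 20, Tw = 20, he = 0),
                    deep = "neumann_zero")
  f <- initial_field(cfg); f$T[] <- 20; f$T[3, 3, 3] <- 40 # single hot node
  wt <- rep(1, 5); wt[c(1, 5)] <- 0.5
  W <- array(outer(outer(wt, wt), wt), dim = c(5, 5, 5))
  st <- transient_state(f)
  for (s in 1:40) st <- ftcs_step(st, 2, cfg)
  expect_equal(sum(W * st$field$T), sum(W * f$T), tolerance = 1e-12)
  expect_gt(min(st$field$T), 20 - 1e-12) # no undershoot below initial range
  expect_lt(max(st$field$T), 40 + 1e-12)
})

test_that("the long-time transient reproduces the steady solution", {
  cfg <- preset_scenario("case1_38C") # clamped surface, constant boundaries
  res <- run_transient(cfg, t_end = 7200, output_times = 7200)
  dev <- max(abs(res$fields[[1]]$T - solve_steady(cfg)$T))
  expect_lte(dev, 1e-3)
})

test_that("backward Euler is stable far above the explicit limit and finds the same steady state", {
  cfg <- preset_scenario("case1_38C")
  res <- run_transient(cfg, t_end = 7200, output_times = 7200,
                       method = "backward_euler", dt = 60)
  expect_true(all(is.finite(res$fields[[1]]$T)))
  expect_lte(max(abs(res$fields[[1]]$T - solve_steady(cfg)$T)), 1e-2)
})

test_that("substep refinement converges at first order in time", {
  base <- preset_scenario("case1_38C", mode = "transient")
  at6 <- function(safety) {
    cfg <- base; cfg$safety_factor <- safety
    run_transient(cfg)$fields[[3]]$T
  }
  d1 <- max(abs(at6(0.8) - at6(0.4)))   # dt ~ 2.0 s vs 1.0 s
  d2 <- max(abs(at6(0.4) - at6(0.2)))
  expect_equal(d2 / d1, 0.5, tolerance = 0.2)       # O(dt) self-consistency
  d3 <- max(abs(at6(0.02) - at6(0.01))) # dt ~ 0.05 s: changes below a millidegree
  expect_lt(d3, 1e-3)
})

test_that("mirror symmetry of the initial condition is preserved at every step", {
  cfg <- preset_scenario("case2_39_5C", mode = "transient")
  f <- initial_field(cfg)
  bump <- outer(outer(rep(1, 5), c(1, 2, 3, 2, 1)), c(2, 1, 4, 1, 2))
  f$T <- f$T + 0.1 * array(bump, dim = c(5, 5, 5)) # symmetric perturbation
  st <- transient_state(f)
  for (s in 1:25) {
    st <- ftcs_step(st, 2, cfg)
    expect_identical(st$field$T, st$field$T[, 5:1, ])
    expect_identical(st$field$T, st$field$T[, , 5:1])
  }
})

test_that("initial-condition differences are forgotten by the stable scheme", {
  cfg <- preset_scenario("case1_38C", mode = "transient")
  noisy <- initial_field(cfg)
  set.seed(7)
  noise <- array(stats::runif(125, -2, 2), dim = c(5, 5, 5))
  noise[1, , ] <- 0; noise[5, , ] <- 0
  noisy$T <- noisy$T + noise
  run_from <- function(f0) {
    st <- transient_state(f0)
    for (s in 1:300) st <- ftcs_step(st, 2, cfg)
    st$field$T
  }
  d0 <- max(abs(noise))
  d1 <- max(abs(run_from(noisy) - run_from(initial_field(cfg))))
  expect_lt(d1, 0.05 * d0)
})

test_that("run_transient honours schedule, captures and reset semantics", {
  cfg <- preset_scenario("case1_38C", mode = "transient")
  res <- run_transient(cfg, output_times = c(0, 120, 240, 360))
  expect_equal(res$times, c(0, 120, 240, 360))
  expect_equal(res$fields[[1]]$T, initial_field(cfg)$T) # t = 0 capture
  # captures happen before the reset: the skin has rewarmed above Tw
  expect_gt(field_at(res$fields[[2]], 0, 0, 0), cfg$shared$Tw + 1)

  curve <- cooling_curve(res, c(0, 0, 0))
  expect_equal(curve$t_s, c(0, 120, 240, 360))
  expect_equal(curve$T_C[1], 7)
  expect_error(cooling_curve(res, c(9, 0, 0)), "outside")

  expect_error(run_transient(cfg, output_times = numeric(0)), "empty")
  expect_error(run_transient(cfg, t_end = 360, output_times = c(0, 400)), "t_end")

  # a constant-in-time problem gives a constant cooling curve
  eq <- box_config(props = tissue_properties(k = 0.5, rho = 1000, c = 3000, Qm = 0),
                   shared = shared_constants(mb = 0, TA = 30, Tw = 30, he = 50))
  flat <- run_transient(eq, t_end = 240, output_times = c(0, 120, 240))
  expect_equal(diff(cooling_curve(flat, c(2, 1, -1))$T_C), c(0, 0), tolerance = 1e-12)
})
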