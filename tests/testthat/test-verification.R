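scalp_props <- function(Qm = 0) tissue_properties(k = 0.342, rho = 1070, c = 3600, Qm = Qm)

test_that("the closed slab form satisfies the fin ODE and its limits", {
  p <- slab_problem(scalp_props(Qm = 1800),
                    shared_constants(TA = 38, Tw = 7, he = 200), L = 8e-3)
  hf <- 2e-5
  xs <- seq(hf, p$L - hf, length.out = 100)
  Tpp <- (analytic_slab(p, xs + hf) - 2 * analytic_slab(p, xs) +
            analytic_slab(p, xs - hf)) / hf^2
  w <- p$shared$mb * p$shared$cb
  resid <- p$props$k * Tpp - w * (analytic_slab(p, xs) - p$shared$TA) + p$props$Qm
  expect_lt(max(abs(resid)), 1e-3) # terms are O(1e3); FD step chosen for round-off

  # insulated surface, no sources: perfusion equilibrium at TA
  p0 <- slab_problem(scalp_props(), shared_constants(TA = 38, Tw = 7, he = 0), L = 8e-3)
  expect_equal(analytic_slab(p0, seq(0, 8e-3, length.out = 9)), rep(38, 9))

  # enormous he: Robin collapses onto the Dirichlet cloth temperature
  pD <- slab_problem(scalp_props(), shared_constants(TA = 38, Tw = 7, he = 1e7), L = 8e-3)
  expect_lt(abs(analytic_slab(pD, 0) - 7), 1e-3)

  # zero perfusion takes the quadratic branch; ends must still be honoured
  pq <- slab_problem(tissue_properties(k = 0.5, rho = 1000, c = 3000, Qm = 500),
                     shared_constants(mb = 0, TA = 38, Tw = 7, he = 150), L = 8e-3)
  expect_equal(analytic_slab(pq, pq$L), 38)
  flux <- (analytic_slab(pq, 1e-7) - analytic_slab(pq, 0)) / 1e-7
  expect_equal(pq$props$k * flux, pq$shared$he * (analytic_slab(pq, 0) - 7),
               tolerance = 1e-4)
  expect_error(analytic_slab(pq, 9e-3), "outside")
})

test_that("closed form and dense 1D finite differences agree (frozen oracle values)", {
  # published scalp slab: L = 8 mm, TA = 38, Tw = 7, he = 0.64, no sources
  p <- slab_problem(scalp_props(), shared_constants(TA = 38, Tw = 7, he = 0.64), L = 8e-3)
  # values computed once from the cosh/sinh form and cross-checked against
  # a 10000-node dense solve (agreement 8.6e-8 C)
  expect_equal(analytic_slab(p, 0), 37.5434334473, tolerance = 1e-9)
  expect_equal(analytic_slab(p, 4e-3), 37.7718464264, tolerance = 1e-9)
  fd <- fd_slab_1d(p, n = 4000L)
  expect_lt(max(abs(analytic_slab(p, fd$x) - fd$T_C)), 1e-6)
  # and for the Dirichlet-surface branch
  pd <- slab_problem(scalp_props(), shared_constants(TA = 38, Tw = 7), L = 8e-3,
                     surface = "dirichlet")
  fdd <- fd_slab_1d(pd, n = 4000L)
  expect_lt(max(abs(analytic_slab(pd, fdd$x) - fdd$T_C)), 1e-6)
})

test_that("the 3D solver degenerates to the 1D slab at every lateral position", {
  p <- slab_problem(scalp_props(), shared_constants(TA = 38, Tw = 7, he = 200), L = 8e-3)
  cfg <- slab_scenario(p$props, p$shared, L = 8e-3, h = 1e-3)
  fld <- solve_steady(cfg)
  for (i in cfg$grid$i) {
    plane <- fld$T[i + 1L, , ]
    expect_lt(max(plane) - min(plane), 1e-11) # laterally uniform
  }
  num <- vapply(cfg$grid$i, function(i) field_at(fld, i, 0L, 0L), numeric(1))
  expect_equal(num, analytic_slab(p, cfg$grid$i * 1e-3), tolerance = 1e-4)
})

test_that("grid refinement shows second order (first order for the one-sided Robin)", {
  p <- slab_problem(scalp_props(), shared_constants(TA = 38, Tw = 7, he = 200), L = 8e-3)
  co <- convergence_order(p, c(2e-3, 1e-3, 0.5e-3))
  expect_false(co$exact)
  expect_true(all(diff(co$errors) < 0))
  expect_true(all(co$orders > 1.8 & co$orders < 2.2))

  co1 <- convergence_order(p, c(2e-3, 1e-3, 0.5e-3), robin_order = 1L)
  expect_true(all(co1$orders > 0.8 & co1$orders < 1.4))

  # degenerate exact case: uniform solution, reported as exact, not an order
  p0 <- slab_problem(scalp_props(), shared_constants(TA = 38, Tw = 7, he = 0), L = 8e-3)
  expect_true(convergence_order(p0, c(2e-3, 1e-3, 0.5e-3))$exact)

  expect_error(convergence_order(p, c(2e-3, 1e-3)), "at least 3")
  expect_error(convergence_order(p, c(2e-3, 1e-3, 0.6e-3)), "divide")
})

test_that("reference fixtures parse, round-trip byte-identically, and have the printed counts", {
  for (id in sprintf("table%d", 1:6)) {
    ref <- read_reference_table(id)
    expect_equal(nrow(ref), if (attr(ref, "kind") == "steady") 72L else 70L)
    tf <- tempfile(fileext = ".csv")
    write_reference_table(ref, tf)
    orig <- system.file("extdata", paste0(id, ".csv"), package = "bioheat3d")
    expect_identical(readLines(tf), readLines(orig))
  }
  expect_error(read_reference_table("table9"), "no fixture")
})

test_that("the symmetry audit flags the printed mirror violations", {
  aud3 <- symmetry_audit(read_reference_table("table3"))
  hit <- aud3[aud3$i == 3 & aud3$j == 0 & abs(aud3$k) == 1, ]
  expect_equal(nrow(hit), 2L) # the 32.19 / 31.19 pair as printed
  expect_equal(unique(hit$spread), 1.00, tolerance = 1e-9)

  # a symmetric table passes clean
  sym <- data.frame(i = c(1L, 1L), j = c(1L, -1L), k = c(0L, 0L),
                    T_C = c("10.00", "10.00"), note = "")
  expect_equal(nrow(symmetry_audit(sym)), 0L)
})

test_that("comparison reports are exact on self-comparison and complete on model runs", {
  ref <- read_reference_table("table1")
  cfg <- preset_scenario("case1_38C", surface = "dirichlet")
  self <- solve_steady(cfg)
  self$T[cbind(ref$i + 1L, ref$j + 3L, ref$k + 3L)] <- as.numeric(ref$T_C)
  rep0 <- compare_reference(self, "table1")
  expect_equal(rep0$max, 0)
  expect_equal(rep0$n_within, 72L)

  rep1 <- compare_reference(solve_steady(cfg), "table1")
  expect_equal(rep1$n, 72L)
  expect_gte(rep1$max, rep1$mean)
  expect_gte(rep1$mean, 0)
  expect_output(print(rep1), "comparison vs table1")

  # transient comparison wires snapshots to the right table columns
  res <- run_transient(preset_scenario("case1_38C", mode = "transient"))
  rep4 <- compare_reference(res, "table4")
  expect_equal(rep4$n, 210L) # 70 nodes x 3 times
  expect_true(all(c("time", "dev", "suspect") %in% names(rep4$nodes)))

  # excluding audit-flagged rows can only lower the headline maximum
  rep3 <- compare_reference(solve_steady(preset_scenario("case3_41C")), "table3")
  rep3x <- compare_reference(solve_steady(preset_scenario("case3_41C")), "table3",
                             exclude_suspects = TRUE)
  expect_lte(rep3x$max, rep3$max)
})

test_that("the published transient table shows monotone cooling at the skin centre", {
  # fixture transcription check: surface-centre readings decrease 2 -> 6 min
  ref <- read_reference_table("table4")
  row <- ref[ref$i == 0 & ref$j == 0 & ref$k == 0, ]
  vals <- as.numeric(c(row$T_2min, row$T_4min, row$T_6min))
  expect_equal(vals, c(14.21, 12.43, 11.65))
  expect_true(all(diff(vals) < 0))
})
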