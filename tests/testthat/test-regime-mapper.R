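test_that("continuation tracks the phage-free branch to its extinction point", {
  # with the free-cell autoimmunity group equal to the growth rate, the
  # phage-free level 1 - delta hits zero exactly at delta = 1
  p <- fig1_params()
  br <- continue_fixed_point_1d(p, "delta", c(0, 1.2), steps = 61L)
  Fb <- br$F
  expect_equal(Fb$states[, "P"], 1 - Fb$values, tolerance = 1e-12)
  loss <- Fb$special_points[Fb$special_points$label == "infeasibility", ]
  expect_true(any(abs(loss$value - 1) < 0.03))
})

test_that("coexistence and phage-free branches collide at delta2 and exchange stability", {
  # deep in the validity regime the closed-form delta2 locates the
  # collision of C* with F* to well under a percent
  p <- validity_params()
  th <- delta_thresholds(p)
  br <- continue_fixed_point_1d(p, "delta", c(0.5, 1), steps = 201L)
  coll <- br$C$special_points[br$C$special_points$label ==
                                "fold/collision", ]
  expect_gte(nrow(coll), 1)
  expect_equal(coll$value[1], th$delta2, tolerance = 0.01)
  # F* is unstable below the collision and stable above it
  dstar <- coll$value[1]
  below <- br$F$values < dstar - 0.02
  above <- br$F$values > dstar + 0.02 & br$F$values < th$delta1
  expect_true(all(br$F$stability[below] == "unstable"))
  expect_true(all(br$F$stability[above] == "stable"))
  # C* is stable while feasible below the collision
  expect_true(all(br$C$stability[below] == "stable"))
})

test_that("continuation rejects empty ranges", {
  p <- fig1_params()
  expect_error(continue_fixed_point_1d(p, "delta", c(0.5, 0.5)), "range")
  expect_error(continue_fixed_point_1d(p, "delta", c(0, 1), steps = 1L),
               "steps")
})

test_that("the host-extinction boundary matches the delta1 hyperbola", {
  # in the (delta, G_Pphi) plane hosts die beyond delta*G_Pphi = A_P
  p <- fig1_params()
  cc <- trace_boundary_2d("simple", p, "delta", "G_Pphi",
                          xlim = c(0.3, 1.4), ylim = c(1.6, 4),
                          resolution = c(6, 4))
  host <- cc[cc$side_low == "phage-free" & cc$side_high == "host-extinct",
             , drop = FALSE]
  expect_gt(nrow(host), 0)
  err <- abs(host$x * host$y - p$A_P) / p$A_P
  expect_lt(max(err), 0.01)
})

test_that("a uniform rectangle yields an empty curve with a note", {
  p <- fig1_params(delta = 0.1)
  cc <- trace_boundary_2d("simple", p, "delta", "G_Qphi",
                          xlim = c(0.01, 0.1), ylim = c(0.1, 0.5),
                          resolution = 3L)
  expect_equal(nrow(cc), 0)
  expect_match(attr(cc, "note"), "uniform")
})

test_that("regime labels follow the advantage decomposition", {
  p <- table2_params()
  extinct <- detailed_state(P = 0, Y_PS = 1)
  expect_identical(classify_steady_state(extinct, p), "III")
  bare <- detailed_state(P = 0.2, V = 0.03)  # empty cassettes
  expect_identical(classify_steady_state(bare, p), "I")
  abi <- detailed_state(P = 0.5, V = 0.01, Y_QS = 0.1)  # pure ABI
  expect_identical(classify_steady_state(abi, p), "IV")
  full <- detailed_state(P = 0.8, V = 0.001, Y_QA = 0.1, Y_QS = 0.1)
  expect_identical(classify_steady_state(full, p), "II")

  ss <- structure(list(state = bare, converged = FALSE),
                  class = "steady_state")
  expect_error(classify_steady_state(ss, p), "unclassifiable")
})

test_that("a single-cell sweep returns a one-row labelled map", {
  p <- table2_params()
  m <- sweep_regimes(p, beta_grid = 1, Gc_grid = 1, delta = 0)
  expect_equal(nrow(m), 1)
  expect_true(m$regime %in% c("I", "II", "III", "IV"))
  expect_true(m$converged)
})

test_that("sweeps are deterministic and warm-start independent", {
  p <- table2_params()
  bg <- 10^seq(-1, 1, length.out = 4)
  gg <- 10^seq(0, 4, length.out = 4)
  m1 <- sweep_regimes(p, bg, gg, delta = 0.01)
  m2 <- sweep_regimes(p, bg, gg, delta = 0.01)
  expect_identical(m1$regime, m2$regime)
  cold <- sweep_regimes(p, bg, gg, delta = 0.01, warm_start = FALSE)
  expect_lt(mean(m1$regime != cold$regime), 0.01)
})

test_that("comparing a variant with itself yields a zero difference map", {
  p <- table2_params()
  cmp <- compare_variants(p, beta_grid = c(0.1, 1), Gc_grid = c(1, 100),
                          delta = 1e-4,
                          variants = c("baseline", "baseline"))
  expect_true(all(cmp$differences$dP == 0))
  expect_true(all(cmp$differences$dV == 0))
  expect_identical(cmp$differences$regime_from,
                   cmp$differences$regime_to)
  expect_error(compare_variants(p, 1, 1, variants = "baseline"),
               "two variants")
})
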