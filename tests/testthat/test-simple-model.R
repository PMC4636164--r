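test_that("the field vanishes at the analytic fixed points", {
  p <- fig1_params(delta = 0.3)
  expect_equal(unname(simple_rhs(c(0, 0, 0), p)), c(0, 0, 0))
  Pf <- 1 - p$delta * p$G_Pphi / p$A_P
  expect_equal(unname(simple_rhs(c(Pf, 0, 0), p)), c(0, 0, 0),
               tolerance = 1e-14)
})

test_that("the free-cell equation reduces to logistic growth without phage", {
  p <- simple_params(A_P = 2, G_Pphi = 1, G_Qphi = 1, G_Qp = 1,
                     G_Qv = 1, G_V = 1, alpha_v = 50, delta = 0)
  expect_equal(simple_rhs(c(P = 0.5, Q = 0, V = 0), p)[["P"]], 0.5)
})

test_that("phage-free level and thresholds follow the survival formulas", {
  p0 <- fig1_params(delta = 0)
  expect_equal(fixed_points_simple(p0, assess = FALSE)$F$state[["P"]], 1)

  p <- simple_params(A_P = 2, G_Pphi = 2, G_Qphi = 1, G_Qp = 1,
                     G_Qv = 1, G_V = 1, alpha_v = 50, delta = 0.5)
  expect_equal(fixed_points_simple(p, assess = FALSE)$F$state[["P"]], 0.5)

  # delta1 = A_P / G_Pphi
  expect_equal(delta_thresholds(fig1_params())$delta1, 1)
  p2 <- simple_params(A_P = 2, G_Pphi = 4, G_Qphi = 1, G_Qp = 1,
                      G_Qv = 1, G_V = 1, alpha_v = 50, delta = 0)
  expect_equal(delta_thresholds(p2)$delta1, 0.5)
})

test_that("closed-form coexistence level equals the phage-limited value without immunity", {
  p <- simple_params(A_P = 2, G_Pphi = 2, G_Qphi = 0, G_Qp = 0,
                     G_Qv = 2, G_V = 10, alpha_v = 50, delta = 0)
  fps <- fixed_points_simple(p, refine = FALSE, assess = FALSE)
  expect_equal(fps$C$diagnostics$closed_form[["P"]], 0.2)
})

test_that("delta2 < delta1 whenever the closed-form level is feasible, and V_c vanishes at delta2", {
  set.seed(42)
  for (i in 1:25) {
    p <- random_simple_params()
    th <- delta_thresholds(p)
    if (is.na(th$delta2)) next
    expect_lt(th$delta2, th$delta1)
    # at delta = delta2 the coexistence state collides with the
    # phage-free state
    p2 <- crisprcoevo:::.with_param(p, "delta", th$delta2)
    cf <- crisprcoevo:::closed_form_cstar(p2)
    expect_equal(cf[["V"]], 0, tolerance = 1e-10)
    Ff <- fixed_points_simple(p2, assess = FALSE)$F$state
    expect_equal(unname(cf), unname(Ff), tolerance = 1e-8)
  }
})

test_that("closed-form phage density decreases strictly with free-cell activation", {
  p <- validity_params()
  th <- delta_thresholds(p)
  deltas <- seq(0, th$delta2 * 0.99, length.out = 20)
  V <- vapply(deltas, function(d)
    crisprcoevo:::closed_form_cstar(
      crisprcoevo:::.with_param(p, "delta", d))[["V"]], numeric(1))
  expect_true(all(diff(V) < 0))
})

test_that("coexistence-boundary intercepts match their closed forms and shrink with immunity", {
  p <- simple_params(A_P = 2, G_Pphi = 2, G_Qphi = 0, G_Qp = 0,
                     G_Qv = 2, G_V = 10, alpha_v = 50, delta = 0)
  cb <- coexistence_boundary(p)
  expect_equal(cb$K1, 0.8)
  expect_equal(cb$K2, 8)

  # raising the restriction rate shrinks both intercepts
  for (gqp in c(0.5, 1, 2)) {
    cb2 <- coexistence_boundary(crisprcoevo:::.with_param(p, "G_Qp", gqp))
    expect_lt(cb2$K1, cb$K1)
    expect_lt(cb2$K2, cb$K2)
    cb <- cb2
  }

  # burst size equal to the deactivation rate collapses the wedge
  pdeg <- simple_params(A_P = 2, G_Pphi = 2, G_Qphi = 0, G_Qp = 0,
                        G_Qv = 2, G_V = 50, alpha_v = 50, delta = 0)
  expect_error(coexistence_boundary(pdeg), "no coexistence wedge")
})

test_that("extinction-state stability flips exactly at the survival threshold", {
  # eigenvalues at the origin are A_P - delta*G_Pphi, -G_Q, -G_V
  for (delta in c(0.5, 1.5)) {
    p <- fig1_params(delta = delta)
    f <- fixed_points_simple(p, assess = FALSE)$E
    f <- assess_stability(f, p)
    ev <- sort(Re(f$diagnostics$eigenvalues))
    expect_equal(ev, sort(c(p$A_P - delta * p$G_Pphi, -p$G_Q, -p$G_V)),
                 tolerance = 1e-10)
    expect_identical(f$stability,
                     if (delta > 1) "stable" else "unstable")
  }
})

test_that("Routh-Hurwitz verdict matches the eigenvalue verdict on random Jacobians", {
  expect_identical(routh_hurwitz(diag(c(-1, -2, -3)))$verdict, "stable")
  set.seed(7)
  n_checked <- 0
  while (n_checked < 100) {
    J <- matrix(rnorm(9), 3, 3)
    rh <- routh_hurwitz(J, tol = 1e-6)
    mx <- max(Re(eigen(J, only.values = TRUE)$values))
    if (rh$verdict == "marginal" || abs(mx) < 1e-6) next
    expect_identical(rh$verdict, if (mx < 0) "stable" else "unstable")
    n_checked <- n_checked + 1
  }
})

test_that("assess_stability rejects states that are not fixed points", {
  p <- fig1_params()
  f <- crisprcoevo:::.fixed_point("C", c(P = 0.5, Q = 0.2, V = 0.7),
                                  feasible = TRUE)
  expect_error(assess_stability(f, p), "not a fixed point")
})

test_that("closed form and refined root agree in the large-ratio limit", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_simple_params(validity_min = 100)
    fps <- fixed_points_simple(p, assess = FALSE)
    d <- fps$C$diagnostics
    expect_false(isTRUE(d$closed_form_only))
    expect_lt(d$discrepancy, 0.01)
  }
})

test_that("fixed-point table carries states, thresholds and boundary constants", {
  p <- fig1_params()
  tab <- fixed_points_table(fixed_points_simple(p), p)
  expect_identical(tab$kind, c("E", "F", "C"))
  expect_true(all(c("P", "Q", "V", "feasible", "stability", "delta1",
                    "delta2", "K1", "K2") %in% names(tab)))
  expect_equal(tab$delta1, rep(1, 3))
})
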