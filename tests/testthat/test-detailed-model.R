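test_that("compiled and reference right-hand sides agree on random states", {
  set.seed(3)
  p <- table2_params()
  parms <- crisprcoevo:::.detailed_parm_vector(p, "baseline")
  for (i in 1:20) {
    s <- detailed_state(P = runif(1), Q = runif(1), V = runif(1),
                        X_A = runif(1), Y_QA = runif(1), Y_QI = runif(1),
                        Y_QS = runif(1), Y_PA = runif(1),
                        Y_PI = runif(1), Y_PS = runif(1))
    r_ref <- detailed_rhs(s, p)
    # one explicit Euler step of size h returns y + h*f exactly, so the
    # compiled field can be read off without adaptive-step error
    h <- 1e-9
    sol <- deSolve::ode(y = s, times = c(0, h),
                        func = "crisprcoevo_derivs_detailed",
                        parms = parms, dllname = "crisprcoevo",
                        initfunc = "crisprcoevo_init_detailed",
                        method = "euler")
    r_c <- (sol[2, -1] - sol[1, -1]) / h
    expect_equal(unname(r_c), unname(r_ref),
                 tolerance = 1e-7 * max(1, abs(r_ref)))
  }
})

test_that("the phage-free fixed point annihilates the field", {
  p <- table2_params(delta = 1e-4, beta = 1, G_C = 10)
  fp <- phage_free_fixed_point(p)
  expect_equal(fp$state[["Y_PS"]], 0.1)
  expect_equal(max(abs(detailed_rhs(fp$state, p))), 0, tolerance = 1e-9)
})

test_that("self-targeting spacers have no source without host protospacers", {
  p <- table2_params(delta = 0, beta = 0)
  s <- detailed_state(P = 0.3, Q = 0.1, V = 0.2, X_A = 0.5, Y_QA = 0.4,
                      Y_QI = 0.1, Y_QS = 0, Y_PA = 0.2, Y_PI = 0.1,
                      Y_PS = 0)
  r <- detailed_rhs(s, p)
  expect_identical(r[["Y_QS"]], 0)
  expect_identical(r[["Y_PS"]], 0)
})

test_that("protospacer uptake follows the infection flux", {
  p <- table2_params()
  s <- detailed_state(P = 0.1, Q = 0.1, V = 0.1)
  r <- detailed_rhs(s, p)
  expect_equal(r[["X_A"]], p$A_V * 0.1 * (1 - p$mu_v), tolerance = 1e-12)
})

test_that("NaN states are rejected", {
  p <- table2_params()
  s <- default_initial_state("detailed")
  s[["V"]] <- NaN
  expect_error(detailed_rhs(s, p), "NaN")
})

test_that("phage-free steady state follows the acquisition/deletion balance", {
  p0 <- table2_params(beta = 0)
  fp0 <- phage_free_fixed_point(p0)
  expect_equal(fp0$state[["Y_PS"]], 0)
  expect_equal(fp0$state[["P"]], 1)

  p1 <- table2_params(delta = 1e-5, beta = 1, G_C = 2)
  expect_equal(phage_free_fixed_point(p1)$state[["Y_PS"]], 0.5)

  # activation above the survival bound makes the state infeasible
  p2 <- table2_params(beta = 1, G_C = 1, delta = 0.5)
  expect_lt(delta_max(p2), 0.5)
  expect_false(phage_free_fixed_point(p2)$feasible)

  p3 <- table2_params(delta = 0.5, beta = 1)
  p3 <- crisprcoevo:::.with_param(p3, "G_C", 0)
  expect_error(phage_free_fixed_point(p3), "no phage-free steady state")
})

test_that("the critical activation bound follows its closed form", {
  p <- detailed_params(A_P = 1e6, A_V = 2.5e7, G_Qp = 1e9,
                       G_Qphi = 1e8, G_Qv = 1e6, G_V = 5e6, G_C = 1,
                       M_V = 0.3, beta = 1, delta = 0, mu_v = 3e-7,
                       alpha_v = 50)
  expect_equal(delta_max(p), 0.01)
  expect_equal(delta_max(crisprcoevo:::.with_param(p, "beta", 2)), 0.005)
  expect_identical(delta_max(crisprcoevo:::.with_param(p, "beta", 0)),
                   Inf)
  expect_identical(delta_max(crisprcoevo:::.with_param(p, "G_Qphi", 0)),
                   Inf)
})

test_that("frozen-quota reduction reproduces the population block exactly", {
  p <- table2_params(delta = 1e-3, beta = 2, G_C = 10)
  set.seed(5)
  for (i in 1:10) {
    s <- detailed_state(P = runif(1, 0.05, 1), Q = runif(1, 0.05, 0.5),
                        V = runif(1, 0.01, 0.5), X_A = runif(1),
                        Y_QA = runif(1), Y_QI = runif(1),
                        Y_QS = runif(1), Y_PA = runif(1),
                        Y_PI = runif(1), Y_PS = runif(1))
    sp <- reduce_to_simple(p, s[c("Y_QA", "Y_QS", "Y_PS")])
    conv <- attr(sp, "conversion")
    s_simple <- c(P = s[["P"]], Q = s[["Q"]], V = conv$V * s[["V"]])
    rd <- detailed_rhs(s, p)
    rs <- simple_rhs(s_simple, sp)
    # rates convert by the time-unit ratio; the phage coordinate by the
    # burst-size factor
    expect_equal(rs[["P"]], rd[["P"]] / conv$time, tolerance = 1e-10)
    expect_equal(rs[["Q"]], rd[["Q"]] / conv$time, tolerance = 1e-10)
    expect_equal(rs[["V"]], conv$V * rd[["V"]] / conv$time,
                 tolerance = 1e-10)
  }
})

test_that("zero quotas reduce to a defenseless host", {
  p <- table2_params()
  sp <- reduce_to_simple(p, c(Y_QA = 0, Y_QS = 0, Y_PS = 0))
  expect_equal(sp$G_Qp, 0)
  expect_equal(sp$G_Qphi, 0)
  expect_equal(sp$G_Pphi, 0)
  # immune-advantage factor of the coexistence state is then 1
  cf <- crisprcoevo:::closed_form_cstar(sp)
  expect_equal(cf[["P"]], sp$G_V / sp$alpha_v)

  # self-targeting spacers alone yield a pure abortive-infection system
  sp2 <- reduce_to_simple(p, c(Y_QA = 0, Y_QS = 0.5, Y_PS = 0.5))
  expect_equal(sp2$G_Qp, 0)
  expect_gt(sp2$G_Qphi, 0)
})

test_that("variants alter exactly the intended terms", {
  p <- table2_params(delta = 0.2, beta = 1, G_C = 3)
  s <- detailed_state(P = 0.4, Q = 0.2, V = 0.1, X_A = 0.5, Y_QA = 0.3,
                      Y_QI = 0.2, Y_QS = 0.6, Y_PA = 0.2, Y_PI = 0.1,
                      Y_PS = 0.4)
  base <- detailed_rhs(s, p, "baseline")
  noabi <- detailed_rhs(s, p, "no_abi")
  # infected-cell autoimmunity loss removed from the Q equation only
  expect_equal(noabi[["Q"]] - base[["Q"]],
               p$G_Qphi * s[["Y_QS"]] * s[["Q"]], tolerance = 1e-6)
  expect_equal(noabi[["P"]], base[["P"]])       # free-cell ABI retained
  expect_equal(noabi[["V"]], base[["V"]])
  expect_equal(noabi[["Y_PS"]], base[["Y_PS"]])

  dc <- detailed_rhs(s, p, "deletion_constitutive")
  # free-cell deletion at full rate, infected-cell unchanged
  expect_equal(dc[["Y_PA"]] - base[["Y_PA"]],
               -(1 - p$delta) * p$G_C * s[["Y_PA"]], tolerance = 1e-6)
  expect_equal(dc[["Y_QA"]], base[["Y_QA"]])

  di <- detailed_rhs(s, p, "deletion_inverse")
  # infected-cell deletion fully repressed
  expect_equal(di[["Y_QA"]] - base[["Y_QA"]], p$G_C * s[["Y_QA"]],
               tolerance = 1e-6)
  expect_equal(di[["Y_PS"]], dc[["Y_PS"]])
})

test_that("decoupled deletion reduces the phage-free self-targeting burden", {
  p <- table2_params(delta = 1e-3, beta = 10, G_C = 5)
  base <- phage_free_fixed_point(p, "baseline")
  dc <- phage_free_fixed_point(p, "deletion_constitutive")
  expect_equal(base$state[["Y_PS"]], p$beta / p$G_C)
  expect_equal(dc$state[["Y_PS"]], p$delta * p$beta / p$G_C)
  expect_lt(dc$state[["Y_PS"]], base$state[["Y_PS"]])
  expect_equal(phage_free_fixed_point(p, "deletion_inverse")$state[["Y_PS"]],
               dc$state[["Y_PS"]])
})
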