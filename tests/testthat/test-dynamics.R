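p_base <- af_params()

test_that("age-related rates match their closed forms", {
  # sigmoid midpoint, plateau, and near-birth suppression
  expect_equal(age_activation(p_base$tc, p_base), 1460)
  expect_equal(age_activation(1e4, p_base), 2920, tolerance = 1e-12)
  expect_equal(age_activation(0, p_base), 2920 / (1 + exp(70 / 3)))
  expect_true(all(diff(age_activation(seq(0, 100, 0.5), p_base)) > 0))

  expect_equal(age_recovery(0, p_base), p_base$R0)
  expect_equal(age_recovery(50, p_base), p_base$R0 * 840^(-1.2))
  expect_true(all(diff(age_recovery(seq(0, 100, 0.5), p_base)) < 0))
})

test_that("total rates sum their components and guard positivity", {
  s <- af_state(t = 0)
  expect_equal(total_activation(s, p_base), p_base$A0 + age_activation(0, p_base))
  s <- af_state(t = p_base$tc)
  expect_equal(total_activation(s, p_base), p_base$A0 + 1460)
  s <- af_state(t = 200, Aepi = p_base$Amax)
  expect_equal(total_activation(s, p_base),
               p_base$A0 + p_base$A1 + p_base$Amax, tolerance = 1e-10)

  rage <- age_recovery(30, p_base)
  expect_equal(total_recovery(af_state(30, 1), p_base), rage)
  expect_equal(total_recovery(af_state(30, 1, Repi = -rage / 2), p_base),
               rage / 2)
  expect_error(total_recovery(af_state(30, 1, Repi = -rage), p_base),
               "non-positive total recovery")
})

test_that("sinus-rhythm evolution matches identity, decay and the ODE oracle", {
  skip_if_not_installed("deSolve")
  s <- af_state(t = 55, S = 0, Aepi = 120, Repi = 3000)
  expect_equal(evolve_sr(s, 0, p_base), s)
  far <- evolve_sr(s, 50, p_base)
  expect_equal(far$Aepi, 0, tolerance = 1e-300)
  expect_equal(far$Repi, 0, tolerance = 1e-300)

  set.seed(11)
  for (i in 1:20) {
    s <- af_state(t = runif(1, 0, 90), S = 0,
                  Aepi = runif(1, 1, p_base$Amax),
                  Repi = runif(1, 100, 5000))
    # keep beta*tau moderate so the ODE oracle retains relative accuracy
    tau <- runif(1, 1e-4, 0.04)
    got <- evolve_sr(s, tau, p_base)
    want <- ode_evolve_sr(s, tau, p_base)
    expect_rel_equal(got$Aepi, want$Aepi, 1e-8)
    expect_rel_equal(got$Repi, want$Repi, 1e-8)
  }
})

test_that("AF evolution matches identity, its fixed point and the ODE oracle", {
  skip_if_not_installed("deSolve")
  s <- af_state(t = 60, S = 1, Aepi = 500, Repi = -1000)
  expect_equal(evolve_af(s, 0, p_base), s)
  s_max <- af_state(t = 60, S = 1, Aepi = p_base$Amax, Repi = 0)
  expect_equal(evolve_af(s_max, 0.7, p_base)$Aepi, p_base$Amax)

  set.seed(12)
  for (i in 1:20) {
    t0 <- runif(1, 40, 90)
    rage <- age_recovery(t0, p_base)
    s <- af_state(t = t0, S = 1,
                  Aepi = runif(1, 0, p_base$Amax),
                  Repi = runif(1, -0.5, 1) * rage)
    tau <- runif(1, 0, 0.05)
    got <- evolve_af(s, tau, p_base)
    want <- ode_evolve_af(s, tau, p_base)
    expect_rel_equal(got$Aepi, want$Aepi, 1e-8)
    # compare on the total recovery rate (the biologically meaningful one)
    got_r <- age_recovery(got$t, p_base) + got$Repi
    want_r <- age_recovery(want$t, p_base) + want$Repi
    expect_rel_equal(got_r, want_r, 1e-8)
  }
})

test_that("cumulative initiation hazard equals adaptive quadrature", {
  expect_equal(sr_cumulative_hazard(af_state(t = 50), 0, p_base), 0)
  # homogeneous limit
  p_const <- make_fixture("constant_rate", activation = 7, recovery = 3)
  expect_equal(sr_cumulative_hazard(af_state(t = 2), 1.5, p_const), 7 * 1.5)

  set.seed(13)
  for (i in 1:15) {
    s <- af_state(t = runif(1, 0, 95), S = 0, Aepi = runif(1, 0, p_base$Amax))
    tau <- runif(1, 0.01, 1)
    got <- sr_cumulative_hazard(s, tau, p_base)
    expect_rel_equal(got, quad_sr_hazard(s, tau, p_base), 1e-9)
  }
  # strictly increasing in tau
  s <- af_state(t = 60, Aepi = 100)
  taus <- seq(0.01, 5, length.out = 50)
  expect_true(all(diff(sr_cumulative_hazard(s, taus, p_base)) > 0))
})

test_that("hazard inversion is exact in the constant-rate limit and self-consistent", {
  p_const <- make_fixture("constant_rate", activation = 4, recovery = 3)
  expect_equal(invert_sr_hazard(af_state(t = 1), 2, p_const), 0.5)

  set.seed(14)
  for (i in 1:20) {
    s <- af_state(t = runif(1, 0, 95), S = 0, Aepi = runif(1, 0, p_base$Amax))
    tau0 <- 10^runif(1, -6, 0.5)
    E <- sr_cumulative_hazard(s, tau0, p_base)
    if (E <= 0) next
    tau <- invert_sr_hazard(s, E, p_base)
    expect_lt(abs(sr_cumulative_hazard(s, tau, p_base) - E), 1e-9 * max(1, E))
  }
  # residual against the quadrature oracle at a fixed target
  s <- af_state(t = 60, S = 0, Aepi = 50)
  tau <- invert_sr_hazard(s, 2.5, p_base)
  expect_lt(abs(quad_sr_hazard(s, tau, p_base) - 2.5), 1e-8)
})

test_that("AF hazard inversion has the bounded closed form with a 'never' sentinel", {
  # mu -> 0 homogeneous limit
  p0 <- make_fixture("constant_rate", activation = 1, recovery = 100)
  expect_equal(invert_af_hazard(af_state(10, 1), 1, p0), 1 / 100)
  # closed form below the bound
  p <- af_params(mu = 52)
  s <- af_state(t = 0, S = 1, Repi = 100 - age_recovery(0, p))
  expect_equal(invert_af_hazard(s, 1, p), -log(1 - 0.52) / 52)
  # at or beyond the hazard bound the episode never self-terminates
  r_enter <- total_recovery(s, p)
  expect_identical(invert_af_hazard(s, r_enter / p$mu, p), Inf)
  expect_identical(invert_af_hazard(s, r_enter / p$mu * 2, p), Inf)
  # cross-check the closed form by root-finding on quadrature of the rate
  E <- 1
  f <- function(tau) {
    stats::integrate(function(u) 100 * exp(-52 * u), 0, tau,
                     rel.tol = 1e-12)$value - E
  }
  tau_quad <- stats::uniroot(f, c(1e-8, 1), tol = 1e-14)$root
  expect_equal(invert_af_hazard(s, E, p), tau_quad, tolerance = 1e-9)
})

test_that("termination boost reflects only negative episode components", {
  s <- af_state(t = 50, S = 1, Aepi = 77, Repi = -0.5)
  b <- apply_termination_boost(s, af_params(B = 1))
  expect_equal(b$Repi, 0.5)
  expect_equal(b$S, 0)
  expect_equal(b$Aepi, 77) # activation is continuous across the switch
  # positive component: no reflection, any B
  s2 <- af_state(t = 50, S = 1, Aepi = 1, Repi = 0.2)
  expect_equal(apply_termination_boost(s2, af_params(B = 5))$Repi, 0.2)
  # B = 0 switches the overshoot off entirely
  expect_equal(apply_termination_boost(s, af_params(B = 0))$Repi, 0)
})

test_that("Aepi stays within [0, Amax] under arbitrary evolve/boost sequences", {
  set.seed(15)
  for (rep in 1:10) {
    s <- af_state(t = runif(1, 0, 50), S = 0, Aepi = runif(1, 0, p_base$Amax))
    for (step in 1:50) {
      if (s$S == 0) {
        s <- evolve_sr(s, rexp(1, 20), p_base)
        s <- af_state(s$t, 1, s$Aepi, s$Repi)
      } else {
        s <- evolve_af(s, rexp(1, 200), p_base)
        aepi_before <- s$Aepi
        s <- apply_termination_boost(s, p_base)
        expect_identical(s$Aepi, aepi_before) # continuity across the event
      }
      expect_gte(s$Aepi, 0)
      expect_lte(s$Aepi, p_base$Amax)
    }
  }
})
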