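# Independent oracles used across the suite.

# Reference event loop written against the exported R dynamics functions.
# Consumes the same Exp(1) stream as the compiled simulator, so with an equal
# seed the two must reproduce the same event times.
simulate_patient_ref <- function(params, seed, horizon, init = af_state()) {
  set.seed(seed)
  st <- init
  starts <- c(); ends <- c(); cens <- c()
  while (st$t < horizon) {
    E <- stats::rexp(1)
    rem <- horizon - st$t
    if (sr_cumulative_hazard(st, rem, params) < E) break
    tau <- invert_sr_hazard(st, E, params)
    if (tau >= rem) break
    st <- evolve_sr(st, tau, params)
    st <- af_state(st$t, 1, st$Aepi, st$Repi)
    ep_start <- st$t
    E <- stats::rexp(1)
    tau_af <- invert_af_hazard(st, E, params)
    if (is.infinite(tau_af) || st$t + tau_af >= horizon) {
      starts <- c(starts, ep_start); ends <- c(ends, horizon)
      cens <- c(cens, TRUE)
      break
    }
    st <- evolve_af(st, tau_af, params)
    st <- apply_termination_boost(st, params)
    starts <- c(starts, ep_start); ends <- c(ends, st$t); cens <- c(cens, FALSE)
  }
  tibble::tibble(start = starts, end = ends, censored = cens)
}

# high-accuracy ODE integration of the between-event dynamics (deSolve)
ode_evolve_sr <- function(state, tau, params) {
  f <- function(t, y, p) {
    list(c(-p$beta * y[1], -p$nu * y[2]))
  }
  out <- deSolve::lsoda(c(Aepi = state$Aepi, Repi = state$Repi),
                        c(0, tau), f, params, rtol = 1e-12, atol = 1e-14)
  af_state(state$t + tau, 0, out[2, "Aepi"], out[2, "Repi"])
}

ode_evolve_af <- function(state, tau, params) {
  # total recovery decays at rate mu; Aepi saturates towards Amax at rate alpha
  f <- function(t, y, p) {
    list(c(p$alpha * (p$Amax - y[1]), -p$mu * y[2]))
  }
  r0 <- age_recovery(state$t, params) + state$Repi
  out <- deSolve::lsoda(c(Aepi = state$Aepi, R = r0),
                        c(0, tau), f, params, rtol = 1e-12, atol = 1e-14)
  af_state(state$t + tau, 1, out[2, "Aepi"],
           out[2, "R"] - age_recovery(state$t + tau, params))
}

# adaptive quadrature of the total activation rate over [t, t + tau]
quad_sr_hazard <- function(state, tau, params) {
  f <- function(u) {
    params$A0 + age_activation(state$t + u, params) +
      state$Aepi * exp(-params$beta * u)
  }
  stats::integrate(f, 0, tau, rel.tol = 1e-12, abs.tol = 0,
                   subdivisions = 1000L)$value
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
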