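# Closed-form rate dynamics of the two-state switching model.
#
# Between switching events the episode-induced activation component Aepi and
# the recovery components evolve by linear ODEs with closed-form solutions;
# the functions here evaluate those solutions, the exact cumulative hazards
# they imply, and the hazard inversions used to sample waiting times.

# log(1 + e^x) without overflow; x + log1p(e^-x) for large x
softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

#' Instantaneous patient state
#'
#' Bundles the instantaneous state of a simulated patient: age `t` (yr),
#' rhythm flag `S` (0 = sinus rhythm, 1 = AF), episode-induced activation
#' component `Aepi` (1/yr, in `[0, Amax]`), and episode-induced recovery
#' component `Repi` (1/yr; may be negative during and at the end of an AF
#' episode, since only the *total* recovery rate has a direct biological
#' meaning).
#'
#' @param t Age in years.
#' @param S Rhythm flag: 0 (sinus rhythm) or 1 (AF).
#' @param Aepi Episode-induced activation rate, 1/yr.
#' @param Repi Episode-induced recovery component, 1/yr.
#' @return An object of class `af_state`.
#' @export
af_state <- function(t = 0, S = 0, Aepi = 0, Repi = 0) {
  stopifnot(t >= 0, S %in% c(0, 1), Aepi >= 0)
  structure(list(t = t, S = S, Aepi = Aepi, Repi = Repi), class = "af_state")
}

#' @export
print.af_state <- function(x, ...) {
  cat(sprintf("<af_state> t = %.6g yr, %s, Aepi = %.6g, Repi = %.6g (1/yr)\n",
              x$t, if (x$S == 1) "AF" else "SR", x$Aepi, x$Repi))
  invisible(x)
}

#' Age-related activation rate
#'
#' Sigmoidal rise of the AF initiation hazard with age:
#' `A1 / (1 + exp(-(t - tc) / td))`. Low near birth, plateauing at `A1` well
#' beyond the centre age `tc`.
#'
#' @param t Age(s) in years (vectorised).
#' @param params An [af_params()] object.
#' @return Rate(s) in 1/yr, strictly increasing in `t`, bounded in `(0, A1)`.
#' @export
#' @examples
#' p <- af_params()
#' age_activation(p$tc, p) # half the plateau: 1460
age_activation <- function(t, params) {
  params$A1 / (1 + exp(-(t - params$tc) / params$td))
}

#' Age-related recovery rate
#'
#' Exponential decline of the AF termination hazard with age:
#' `R0 * exp(-lam * t)`. The reciprocal is the mean duration an episode
#' started at age `t` would have under the age-related hazard alone.
#'
#' @inheritParams age_activation
#' @return Rate(s) in 1/yr, strictly decreasing in `t`.
#' @export
age_recovery <- function(t, params) {
  params$R0 * exp(-params$lam * t)
}

#' Total activation rate at a state
#'
#' Sum of the three activation components: genetic (`A0`), age-related
#' ([age_activation()]), and episode-induced (`Aepi`).
#'
#' @param state An [af_state()].
#' @param params An [af_params()] object.
#' @return Rate in 1/yr.
#' @export
total_activation <- function(state, params) {
  params$A0 + age_activation(state$t, params) + state$Aepi
}

#' Total recovery rate at a state
#'
#' Sum of the age-related recovery rate and the episode-induced component.
#' The total is the termination hazard of an ongoing episode and must be
#' strictly positive; a non-positive total is a model violation and raises an
#' error.
#'
#' @inheritParams total_activation
#' @return Rate in 1/yr, strictly positive.
#' @export
total_recovery <- function(state, params) {
  r <- age_recovery(state$t, params) + state$Repi
  if (r <= 0) {
    stop("non-positive total recovery rate (", format(r),
         " 1/yr): model violation")
  }
  r
}

#' Evolve a state deterministically through sinus rhythm
#'
#' Over an AF-free interval of length `tau`, the episode-induced activation
#' decays as `Aepi * exp(-beta * tau)` and the episode-induced recovery
#' component as `Repi * exp(-nu * tau)`; age advances.
#'
#' @param state An [af_state()] with `S = 0`.
#' @param tau Interval length in years, `>= 0`.
#' @param params An [af_params()] object.
#' @return The evolved `af_state`.
#' @export
evolve_sr <- function(state, tau, params) {
  stopifnot(state$S == 0, tau >= 0)
  af_state(
    t = state$t + tau,
    S = 0,
    Aepi = state$Aepi * exp(-params$beta * tau),
    Repi = state$Repi * exp(-params$nu * tau)
  )
}

#' Evolve a state deterministically through an AF episode
#'
#' During AF the episode-induced activation relaxes towards its ceiling:
#' `Aepi' = Amax - (Amax - Aepi) * exp(-alpha * tau)`. The *total* recovery
#' rate decays exponentially at rate `mu`; the episode component is recovered
#' by subtracting the age-related baseline at the new age, and typically turns
#' negative as the episode wears on.
#'
#' @param state An [af_state()] with `S = 1`.
#' @inheritParams evolve_sr
#' @return The evolved `af_state`.
#' @export
evolve_af <- function(state, tau, params) {
  stopifnot(state$S == 1, tau >= 0)
  r_tot <- (age_recovery(state$t, params) + state$Repi) * exp(-params$mu * tau)
  t2 <- state$t + tau
  af_state(
    t = t2,
    S = 1,
    Aepi = params$Amax - (params$Amax - state$Aepi) * exp(-params$alpha * tau),
    Repi = r_tot - age_recovery(t2, params)
  )
}

#' Cumulative initiation hazard over a sinus-rhythm interval
#'
#' Exact integral of the total activation rate from the state's age `t` to
#' `t + tau` while in sinus rhythm:
#' `A0*tau + A1*td*[softplus((t+tau-tc)/td) - softplus((t-tc)/td)]
#'  + (Aepi/beta)*(1 - exp(-beta*tau))`.
#' Non-negative, strictly increasing and unbounded in `tau` (for `A0 > 0`).
#'
#' @param state An [af_state()] with `S = 0`.
#' @param tau Interval length(s) in years (vectorised).
#' @param params An [af_params()] object.
#' @return Dimensionless cumulative hazard(s).
#' @export
sr_cumulative_hazard <- function(state, tau, params) {
  stopifnot(state$S == 0, all(tau >= 0))
  sig <- params$A1 * params$td *
    (softplus((state$t + tau - params$tc) / params$td) -
       softplus((state$t - params$tc) / params$td))
  epi <- if (params$beta > 0) {
    state$Aepi / params$beta * (-expm1(-params$beta * tau))
  } else {
    state$Aepi * tau
  }
  params$A0 * tau + sig + epi
}

# derivative of the sr cumulative hazard: total activation at t + tau
sr_hazard_rate <- function(state, tau, params) {
  params$A0 + age_activation(state$t + tau, params) +
    state$Aepi * exp(-params$beta * tau)
}

#' Invert the sinus-rhythm cumulative hazard
#'
#' Solves `sr_cumulative_hazard(state, tau) = E` for the waiting time `tau`
#' until the next AF onset, given a unit-exponential deviate `E`. The hazard
#' is strictly increasing and unbounded, so the root is unique; it is found by
#' geometric bracket expansion from the constant-rate guess `E / A(t)`
#' followed by safeguarded Newton iteration, to a residual below
#' `1e-9 * max(1, E)`. A floor of 1e-12 yr avoids zero-length waits from
#' floating-point underflow.
#'
#' @param state An [af_state()] with `S = 0`.
#' @param E Positive cumulative-hazard target (unit-exponential draw).
#' @param params An [af_params()] object.
#' @return Waiting time in years.
#' @export
invert_sr_hazard <- function(state, E, params) {
  stopifnot(state$S == 0, E > 0)
  tol <- 1e-12 * max(1, E)
  a0 <- sr_hazard_rate(state, 0, params)
  tau <- E / a0
  lo <- 0
  hi <- tau
  while (sr_cumulative_hazard(state, hi, params) < E) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e12) stop("failed to bracket hazard inversion")
  }
  tau <- min(max(tau, lo), hi)
  for (i in seq_len(200)) {
    f <- sr_cumulative_hazard(state, tau, params) - E
    if (abs(f) <= tol) break
    if (f > 0) hi <- tau else lo <- tau
    step <- f / sr_hazard_rate(state, tau, params)
    tau_new <- tau - step
    if (!is.finite(tau_new) || tau_new <= lo || tau_new >= hi) {
      tau_new <- (lo + hi) / 2 # safeguard: bisection
    }
    if (tau_new == tau) break
    tau <- tau_new
  }
  max(tau, 1e-12)
}

#' Invert the AF cumulative hazard
#'
#' During an episode the total recovery rate decays as
#' `R_enter * exp(-mu * tau)`, so the cumulative termination hazard
#' `R_enter * (1 - exp(-mu*tau)) / mu` is bounded above by `R_enter / mu`.
#' If the unit-exponential draw `E` reaches that bound the episode never
#' self-terminates (the modelled route into permanent AF) and `Inf` is
#' returned as an explicit "never" sentinel; otherwise the closed-form
#' inversion `-log(1 - mu*E/R_enter) / mu` is exact.
#'
#' @param state An [af_state()] with `S = 1` and positive total recovery.
#' @inheritParams invert_sr_hazard
#' @return Waiting time in years, or `Inf` if the episode cannot terminate.
#' @export
invert_af_hazard <- function(state, E, params) {
  stopifnot(state$S == 1, E > 0)
  r_enter <- total_recovery(state, params) # errors if <= 0
  if (params$mu == 0) {
    return(max(E / r_enter, 1e-12))
  }
  if (E >= r_enter / params$mu) {
    return(Inf)
  }
  max(-log1p(-params$mu * E / r_enter) / params$mu, 1e-12)
}

#' Apply the post-episode recovery boost
#'
#' At the moment an AF episode terminates, if the episode-induced recovery
#' component is negative (the usual case after a long episode), it is
#' reflected and scaled: `Repi <- -B * Repi`, so the total recovery rate
#' overshoots its age-related baseline and drives the clinically observed
#' clustering of short episodes after a long one. If `Repi >= 0` no boost is
#' applied. The rhythm flag flips to sinus rhythm; `Aepi` is untouched (the
#' activation rate is continuous across switching events).
#'
#' @param state An [af_state()] with `S = 1`, already evolved to the
#'   termination time.
#' @param params An [af_params()] object.
#' @return The post-termination `af_state` with `S = 0`.
#' @export
apply_termination_boost <- function(state, params) {
  stopifnot(state$S == 1)
  repi <- if (state$Repi < 0) -params$B * state$Repi else state$Repi
  af_state(t = state$t, S = 0, Aepi = state$Aepi, Repi = repi)
}
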