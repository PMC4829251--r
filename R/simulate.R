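new_af_trajectory <- function(start, end, censored, params, seed, horizon,
                              final_state = NULL) {
  out <- tibble::tibble(
    start = as.double(start),
    end = as.double(end),
    censored = as.logical(censored)
  )
  structure(out,
            class = c("af_trajectory", class(out)),
            params = params, seed = seed, horizon = horizon,
            final_state = final_state)
}

#' Simulate one patient's lifetime AF trajectory
#'
#' Runs the event-driven exact simulation of the two-state switching process
#' from birth (or a supplied entry state) to the horizon. While in sinus
#' rhythm, the waiting time to the next episode onset is sampled by drawing a
#' unit exponential and inverting the exact cumulative hazard of the
#' time-dependent activation rate; during AF, the termination hazard is
#' bounded, and a draw beyond the bound means the episode never
#' self-terminates and runs to the horizon (censored — the route into
#' permanent AF). Between events all rate components follow their closed-form
#' deterministic solutions; the only randomness is in the exponential draws,
#' so a given seed reproduces the trajectory bit-for-bit.
#'
#' @param params An [af_params()] object.
#' @param seed Integer seed for this patient.
#' @param horizon Simulation end (age, yr); default 100.
#' @param init Optional [af_state()] entry state (`S = 0`); default: birth,
#'   with no episode-induced components.
#' @param max_episodes Safety cap on the episode count per patient.
#' @param check Warn when `params` violates the model constraints (set
#'   `FALSE` for deliberate constraint-breaking experiments).
#' @return An `af_trajectory`: a tibble with one row per AF episode
#'   (`start`, `end` in years of age, `censored` flag), carrying `params`,
#'   `seed` and `horizon` as attributes. Episodes are strictly ordered and
#'   non-overlapping; at most the last is censored (ends at the horizon).
#' @export
#' @examples
#' traj <- simulate_patient(af_params(), seed = 1)
#' nrow(traj) # number of lifetime episodes
simulate_patient <- function(params, seed, horizon = time_conventions()$horizon,
                             init = NULL, max_episodes = 5e6, check = TRUE) {
  stopifnot(inherits(params, "af_params"), horizon > 0)
  if (check) {
    viol <- validate_params(params)
    if (nrow(viol) > 0) {
      warning("simulating with a parameter set that violates model constraints: ",
              paste(viol$rule, collapse = "; "))
    }
  }
  if (is.null(init)) init <- af_state()
  stopifnot(inherits(init, "af_state"), init$S == 0, init$t < horizon)
  set.seed(seed)
  res <- sim_patient_cpp(unclass(params), horizon,
                         init$t, init$Aepi, init$Repi, max_episodes)
  new_af_trajectory(res$start, res$end, res$censored == 1,
                    params = params, seed = seed, horizon = horizon,
                    final_state = res$final_state)
}

#' @export
print.af_trajectory <- function(x, ...) {
  h <- attr(x, "horizon")
  af_time <- sum(x$end - x$start)
  cat(sprintf("<af_trajectory> %d episodes over %g yr (seed %s); AF time %.4g yr%s\n",
              nrow(x), h, format(attr(x, "seed")), af_time,
              if (any(x$censored)) "; ends in permanent AF" else ""))
  NextMethod()
}

#' Rejection-thinning reference simulator
#'
#' Simulates the same switching process as [simulate_patient()] by
#' Lewis-Shedler thinning: candidate events are proposed from a local
#' constant upper bound on the rate over short lookahead windows and accepted
#' with probability rate/bound. In sinus rhythm the bound uses the age-related
#' activation at the window end (increasing) plus the current episode-induced
#' component (decreasing); during AF the total recovery rate is decreasing, so
#' the current value bounds it. Statistically equivalent to the exact
#' hazard-inversion simulator, but much slower — intended for validation on
#' short horizons, not production runs.
#'
#' @inheritParams simulate_patient
#' @param window Lookahead window length (yr) for the local rate bound.
#' @return An `af_trajectory`.
#' @export
thinning_oracle <- function(params, seed, horizon, init = NULL,
                            window = 0.02, max_episodes = 1e6) {
  stopifnot(inherits(params, "af_params"), horizon > 0)
  if (is.null(init)) init <- af_state()
  stopifnot(init$S == 0, init$t < horizon)
  set.seed(seed)
  t <- init$t; Aepi <- init$Aepi; Repi <- init$Repi
  starts <- c(); ends <- c(); cens <- c()
  in_af <- FALSE
  r_cur <- NA_real_ # total recovery rate while in AF
  while (t < horizon) {
    if (!in_af) {
      M <- params$A0 + age_activation(min(t + window, horizon), params) + Aepi
      w <- stats::rexp(1, rate = M)
      if (w > window || t + w >= horizon) {
        adv <- min(window, horizon - t)
        Aepi <- Aepi * exp(-params$beta * adv)
        Repi <- Repi * exp(-params$nu * adv)
        t <- t + adv
        next
      }
      rate_w <- params$A0 + age_activation(t + w, params) +
        Aepi * exp(-params$beta * w)
      Aepi <- Aepi * exp(-params$beta * w)
      Repi <- Repi * exp(-params$nu * w)
      t <- t + w
      if (stats::runif(1) <= rate_w / M) {
        in_af <- TRUE
        starts <- c(starts, t)
        r_cur <- age_recovery(t, params) + Repi
        if (r_cur <= 0) stop("non-positive total recovery rate at episode start")
        if (length(starts) > max_episodes) stop("episode cap exceeded")
      }
    } else {
      M <- r_cur
      w <- if (M > 0) stats::rexp(1, rate = M) else Inf
      if (w > window || t + w >= horizon) {
        adv <- min(window, horizon - t)
        r_cur <- r_cur * exp(-params$mu * adv)
        Aepi <- params$Amax - (params$Amax - Aepi) * exp(-params$alpha * adv)
        t <- t + adv
        if (t >= horizon) { # censored episode at the horizon
          ends <- c(ends, horizon); cens <- c(cens, TRUE)
        }
        next
      }
      rate_w <- r_cur * exp(-params$mu * w)
      r_cur <- rate_w
      Aepi <- params$Amax - (params$Amax - Aepi) * exp(-params$alpha * w)
      t <- t + w
      if (stats::runif(1) <= rate_w / M) {
        in_af <- FALSE
        Repi <- r_cur - age_recovery(t, params)
        if (Repi < 0) Repi <- -params$B * Repi
        ends <- c(ends, t); cens <- c(cens, FALSE)
      }
    }
  }
  n <- length(ends)
  new_af_trajectory(starts[seq_len(n)], ends, cens,
                    params = params, seed = seed, horizon = horizon)
}

#' Write / read a patient trajectory
#'
#' The episode table goes to CSV (`patient_id,start_yr,end_yr,censored`, `.`
#' decimal, 12 significant digits) and the provenance (parameters, seed,
#' horizon) to a JSON sidecar next to it. Writing, reading and re-writing
#' yields byte-identical files.
#'
#' @param traj An `af_trajectory` from [simulate_patient()].
#' @param path Output CSV path; the sidecar replaces the extension with
#'   `.json`.
#' @param patient_id Identifier written to the CSV rows.
#' @return `path`, invisibly (writer); an `af_trajectory` (reader).
#' @export
write_trajectory <- function(traj, path, patient_id = 1L) {
  stopifnot(inherits(traj, "af_trajectory"))
  lines <- c(
    "patient_id,start_yr,end_yr,censored",
    sprintf("%d,%.12g,%.12g,%d", patient_id, traj$start, traj$end,
            as.integer(traj$censored))
  )
  writeLines(lines, path, sep = "\n")
  sidecar <- paste0(sub("\\.[^.]*$", "", path), ".json")
  jsonlite::write_json(
    list(params = unclass(attr(traj, "params")),
         seed = attr(traj, "seed"),
         horizon = attr(traj, "horizon")),
    sidecar, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric", "numeric",
                                             "integer"))
  sidecar <- paste0(sub("\\.[^.]*$", "", path), ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  params <- do.call(af_params, meta$params[setdiff(names(meta$params), "R0_unit")])
  new_af_trajectory(df$start_yr, df$end_yr, df$censored == 1,
                    params = params, seed = meta$seed, horizon = meta$horizon)
}
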