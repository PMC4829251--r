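# Ensemble execution and onset-aligned population statistics.

# per-patient seeds spawned from the master seed; order-independent, and the
# same master seed yields the same patient seeds for every parameter variant
# (paired-seed comparisons across variants)
spawn_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

# running sum/sumsq accumulator over bins with varying per-bin support
acc_new <- function(nbins) {
  list(sum = numeric(nbins), sumsq = numeric(nbins), n = integer(nbins))
}
acc_add <- function(acc, values, bins = seq_along(values)) {
  acc$sum[bins] <- acc$sum[bins] + values
  acc$sumsq[bins] <- acc$sumsq[bins] + values^2
  acc$n[bins] <- acc$n[bins] + 1L
  acc
}
acc_tbl <- function(acc, t) {
  keep <- acc$n > 0
  m <- acc$sum[keep] / acc$n[keep]
  v <- pmax(acc$sumsq[keep] / acc$n[keep] - m^2, 0)
  tibble::tibble(t = t[keep], mean = m, sd = sqrt(v), n = acc$n[keep])
}

#' Simulate and summarise an ensemble of patients
#'
#' Simulates `n` independent patients (per-patient seeds spawned from
#' `master_seed`), classifies each trajectory into clinical stages, and
#' accumulates: per-patient onset ages; mean and population-sd annual burden
#' and episodes-per-year versus absolute age; the same curves aligned to each
#' patient's paroxysmal onset (annual windows forward from the onset); and
#' sliding-window curves aligned backwards from each patient's permanent
#' onset (12-month window stepped monthly). Patients lacking an anchor are
#' excluded from the respective aligned curve and counted in `excluded`.
#'
#' @param params An [af_params()] object.
#' @param n Number of patients (`>= 1`).
#' @param master_seed Integer master seed.
#' @param horizon Simulation end (yr of age).
#' @param duration_observation Optional length-2 ages `[t0, t1)`: also
#'   accumulate the mean per-patient histogram of durations of episodes
#'   starting in this window.
#' @param duration_breaks Duration bin edges (yr) for the histogram.
#' @param before_max Depth (yr) of the backwards-aligned grid.
#' @param keep_trajectories Keep the per-patient episode tables (memory-heavy
#'   for large `n`).
#' @param max_episodes Per-patient episode cap passed to
#'   [simulate_patient()].
#' @param check Warn once when `params` violates the model constraints.
#' @return An `af_ensemble` object; see [tidy.af_ensemble()],
#'   [glance.af_ensemble()] and [autoplot.af_ensemble()].
#' @export
#' @examples
#' ens <- run_ensemble(af_params(), n = 5, master_seed = 1)
#' glance(ens)
run_ensemble <- function(params, n, master_seed,
                         horizon = time_conventions()$horizon,
                         duration_observation = NULL,
                         duration_breaks = duration_breaks_default(),
                         before_max = 30,
                         keep_trajectories = FALSE,
                         max_episodes = 5e6, check = TRUE) {
  stopifnot(n >= 1)
  if (check) {
    viol <- validate_params(params)
    if (nrow(viol) > 0) {
      warning("ensemble uses a parameter set that violates model constraints: ",
              paste(viol$rule, collapse = "; "))
    }
  }
  seeds <- spawn_seeds(master_seed, n)
  nb_age <- floor(horizon)
  age_grid <- 0:(nb_age - 1)
  rel_grid <- 0:(nb_age - 1)
  before_grid <- seq(1, before_max, by = 1 / 12) # years before the anchor

  burden_age <- acc_new(nb_age)
  counts_age <- acc_new(nb_age)
  burden_after <- acc_new(nb_age)
  counts_after <- acc_new(nb_age)
  burden_before <- acc_new(length(before_grid))
  counts_before <- acc_new(length(before_grid))
  hist_acc <- numeric(length(duration_breaks) - 1)
  onsets <- vector("list", n)
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  n_no_parox <- 0L
  n_no_perm <- 0L

  for (i in seq_len(n)) {
    traj <- simulate_patient(params, seeds[i], horizon,
                             max_episodes = max_episodes, check = FALSE)
    tl <- classify(traj)
    onsets[[i]] <- dplyr::bind_cols(
      tibble::tibble(patient_id = i, seed = seeds[i]), tl,
      tibble::tibble(n_episodes = nrow(traj))
    )
    # absolute-age annual curves (all patients contribute every bin)
    f <- af_time_before(traj, 0:nb_age)
    burden_age <- acc_add(burden_age, diff(f))
    counts_age <- acc_add(counts_age, diff(n_starts_before(traj, 0:nb_age)))
    # aligned forward from paroxysmal onset
    if (!is.na(tl$paroxysmal_onset)) {
      a <- tl$paroxysmal_onset
      k <- floor(horizon - a)
      if (k >= 1) {
        edges <- a + 0:k
        burden_after <- acc_add(burden_after,
                                diff(af_time_before(traj, edges)), 1:k)
        counts_after <- acc_add(counts_after,
                                diff(n_starts_before(traj, edges)), 1:k)
      }
    } else {
      n_no_parox <- n_no_parox + 1L
    }
    # sliding annual window backwards from permanent onset
    if (!is.na(tl$permanent_onset)) {
      a <- tl$permanent_onset
      sel <- which(before_grid <= a)
      if (length(sel) > 0) {
        lo <- a - before_grid[sel]
        bvals <- af_time_before(traj, lo + 1) - af_time_before(traj, lo)
        cvals <- n_starts_before(traj, lo + 1) - n_starts_before(traj, lo)
        burden_before <- acc_add(burden_before, bvals, sel)
        counts_before <- acc_add(counts_before, cvals, sel)
      }
    } else {
      n_no_perm <- n_no_perm + 1L
    }
    if (!is.null(duration_observation)) {
      h <- duration_histogram(traj, duration_observation, duration_breaks)
      hist_acc <- hist_acc + h$count
    }
    if (keep_trajectories) trajs[[i]] <- traj
  }

  dur_hist <- NULL
  if (!is.null(duration_observation)) {
    counts <- hist_acc / n
    tot <- sum(counts)
    dur_hist <- tibble::tibble(
      bin_lo = duration_breaks[-length(duration_breaks)],
      bin_hi = duration_breaks[-1],
      count = counts,
      proportion = if (tot > 0) counts / tot else counts
    )
  }

  structure(list(
    n = n, params = params, master_seed = master_seed, horizon = horizon,
    onsets = dplyr::bind_rows(onsets),
    burden_age = acc_tbl(burden_age, age_grid),
    counts_age = acc_tbl(counts_age, age_grid),
    burden_after_paroxysmal = dplyr::rename(acc_tbl(burden_after, rel_grid),
                                            t_rel = t),
    counts_after_paroxysmal = dplyr::rename(acc_tbl(counts_after, rel_grid),
                                            t_rel = t),
    burden_before_permanent = dplyr::rename(acc_tbl(burden_before, before_grid),
                                            years_before = t),
    counts_before_permanent = dplyr::rename(acc_tbl(counts_before, before_grid),
                                            years_before = t),
    duration_hist = dur_hist,
    excluded = list(no_paroxysmal = n_no_parox, no_permanent = n_no_perm),
    trajectories = trajs
  ), class = "af_ensemble")
}

#' @export
print.af_ensemble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<af_ensemble> n = %d (master seed %s)\n", x$n,
              format(x$master_seed)))
  cat(sprintf("  mean paroxysmal onset: %.1f yr; mean permanent onset: %.1f yr\n",
              g$mean_paroxysmal_onset, g$mean_permanent_onset))
  cat(sprintf("  fraction reaching permanent AF by %g yr: %.3f\n",
              x$horizon, g$fraction_permanent))
  invisible(x)
}

#' Per-patient onset table of an ensemble
#'
#' @param x An `af_ensemble`.
#' @param ... Unused.
#' @return A tibble, one row per patient: `patient_id`, `seed`, the three
#'   stage onsets, and `n_episodes`.
#' @method tidy af_ensemble
#' @export
tidy.af_ensemble <- function(x, ...) x$onsets

#' One-row summary of an ensemble
#'
#' @param x An `af_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, means and sds of paroxysmal and permanent
#'   onset ages, mean paroxysmal-to-permanent interval, fraction of patients
#'   reaching permanent AF, and mean episode count.
#' @method glance af_ensemble
#' @export
glance.af_ensemble <- function(x, ...) {
  o <- x$onsets
  tibble::tibble(
    n = x$n,
    mean_paroxysmal_onset = mean(o$paroxysmal_onset, na.rm = TRUE),
    sd_paroxysmal_onset = stats::sd(o$paroxysmal_onset, na.rm = TRUE),
    mean_permanent_onset = mean(o$permanent_onset, na.rm = TRUE),
    sd_permanent_onset = stats::sd(o$permanent_onset, na.rm = TRUE),
    mean_parox_to_permanent = mean(o$permanent_onset - o$paroxysmal_onset,
                                   na.rm = TRUE),
    fraction_permanent = mean(!is.na(o$permanent_onset)),
    mean_episodes = mean(o$n_episodes)
  )
}

# mean of the ensemble-mean annual burden over an absolute age range
mean_burden_between <- function(ens, ages = c(50, 80)) {
  b <- ens$burden_age
  mean(b$mean[b$t >= ages[1] & b$t < ages[2]])
}

#' Default one-at-a-time scan plan
#'
#' Every parameter rescaled by 10 and 0.1, except the sigmoid centre `tc`
#' (shifted by -10 and +10 years) and the recovery decay rate `lam` (rescaled
#' by 0.9 and 1.1, since tenfold changes there are off any plausible scale).
#'
#' @return A tibble with columns `field`, `mode`, `value`.
#' @export
oat_plan_default <- function() {
  fields <- c("A0", "A1", "Amax", "td", "alpha", "beta", "R0", "mu", "nu", "B")
  dplyr::bind_rows(
    tidyr::expand_grid(field = fields, mode = "scale", value = c(10, 0.1)),
    tibble::tibble(field = "tc", mode = "shift", value = c(-10, 10)),
    tibble::tibble(field = "lam", mode = "scale", value = c(0.9, 1.1))
  )
}

#' One-at-a-time parameter scan
#'
#' Runs an ensemble for the base parameter set and for each single-parameter
#' variant in `plan`, with identical per-patient seeds across variants so
#' comparisons are paired. Each row reports the mean annual burden over ages
#' 50-80 (the supplement's summary statistic) along with the full ensemble
#' summary.
#'
#' @param base An [af_params()] object.
#' @param plan A tibble with columns `field`, `mode` (`"scale"`/`"shift"`)
#'   and `value`; default [oat_plan_default()]. A zero-row plan runs only the
#'   base set.
#' @param n Patients per variant (the supplement used 100 sample paths).
#' @param master_seed Integer master seed (shared across variants).
#' @param horizon Simulation end (yr).
#' @param burden_ages Age range for the summary burden.
#' @param ... Passed to [run_ensemble()].
#' @return A tibble, one row per run: `label`, `field`, `mode`, `value`,
#'   `mean_burden_50_80`, and a `summary` list-column of `af_ensemble`
#'   objects (base row first).
#' @export
oat_scan <- function(base, plan = oat_plan_default(), n = 100, master_seed = 1,
                     horizon = time_conventions()$horizon,
                     burden_ages = c(50, 80), ...) {
  stopifnot(inherits(base, "af_params"))
  plan <- tibble::as_tibble(plan)
  if (nrow(plan) > 0) {
    stopifnot(all(c("field", "mode", "value") %in% names(plan)))
    bad <- setdiff(unique(plan$field), names(base))
    if (length(bad) > 0) stop("unknown parameter field(s): ",
                              paste(bad, collapse = ", "))
    if (!all(plan$mode %in% c("scale", "shift"))) {
      stop("plan mode must be 'scale' or 'shift'")
    }
  }
  runs <- dplyr::bind_rows(
    tibble::tibble(label = "baseline", field = NA_character_,
                   mode = NA_character_, value = NA_real_),
    if (nrow(plan) > 0) {
      dplyr::mutate(plan,
                    label = sprintf("%s_%s_%g", .data$field, .data$mode,
                                    .data$value),
                    .before = 1)
    }
  )
  runs$summary <- purrr::pmap(
    runs[, c("field", "mode", "value")],
    function(field, mode, value) {
      p <- if (is.na(field)) base else {
        param_variant(base, field, mode, value, quiet = TRUE)
      }
      run_ensemble(p, n = n, master_seed = master_seed, horizon = horizon,
                   check = FALSE, ...)
    }
  )
  runs$mean_burden_50_80 <- vapply(runs$summary, mean_burden_between,
                                   numeric(1), ages = burden_ages)
  runs
}

#' The four-variant parameter experiment
#'
#' Runs, with paired seeds: the baseline set; the age-related activation
#' plateau reduced tenfold (`A1` x 0.1); the episode-induced activation
#' ceiling reduced tenfold (`Amax` x 0.1); and the recovery decay rate
#' reduced by a third (`lam` x 2/3, i.e. `1.2 * log(840) / 75`). For each
#' variant the ensemble carries the mean annual burden versus absolute age
#' and the duration histogram of episodes starting between ages 60 and 65
#' (the five-year "monitoring window").
#'
#' @param n Sample paths per variant (100 in the reference experiment).
#' @param master_seed Integer master seed (shared across variants).
#' @param horizon Simulation end (yr).
#' @param params Base parameter set.
#' @param ... Passed to [run_ensemble()].
#' @return A tibble, one row per variant: `label`, `params` and `summary`
#'   list-columns.
#' @export
fig7_experiment <- function(n = 100, master_seed = 1,
                            horizon = time_conventions()$horizon,
                            params = af_params(), ...) {
  variants <- list(
    baseline = params,
    A1_tenth = param_variant(params, "A1", "scale", 0.1, quiet = TRUE),
    Amax_tenth = param_variant(params, "Amax", "scale", 0.1, quiet = TRUE),
    lam_two_thirds = param_variant(params, "lam", "scale", 2 / 3, quiet = TRUE)
  )
  tibble::tibble(
    label = names(variants),
    params = unname(variants),
    summary = purrr::map(variants, function(p) {
      run_ensemble(p, n = n, master_seed = master_seed, horizon = horizon,
                   duration_observation = c(60, 65), check = FALSE, ...)
    }) |> unname()
  )
}
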