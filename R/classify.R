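#' Clinical-stage classification of a trajectory
#'
#' Maps an episode list to the onset times of the three clinical stages used
#' in the simulations: a patient enters *paroxysmal* AF the moment an episode
#' has lasted 14.4 minutes (1% of a day); *persistent* AF the moment an
#' episode has lasted 7 days; and *permanent* AF at the start of a final
#' episode that continues to the simulation horizon without returning to
#' sinus rhythm (the censored episode). Onsets are timed at the earliest
#' moment the criterion is knowable, i.e. episode start plus the threshold; a
#' censored episode at least as long as a threshold also qualifies for it.
#' Stages never reached are `NA`.
#'
#' Classification is pure: it depends only on the episode list, and repeated
#' application gives identical results.
#'
#' @param trajectory An `af_trajectory` (or any tibble with `start`, `end`,
#'   `censored` columns in years).
#' @param paroxysmal_threshold,persistent_threshold Episode durations (yr)
#'   defining the stages; defaults 14.4 min and 7 days.
#' @return A one-row tibble with `paroxysmal_onset`, `persistent_onset`,
#'   `permanent_onset` (years of age, `NA` if not reached).
#' @export
#' @examples
#' fx <- make_fixture("toy_episodes")
#' classify(fx)
classify <- function(trajectory,
                     paroxysmal_threshold = time_conventions()$paroxysmal_threshold,
                     persistent_threshold = time_conventions()$persistent_threshold) {
  dur <- trajectory$end - trajectory$start
  onset_at <- function(threshold) {
    i <- which(dur >= threshold)[1]
    if (is.na(i)) NA_real_ else trajectory$start[i] + threshold
  }
  n <- nrow(trajectory)
  permanent <- if (n > 0 && trajectory$censored[n]) trajectory$start[n] else NA_real_
  tibble::tibble(
    paroxysmal_onset = onset_at(paroxysmal_threshold),
    persistent_onset = onset_at(persistent_threshold),
    permanent_onset = permanent
  )
}

#' Write stage timelines to CSV
#'
#' One row per patient: `patient_id,paroxysmal_onset_yr,persistent_onset_yr,
#' permanent_onset_yr`, with empty cells for stages never reached.
#'
#' @param timelines A tibble with a `patient_id` column and the three onset
#'   columns of [classify()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timelines <- function(timelines, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.12g", x))
  lines <- c(
    "patient_id,paroxysmal_onset_yr,persistent_onset_yr,permanent_onset_yr",
    paste(timelines$patient_id,
          fmt(timelines$paroxysmal_onset),
          fmt(timelines$persistent_onset),
          fmt(timelines$permanent_onset), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}
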