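# Burden and episode-count metrics over observation windows.
#
# Burden attributes AF time to windows by exact interval overlap; episode
# counts attribute each episode to the window containing its start time.

# total AF time in [0, x), vectorised over x
af_time_before <- function(trajectory, x) {
  s <- trajectory$start
  e <- trajectory$end
  if (length(s) == 0) return(rep(0, length(x)))
  cume <- cumsum(e - s)
  idx <- findInterval(x, s)
  i1 <- pmax(idx, 1L)
  full <- ifelse(idx > 0, cume[i1], 0)
  over <- ifelse(idx > 0, pmax(0, e[i1] - pmax(x, s[i1])), 0)
  full - over
}

# number of episode starts strictly before x, vectorised
n_starts_before <- function(trajectory, x) {
  findInterval(x, trajectory$start, left.open = TRUE)
}

new_af_series <- function(t, values, value_col, window, origin, trajectory,
                          anchor = NULL, direction = NULL) {
  out <- tibble::tibble(t = t, !!value_col := values)
  structure(out,
            class = c("af_series", class(out)),
            value_col = value_col, window = window, origin = origin,
            trajectory = trajectory, anchor = anchor, direction = direction)
}

#' AF burden per observation window
#'
#' Burden is the fraction of time spent in AF during an observation window.
#' For each window `[origin + k*w, origin + (k+1)*w)` fully inside the
#' horizon, the AF overlap time is computed exactly on the episode intervals
#' (clipped at the window edges) and divided by the window length.
#'
#' @param trajectory An `af_trajectory`.
#' @param window Window length in years (e.g. `1/365` daily, `7/365` weekly,
#'   `30/365` monthly, `1` annual).
#' @param origin Start of the first window (yr).
#' @return An `af_series` tibble with columns `t` (window start, yr) and
#'   `burden` (in `[0, 1]`); window, origin and the source trajectory ride
#'   along as attributes so the series can be re-aligned.
#' @export
#' @examples
#' traj <- simulate_patient(af_params(), seed = 1)
#' burden(traj, window = 1) # annual burden from birth
burden <- function(trajectory, window = 1, origin = 0) {
  stopifnot(window > 0)
  horizon <- attr(trajectory, "horizon") %||% max(trajectory$end, origin)
  k <- floor((horizon - origin) / window + 1e-12)
  edges <- origin + window * (0:k)
  f <- af_time_before(trajectory, edges)
  vals <- diff(f) / window
  new_af_series(edges[-length(edges)], pmin(pmax(vals, 0), 1), "burden",
                window, origin, trajectory)
}

#' Episode counts per observation window
#'
#' Counts the episodes *starting* within each window
#' `[origin + k*w, origin + (k+1)*w)`; an episode spanning a window boundary
#' (or censored at the horizon) is counted once, in its start window.
#'
#' @inheritParams burden
#' @return An `af_series` tibble with columns `t` (window start) and `count`.
#' @export
episode_counts <- function(trajectory, window = 1, origin = 0) {
  stopifnot(window > 0)
  horizon <- attr(trajectory, "horizon") %||% max(trajectory$end, origin)
  k <- floor((horizon - origin) / window + 1e-12)
  edges <- origin + window * (0:k)
  n <- diff(n_starts_before(trajectory, edges))
  new_af_series(edges[-length(edges)], n, "count", window, origin, trajectory)
}

#' Align a series to an anchor event
#'
#' Re-computes a burden or count series on windows aligned to a per-patient
#' anchor (e.g. the paroxysmal-AF onset age). `direction = "after"` lays
#' windows forward from the anchor (`t_rel = 0` covers the first window after
#' it); `direction = "before"` lays whole windows backwards so a window edge
#' coincides with the anchor, and `t_rel` is negative (`t_rel = -w` is the
#' window immediately preceding the anchor, i.e. "one window before").
#'
#' @param series An `af_series` from [burden()] or [episode_counts()].
#' @param anchor Anchor time (yr); `NA` (patient never reached the stage) is
#'   an error.
#' @param direction `"after"` or `"before"`.
#' @return An `af_series` with columns `t` (absolute window start), `t_rel`
#'   (window start relative to the anchor) and the value column.
#' @export
align <- function(series, anchor, direction = c("after", "before")) {
  direction <- match.arg(direction)
  if (is.na(anchor)) stop("anchor is NA: patient never reached this stage")
  traj <- attr(series, "trajectory")
  if (is.null(traj)) stop("series does not carry its source trajectory")
  w <- attr(series, "window")
  value_col <- attr(series, "value_col")
  recompute <- if (value_col == "burden") burden else episode_counts
  if (direction == "after") {
    out <- recompute(traj, window = w, origin = anchor)
  } else {
    k <- floor(anchor / w + 1e-12)
    out <- recompute(traj, window = w, origin = anchor - k * w)
    out <- out[out$t < anchor - w * 1e-9, ]
  }
  out$t_rel <- out$t - anchor
  attr(out, "anchor") <- anchor
  attr(out, "direction") <- direction
  out[, c("t", "t_rel", value_col)]
}

#' Default log-spaced duration bin edges
#'
#' Spans 0.3 seconds (below the shortest possible episode at baseline) to the
#' full horizon, 12 bins per decade.
#'
#' @param horizon Upper edge (yr).
#' @return Numeric vector of bin edges in years.
#' @export
duration_breaks_default <- function(horizon = time_conventions()$horizon) {
  10^seq(log10(1e-8), log10(horizon), length.out = 121)
}

#' Histogram of episode durations within an observation window
#'
#' Durations of episodes starting within `observation = c(t0, t1)`, binned by
#' `breaks` (years). Given a list of trajectories, per-patient counts are
#' averaged across the ensemble. Durations outside the break range are
#' dropped.
#'
#' @param trajectory An `af_trajectory`, or a list of them (ensemble).
#' @param observation Length-2 numeric: observation window `[t0, t1)` in
#'   years of age.
#' @param breaks Increasing vector of duration bin edges (yr).
#' @return A tibble with `bin_lo`, `bin_hi`, `count` (mean per-patient count
#'   when averaging an ensemble) and `proportion` (count normalised to the
#'   total in range).
#' @export
duration_histogram <- function(trajectory, observation,
                               breaks = duration_breaks_default()) {
  stopifnot(length(observation) == 2, observation[1] < observation[2],
            all(diff(breaks) > 0))
  trajs <- if (inherits(trajectory, "af_trajectory")) list(trajectory)
           else trajectory
  nb <- length(breaks) - 1
  acc <- numeric(nb)
  for (tr in trajs) {
    sel <- tr$start >= observation[1] & tr$start < observation[2]
    dur <- tr$end[sel] - tr$start[sel]
    if (length(dur) > 0) {
      idx <- findInterval(dur, breaks, rightmost.closed = TRUE)
      idx <- idx[idx >= 1 & idx <= nb]
      acc <- acc + tabulate(idx, nbins = nb)
    }
  }
  counts <- acc / length(trajs)
  tot <- sum(counts)
  tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    count = counts,
    proportion = if (tot > 0) counts / tot else counts
  )
}
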