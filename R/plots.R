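# ggplot2 methods for the package's result types.

#' Plot a patient trajectory as an episode raster
#'
#' AF episodes drawn as filled intervals along the age axis; optionally
#' restricted to an age window to expose episode clustering.
#'
#' @param object An `af_trajectory`.
#' @param xlim Optional length-2 age window (yr).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot af_trajectory
#' @export
autoplot.af_trajectory <- function(object, xlim = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(xlim)) {
    df <- dplyr::filter(df, .data$end > xlim[1], .data$start < xlim[2])
    df <- dplyr::mutate(df, start = pmax(.data$start, xlim[1]),
                        end = pmin(.data$end, xlim[2]))
  }
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1),
                       fill = "firebrick") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "age (yr)", y = NULL, title = "AF episodes") +
    ggplot2::theme_minimal()
}

#' Plot a burden or episode-count series
#'
#' @param object An `af_series` from [burden()] or [episode_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot af_series
#' @export
autoplot.af_series <- function(object, ...) {
  value_col <- attr(object, "value_col")
  xcol <- if ("t_rel" %in% names(object)) "t_rel" else "t"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data[[xcol]], y = .data[[value_col]])) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = if (xcol == "t_rel") "time relative to anchor (yr)" else "age (yr)",
      y = value_col) +
    ggplot2::theme_minimal()
}

#' Plot ensemble mean curves with +/- 1 sd bands
#'
#' @param object An `af_ensemble`.
#' @param which One of `"burden_age"`, `"counts_age"`,
#'   `"burden_after_paroxysmal"`, `"counts_after_paroxysmal"`,
#'   `"burden_before_permanent"`, `"counts_before_permanent"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot af_ensemble
#' @export
autoplot.af_ensemble <- function(object, which = "burden_age", ...) {
  stopifnot(which %in% c("burden_age", "counts_age",
                         "burden_after_paroxysmal", "counts_after_paroxysmal",
                         "burden_before_permanent", "counts_before_permanent"))
  tbl <- object[[which]]
  xcol <- names(tbl)[1]
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data[[xcol]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = xcol, y = sub("_.*$", "", which),
                  title = sprintf("%s (n = %d)", which, object$n)) +
    ggplot2::theme_minimal()
  if (grepl("before", which)) p <- p + ggplot2::scale_x_reverse()
  p
}

#' Compare mean annual burden curves across parameter variants
#'
#' Overlays the ensemble-mean annual burden versus absolute age for a set of
#' labelled ensembles, e.g. the rows of [fig7_experiment()].
#'
#' @param summaries A tibble with `label` and `summary` (list of
#'   `af_ensemble`) columns, or a named list of `af_ensemble` objects.
#' @return A ggplot object.
#' @export
plot_burden_curves <- function(summaries) {
  if (is.data.frame(summaries)) {
    labels <- summaries$label
    ens <- summaries$summary
  } else {
    labels <- names(summaries)
    ens <- summaries
  }
  df <- purrr::map2_dfr(ens, labels, function(e, lab) {
    dplyr::mutate(e$burden_age, variant = lab)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mean,
                                   colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (yr)", y = "mean annual AF burden",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
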