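#' Plot a density curve with its called peaks and valleys
#'
#' @param object A `peak_set` from [detect_peaks()].
#' @param ... Unused.
#' @return A ggplot: the density curve, dashed vertical lines at peaks,
#'   dotted lines at valleys, and the two height thresholds.
#' @exportS3Method ggplot2::autoplot
autoplot.peak_set <- function(object, ...) {
  curve <- object$curve
  max_y <- max(curve$y)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      yintercept = object$threshold_down * max_y,
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(
      x = "expression", y = "density",
      title = sprintf("%d peak(s) detected", object$n_peaks)
    ) +
    ggplot2::theme_minimal()
  if (object$n_peaks > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$peaks,
      ggplot2::aes(xintercept = .data$location),
      linetype = "dashed", colour = "firebrick"
    )
  }
  if (nrow(object$valleys) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$valleys,
      ggplot2::aes(xintercept = .data$location),
      linetype = "dotted", colour = "steelblue"
    )
  }
  p
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot step plot of the survival probability.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = 0, survival = 1),
    dplyr::select(object, "time", "survival")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier comparison of the two expression modes of one gene
#'
#' @param stratification Tibble `sample_id`, `peak` for one gene (rows of the
#'   [analyze_cohort()] stratification output).
#' @param clinical Clinical tibble (`sample_id`, `os_time`, `os_event`).
#' @param truncate_barcode Optional id truncation (see
#'   [normalize_sample_ids()]).
#' @return A ggplot with one survival step per peak group.
#' @export
plot_km_groups <- function(stratification, clinical, truncate_barcode = NULL) {
  strat <- dplyr::mutate(
    stratification,
    .match_id = normalize_sample_ids(.data$sample_id, truncate_barcode)
  )
  clin <- dplyr::mutate(
    clinical,
    .match_id = normalize_sample_ids(.data$sample_id, truncate_barcode)
  )
  joined <- dplyr::inner_join(
    dplyr::select(strat, ".match_id", "peak"),
    dplyr::select(clin, ".match_id", "os_time", "os_event"),
    by = ".match_id"
  )
  if (nrow(joined) == 0L) abort("no overlap between stratification and clinical table.")
  curves <- joined |>
    dplyr::group_by(.data$peak) |>
    dplyr::group_map(function(df, key) {
      km <- kaplan_meier(df$os_time, df$os_event)
      dplyr::bind_rows(
        tibble(time = 0, survival = 1),
        dplyr::select(km, "time", "survival")
      ) |>
        dplyr::mutate(peak = key$peak)
    }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(
    curves,
    ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$peak)
  ) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}
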