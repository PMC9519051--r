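#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Raster plot of normalised epoch speeds
#'
#' One row per fish, one tile per epoch, coloured by speed normalised to the
#' fish's baseline mean - the standard cohort overview of arrest and
#' recovery.
#'
#' @param epochs Output of [epoch_speeds()].
#' @param max_norm Normalised speeds are clipped at this value for display.
#' @return A ggplot object.
#' @export
plot_speed_raster <- function(epochs, max_norm = 2) {
  df <- epochs |>
    dplyr::filter(.data$baseline_mean > 0) |>
    dplyr::mutate(norm = pmin(.data$speed_mm_s / .data$baseline_mean,
                              max_norm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_start,
                                   y = factor(.data$fish_id),
                                   fill = .data$norm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "speed /\nbaseline") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$phase), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "time (s)", y = "fish") +
    ggplot2::theme_minimal()
}

#' Cohort mean recovery curve
#'
#' Mean (and SEM ribbon) of baseline-normalised speed per epoch across the
#' cohort; recovery toward 1 after the stimulus is the group-level signature
#' of arrest wearing off.
#'
#' @param epochs Output of [epoch_speeds()].
#' @return A ggplot object.
#' @export
plot_recovery_curve <- function(epochs) {
  df <- epochs |>
    dplyr::filter(.data$baseline_mean > 0) |>
    dplyr::mutate(norm = .data$speed_mm_s / .data$baseline_mean) |>
    dplyr::group_by(.data$phase, .data$epoch, .data$t_start) |>
    dplyr::summarise(mean = mean(.data$norm),
                     sem = stats::sd(.data$norm) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_start, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.5, 1), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "speed / baseline") +
    ggplot2::theme_minimal()
}

#' Plot calcium traces by responder class
#'
#' @param object Output of [extract_traces()].
#' @param responders Optional classification tibble from
#'   [classify_responders()]; colours traces by class.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zfa_traces
#' @export
autoplot.zfa_traces <- function(object, responders = NULL, ...) {
  df <- object
  if (!is.null(responders)) {
    df <- dplyr::left_join(df,
                           dplyr::select(responders, "roi", "responder"),
                           by = "roi")
  } else {
    df$responder <- NA
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$dRR,
                                   group = .data$roi,
                                   colour = .data$responder)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey30"),
                                 na.value = "grey30") +
    ggplot2::labs(x = "frame", y = expression(Delta * R / R)) +
    ggplot2::theme_minimal()
}

#' Volcano-style enrichment plot
#'
#' log2 fold change against -log10 adjusted p, with the enrichment
#' thresholds drawn and enriched genes highlighted.
#'
#' @param object A `zfa_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zfa_enrichment
#' @export
autoplot.zfa_enrichment <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$q, 1e-300)),
                                   colour = .data$enriched)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = th$fc, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(th$fdr), linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ q)) +
    ggplot2::theme_minimal()
}

#' Estimation plot of a bootstrapped mean difference
#'
#' Two-panel Gardner-Altman-style figure: raw group values beside the
#' bootstrap distribution of the mean difference with its percentile
#' interval.
#'
#' @param boot A `zfa_boot` object.
#' @param a,b The raw group vectors used for the fit.
#' @param labels Group labels.
#' @return A ggplot object.
#' @export
plot_estimation <- function(boot, a, b, labels = c("control", "treated")) {
  raw <- tibble::tibble(
    group = factor(rep(labels, c(length(a), length(b))), levels = labels),
    value = c(a, b)
  )
  dens <- tibble::tibble(diff = boot$boots)
  ggplot2::ggplot() +
    ggplot2::geom_jitter(data = raw,
                         ggplot2::aes(x = .data$group, y = .data$value),
                         width = 0.08, alpha = 0.6) +
    ggplot2::geom_violin(data = dens,
                         ggplot2::aes(x = "difference",
                                      y = .data$diff + mean(c(a))),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::annotate("pointrange", x = "difference",
                      y = boot$estimate + mean(a),
                      ymin = boot$ci_low + mean(a),
                      ymax = boot$ci_high + mean(a)) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}
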