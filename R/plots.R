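# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a batch growth curve
#'
#' Biomass, substrate and product trajectories, faceted by variable, one
#' line per replicate.
#'
#' @param object A `growth_curve` tibble (see [simulate_batch_culture()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_curve
#' @export
autoplot.growth_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("dcw_g_l", "substrate_g_l", "product_g_l"),
    names_to = "variable", values_to = "g_l")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_h, y = .data$g_l,
    colour = .data$condition,
    group = interaction(.data$condition, .data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (g/L)") +
    ggplot2::theme_minimal()
}

#' Plot sampled flux distributions
#'
#' Frequency histograms of the sampled flux through each summarised
#' reaction, the flux-frequency view used to compare knockout designs.
#'
#' @param object A `flux_summary` from [summarize_reaction_flux()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flux_summary
#' @export
autoplot.flux_summary <- function(object, ...) {
  bars <- object |>
    dplyr::select(reaction, histogram) |>
    tidyr::unnest(histogram) |>
    dplyr::mutate(bin_hi = ifelse(.data$bin_hi > .data$bin_lo,
                                  .data$bin_hi, .data$bin_lo + 1e-9))
  ggplot2::ggplot(bars) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$bin_lo,
                                    xmax = .data$bin_hi,
                                    ymin = 0, ymax = .data$frequency),
                       fill = "steelblue") +
    ggplot2::facet_wrap(~reaction, scales = "free") +
    ggplot2::labs(x = "flux (mmol/gDCW/h)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a Duncan multiple-range comparison
#'
#' Group means with letter annotations; groups sharing a letter are not
#' significantly different at the test's alpha.
#'
#' @param object A `duncan_mrt` from [duncan_mrt()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot duncan_mrt
#' @export
autoplot.duncan_mrt <- function(object, ...) {
  g <- object$groups
  se <- sqrt(object$mse / g$n)
  df <- dplyr::mutate(g, se = se)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$group,
                                                      -.data$mean),
                                   y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean + 1.5 * .data$se),
                       vjust = 0) +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
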