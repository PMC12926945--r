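# ggplot2 visualisations: per-residue PARCH profiles, evaporation curves,
# and the site/cumulative delta bar chart.

#' Plot a PARCH profile
#'
#' Per-residue mean PARCH value with replicate-sd error bars; 0 is
#' hydrophobic, 10 hydrophilic.
#'
#' @param object A `parch_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parch_profile <- function(object, ...) {
  df <- tidy(object)
  df$residue <- factor(df$residue, levels = unique(df$residue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$pv_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pv_mean - .data$pv_sd,
                   ymax = .data$pv_mean + .data$pv_sd),
      width = 0.3, na.rm = TRUE
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 10)) +
    ggplot2::labs(x = NULL, y = "PARCH value (0 = hydrophobic, 10 = hydrophilic)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot a PTM delta report
#'
#' Site ΔPV (colored by class) beside the cumulative neighborhood change
#' (gray), mirroring the bar-chart layout used for modification surveys.
#'
#' @param object A `parch_delta`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parch_delta <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    what = factor(c("site", "neighborhood (cumulative)"),
                  levels = c("site", "neighborhood (cumulative)")),
    delta = c(g$site_delta, g$cumulative_delta),
    fill = c(g$site_class, "cumulative")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$what, y = .data$delta,
                                   fill = .data$fill)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(
      increase = "firebrick", decrease = "royalblue",
      unchanged = "grey60", cumulative = "grey40"
    )) +
    ggplot2::labs(
      x = NULL, y = expression(Delta * "PV"),
      title = sprintf("%s%d -> %s (%s, p = %.3g)", g$resname_unmod,
                      g$resno, g$resname_mod, g$verdict, g$wilcoxon_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot evaporation profiles
#'
#' Water-contact count versus ramp temperature for each residue of a
#' [build_profiles()] tibble.
#'
#' @param profiles Long profile tibble from [build_profiles()].
#' @return A ggplot object.
#' @export
plot_evaporation <- function(profiles) {
  df <- mutate(profiles, residue = paste0(.data$resname, .data$resno))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature_k,
                                   y = .data$n_contacts,
                                   color = .data$residue)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (K)", y = "water contacts",
                  color = NULL) +
    ggplot2::theme_minimal()
}
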