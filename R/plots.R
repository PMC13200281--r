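#' Bar chart of posterior mean rates of change per sector and device
#'
#' Mirrors the standard reporting figure: one bar pair per sector, posterior
#' mean rate of change with 95% CrI error bars, and an asterisk over sectors
#' where the Spectralis - Cirrus difference is significant.
#'
#' @param summaries One or more sector summaries ([summarize_sector()])
#'   row-bound together.
#' @return A ggplot object.
#' @export
plot_roc <- function(summaries) {
  plot_quantity(summaries, "roc", "RNFL rate of change (µm/year)")
}

#' Bar chart of posterior mean average residual SDs per sector and device
#'
#' Asterisks mark sectors where the Spectralis/Cirrus residual-SD ratio is
#' significantly different from 1.
#'
#' @inheritParams plot_roc
#' @return A ggplot object.
#' @export
plot_residual_sd <- function(summaries) {
  plot_quantity(summaries, "resid_sd", "Average residual SD (µm)")
}

plot_quantity <- function(summaries, quantity, ylab) {
  stopifnot(nrow(summaries) > 0)
  dev_rows <- summaries |>
    dplyr::filter(.data$quantity == !!quantity,
                  .data$contrast %in% device_levels()) |>
    dplyr::mutate(sector = factor(.data$sector, levels = sector_levels()))
  sig <- summaries |>
    dplyr::filter(.data$quantity == !!quantity,
                  .data$contrast %in% c("difference", "ratio"),
                  .data$verdict != "null") |>
    dplyr::mutate(sector = factor(.data$sector, levels = sector_levels()))
  p <- ggplot2::ggplot(dev_rows,
                       ggplot2::aes(x = .data$sector, y = .data$mean,
                                    fill = .data$contrast)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = "Sector", y = ylab, fill = "Device") +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0) {
    marks <- dev_rows |>
      dplyr::semi_join(sig, by = "sector") |>
      dplyr::group_by(.data$sector) |>
      dplyr::summarise(y = max(.data$upper, 0) + 0.05 *
                         diff(range(c(dev_rows$lower, dev_rows$upper))),
                       .groups = "drop")
    p <- p + ggplot2::geom_text(data = marks,
                                ggplot2::aes(x = .data$sector, y = .data$y,
                                             label = "*"),
                                inherit.aes = FALSE, size = 6)
  }
  p
}

#' Bar chart of significant-slope percentages with counts annotated
#'
#' @param proportions Row-bound output of [slope_proportions()] with a
#'   `sector` column; if the column is absent a single sector is assumed.
#' @param direction `"negative"` or `"positive"`.
#' @return A ggplot object.
#' @export
plot_proportions <- function(proportions, direction = "negative") {
  d <- proportions |> dplyr::filter(.data$direction == !!direction)
  if (!"sector" %in% names(d)) d$sector <- "G"
  d$sector <- factor(d$sector, levels = sector_levels())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sector,
                                  y = 100 * .data$proportion,
                                  fill = .data$device)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$n_significant),
      position = ggplot2::position_dodge(width = 0.8), vjust = -0.4,
      size = 3
    ) +
    ggplot2::labs(x = "Sector",
                  y = paste0("Eyes with significantly ", direction,
                             " RoC (%)"),
                  fill = "Device") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rnfl_sector_summary <- function(object, ...) {
  plot_roc(object)
}

#' @exportS3Method ggplot2::autoplot
autoplot.rnfl_classification <- function(object, ...) {
  plot_proportions(slope_proportions(object) |>
                     dplyr::mutate(sector = attr(object, "sector") %||% "G"))
}
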