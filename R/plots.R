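# ggplot2 graphics for the main result types.

#' Plot a PDFF map
#'
#' Raster of the fat-fraction map in percent; muscle compartment outlines
#' can be overlaid by passing the mask set.
#'
#' @param object a [pdff_map()].
#' @param masks optional [compartment_masks()] to overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pdff_map <- function(object, masks = NULL, ...) {
  df <- tidyr::expand_grid(
    x = seq_len(nrow(object$intensities)),
    y = seq_len(ncol(object$intensities))
  )
  df$fat <- object$intensities[cbind(df$x, df$y)] / 10
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$fat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "PDFF (%)", limits = c(0, 100)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0("PDFF map (", object$slice_label, ", ",
                     object$pixel_spacing, " mm)"),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(masks)) {
    md <- df
    md$compartment <- masks$labels[cbind(md$x, md$y)]
    md <- md[md$compartment > 0, ]
    p <- p + ggplot2::geom_tile(
      data = md,
      ggplot2::aes(x = .data$x, y = .data$y),
      fill = NA, colour = "white", linewidth = 0.05,
      inherit.aes = FALSE
    )
  }
  p
}

#' MRI-vs-BIA concordance scatter plot
#'
#' Scatter of an MRI muscle index against a BIA measure, coloured by obesity
#' stratum with per-stratum least-squares lines — the standard visual check
#' that concordance weakens in obese subjects.
#'
#' @param data joined cohort/measures tibble with an `obese` column.
#' @param outcome,predictor column names, default fat-free index vs SMI.
#' @return a ggplot object.
#' @export
plot_concordance <- function(data, outcome = "ammi_fatfree",
                             predictor = "smi_bia") {
  missing_cols <- setdiff(c(outcome, predictor, "obese"), names(data))
  if (length(missing_cols) > 0) {
    mm_abort(paste0("missing required columns: ",
                    paste(missing_cols, collapse = ", ")),
             class = "musclemap_schema_error")
  }
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data[[predictor]], y = .data[[outcome]],
                 colour = ifelse(.data$obese, "obese", "non-obese"),
                 shape = ifelse(.data$obese, "obese", "non-obese"))
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_colour_manual(values = c(`non-obese` = "#8ecae6",
                                            obese = "#19323c")) +
    ggplot2::labs(colour = NULL, shape = NULL, x = predictor, y = outcome) +
    ggplot2::theme_minimal()
}

#' Plot the correlation structure of a report
#'
#' Dot plot of Pearson r by MRI outcome, BIA predictor and obesity stratum.
#'
#' @param object a `muscle_report` from [run_full_analysis()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.muscle_report <- function(object, ...) {
  d <- object$correlations
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$r, y = .data$predictor, colour = .data$stratum)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "Pearson r", y = NULL, colour = "stratum") +
    ggplot2::theme_minimal()
}
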