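#' Plot a calibration curve over its standards
#'
#' @param standards Tibble from [read_calibration_standards()].
#' @param curve Optional fitted `calibration_curve` (fitted from the
#'   standards when `NULL`).
#' @return A ggplot.
#' @export
plot_calibration <- function(standards, curve = NULL) {
  curve <- curve %||% fit_calibration(standards)
  ggplot2::ggplot(standards,
                  ggplot2::aes(x = .data$concentration_mM,
                               y = .data$absorbance)) +
    ggplot2::geom_abline(slope = curve$slope, intercept = curve$intercept,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Myoglobin concentration (mM)", y = "Absorbance at 436 nm (OD)",
      title = sprintf("Calibration: OD = %.3f [Mb] + %.3f  (r² = %.4f)",
                      curve$slope, curve$intercept, curve$r_squared)) +
    ggplot2::theme_minimal()
}

#' Raster view of a section channel
#'
#' @param object A `muscle_section`.
#' @param channel Channel name (default `"transmission"`).
#' @param ... Unused.
#' @return A ggplot raster of the channel.
#' @export
autoplot.muscle_section <- function(object, channel = "transmission", ...) {
  m <- object$channels[[channel]]
  if (is.null(m)) abort(paste("No channel", channel))
  df <- tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = channel, x = NULL, y = NULL, fill = "gray") +
    ggplot2::theme_void()
}

#' Group-comparison panels for a study
#'
#' Box-and-jitter panels of the headline per-subject measures by group.
#'
#' @param object An `mb_study`.
#' @param variables Variables to panel.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_study <- function(object,
                              variables = c("mb_weighted_mM",
                                            "mrna_relative",
                                            "rna_per_mg", "mds_pL"),
                              ...) {
  df <- tidyr::pivot_longer(
    select(object$subjects, "subject_id", "group",
           dplyr::all_of(variables)),
    cols = dplyr::all_of(variables),
    names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.55) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
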