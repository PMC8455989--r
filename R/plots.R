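# ggplot2 displays for the main result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.mc_calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(s[, 1]),
                 std.error = unname(s[, 2]),
                 statistic = unname(s[, 3]),
                 p.value = unname(s[, 4]))
}

#' @export
glance.mc_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, nobs = x$n)
}

#' @export
autoplot.mc_calibration <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_um, y = .data$rfu)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::labs(x = "AMC (uM)", y = "Fluorescence (RFU)",
                  title = sprintf("AMC calibration: %.1f RFU/uM, R2 = %.4f",
                                  object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence time course
#'
#' @param trace Tibble with `time_min` and `rfu`.
#' @return A ggplot.
#' @export
plot_kinetics <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_min, y = .data$rfu)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Time (min)", y = "Fluorescence (RFU)") +
    ggplot2::theme_minimal()
}

#' Plot per-site delta oxidation
#'
#' Bars of delta oxidation per cysteine site, annotated with p-values.
#'
#' @param delta Tibble from [delta_oxidation()].
#' @return A ggplot.
#' @export
plot_delta_ox <- function(delta) {
  delta$site <- paste0(delta$protein, " C", delta$cys_pos)
  ggplot2::ggplot(delta, ggplot2::aes(x = .data$site, y = .data$delta_ox)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$p_value), "",
                     sprintf("p=%.3g", .data$p_value))), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Delta oxidation (percentage points)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot domain architectures of annotated proteins
#'
#' One horizontal track per protein with p20 and p10 domain segments,
#' the way metacaspase domain organization is usually drawn.
#'
#' @param annotations Tibble from [annotate_proteins()].
#' @return A ggplot.
#' @export
plot_domain_architecture <- function(annotations) {
  long <- dplyr::bind_rows(
    dplyr::transmute(annotations, id = .data$id, kind = "p20",
                     start = .data$p20_start, end = .data$p20_end),
    dplyr::transmute(annotations, id = .data$id, kind = "p10",
                     start = .data$p10_start, end = .data$p10_end)) |>
    dplyr::filter(!is.na(.data$start))
  ggplot2::ggplot(long, ggplot2::aes(y = .data$id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$id, color = .data$kind),
                          linewidth = 4) +
    ggplot2::scale_color_manual(values = c(p20 = "darkorange", p10 = "steelblue")) +
    ggplot2::labs(x = "Residue (0-based)", y = NULL, color = "Domain") +
    ggplot2::theme_minimal()
}
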