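#' Plot spore fraction and mean final B across the gradient
#'
#' The two summary curves of a gradient sweep, optionally overlaying a
#' second condition (e.g. the doubled stress-regulator transcription rate).
#'
#' @param r1 A `sweep_result`.
#' @param r2 Optional second `sweep_result` on the same grid.
#' @param what `"spore_fraction"` or `"mean_final_B"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(r1, r2 = NULL,
                       what = c("spore_fraction", "mean_final_B")) {
  what <- match.arg(what)
  df <- as.data.frame(r1)
  df$condition <- sprintf("s_B = %g", r1$s_B)
  if (!is.null(r2)) {
    d2 <- as.data.frame(r2)
    d2$condition <- sprintf("s_B = %g", r2$s_B)
    df <- rbind(df, d2)
  }
  ylab <- if (what == "spore_fraction") {
    "fraction of simulations producing a spore"
  } else {
    "mean final B (molecules)"
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$zeta, y = .data[[what]], colour = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(zeta ~ "(stress / gradient position)"),
                  y = ylab, colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot a depth profile
#'
#' @param profile A `depth_profile` tibble (or the output of
#'   [aggregate_profiles()], which adds SEM error bars).
#' @return A ggplot object.
#' @importFrom rlang .data
#' @export
plot_depth_profile <- function(profile) {
  yname <- if ("mean" %in% names(profile)) "mean" else "value"
  p <- ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$depth, y = .data[[yname]]
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth from biofilm top (µm)", y = yname) +
    ggplot2::theme_classic()
  if ("sem" %in% names(profile)) {
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem
    ), width = 0)
  }
  p
}
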