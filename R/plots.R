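#' Piper trilinear diagram
#'
#' Cation and anion ternary fields and the projected diamond, coloured by
#' depth class when available.
#'
#' @param data A data frame of samples.
#' @return A ggplot object.
#' @export
plot_piper <- function(data) {
  pc <- piper_coordinates(data)
  h <- sqrt(3) / 2
  tri <- function(x0) tibble::tibble(x = c(x0, x0 + 1, x0 + 0.5, x0),
                                     y = c(0, 0, h, 0))
  diamond <- tibble::tibble(x = c(1.05, 1.55, 1.05, 0.55, 1.05),
                            y = c(2 * h - h, 2 * h, 2 * h + h, 2 * h, 2 * h - h) - h)
  frame <- dplyr::bind_rows(
    dplyr::mutate(tri(0), part = "cations"),
    dplyr::mutate(tri(1.1), part = "anions"),
    dplyr::mutate(diamond, part = "diamond")
  )
  pts <- dplyr::bind_rows(
    tibble::tibble(x = pc$cation_x, y = pc$cation_y),
    tibble::tibble(x = pc$anion_x, y = pc$anion_y),
    tibble::tibble(x = pc$diamond_x, y = pc$diamond_y)
  )
  if ("depth_m" %in% names(data)) {
    pts$depth_class <- rep(classify_depth(data$depth_m), 3)
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = frame,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$part),
                       colour = "grey40", inherit.aes = FALSE)
  p <- if ("depth_class" %in% names(pts)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$depth_class), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(title = "Piper diagram", colour = "depth")
}

#' Gibbs diagram
#'
#' TDS (log scale) against the cation or anion weight ratio, with the
#' default mechanism-region boundaries drawn as guides.
#'
#' @inheritParams gibbs_classify
#' @return A ggplot object.
#' @export
plot_gibbs <- function(data, which = c("cation", "anion")) {
  which <- match.arg(which)
  g <- gibbs_classify(data, which)
  xlab <- if (which == "cation") "Na / (Na + Ca)" else "Cl / (Cl + HCO3)"
  ggplot2::ggplot(g, ggplot2::aes(x = .data$ratio, y = .data$tds,
                                  colour = .data$gibbs_region)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = c(70, 1000), linetype = 3, colour = "grey50") +
    ggplot2::labs(x = xlab, y = "TDS (mg/L)", colour = "mechanism",
                  title = "Gibbs diagram") +
    ggplot2::theme_minimal()
}

#' Wilcox irrigation diagram
#'
#' EC against \%Na with the default class-boundary guides.
#'
#' @param data A data frame of samples.
#' @return A ggplot object.
#' @export
plot_wilcox <- function(data) {
  idx <- irrigation_indices(data)
  bound <- tidyr::expand_grid(u = c(0.5, 1, 1.5, 2), ec = seq(0, 3500, 50)) |>
    dplyr::mutate(pna = pmin(pmax((.data$u - .data$ec / 3000) * 90, 0), 100))
  ggplot2::ggplot(idx, ggplot2::aes(x = .data$ec, y = .data$percent_na,
                                    colour = .data$wilcox_class)) +
    ggplot2::geom_line(data = bound,
                       ggplot2::aes(x = .data$ec, y = .data$pna, group = .data$u),
                       colour = "grey60", linetype = 2, inherit.aes = FALSE) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 3500), ylim = c(0, 100)) +
    ggplot2::labs(x = "EC (uS/cm)", y = "%Na", colour = "class",
                  title = "Wilcox diagram") +
    ggplot2::theme_minimal()
}

#' USSL irrigation diagram
#'
#' EC (log scale) against SAR with the C and S band boundaries.
#'
#' @param data A data frame of samples.
#' @return A ggplot object.
#' @export
plot_ussl <- function(data) {
  idx <- irrigation_indices(data)
  ggplot2::ggplot(idx, ggplot2::aes(x = .data$ec, y = .data$sar,
                                    colour = .data$ussl_class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(250, 750, 2250), linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_hline(yintercept = c(10, 18, 26), linetype = 2,
                        colour = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "EC (uS/cm)", y = "SAR", colour = "class",
                  title = "USSL diagram") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cumulative probability curve of Monte Carlo hazard quotients
#'
#' @param object An `mc_hq` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_hq <- function(object, ...) {
  tibble::tibble(hq = sort(object$hq),
                 p = seq_along(object$hq) / length(object$hq)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$hq, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "red") +
    ggplot2::labs(x = "Hazard quotient", y = "Cumulative probability",
                  title = paste("Monte Carlo HQ -", object$group),
                  subtitle = sprintf("P(HQ > 1) = %.1f%%", 100 * object$p_exceed)) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap
#'
#' @param object A `cor_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cor_screen <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::bind_rows(long,
                           dplyr::rename(long, var1 = "var2", var2 = "var1"),
                           tibble::tibble(var1 = object$vars, var2 = object$vars,
                                          r = 1, p_value = 0, stars = "",
                                          n = NA_integer_))
  long$var1 <- factor(long$var1, levels = object$vars)
  long$var2 <- factor(long$var2, levels = rev(object$vars))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$var1, y = .data$var2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = paste0(sprintf("%.2f", .data$r),
                                                   .data$stars)), size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pearson correlation screen") +
    ggplot2::theme_minimal()
}
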