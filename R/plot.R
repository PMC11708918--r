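#' Plot an allele-frequency trajectory
#'
#' Line plot of allele frequency against generation. Sex-structured
#' trajectories show hermaphrodite and male frequencies as separate series.
#'
#' @param object A `drive_trajectory` tibble from [iterate_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drive_trajectory <- function(object, ...) {
  if ("ph" %in% names(object)) {
    df <- tidyr::pivot_longer(object, c("ph", "pm"),
                              names_to = "sex", values_to = "p") |>
      dplyr::mutate(sex = dplyr::recode(.data$sex, ph = "hermaphrodites",
                                        pm = "males"))
    ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$p,
                                     colour = .data$sex)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::labs(x = "generation", y = "M1 allele frequency",
                    colour = NULL) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$generation, .data$p)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "generation", y = "M1 allele frequency") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  }
}

#' Plot invasion thresholds against selfing rate
#'
#' @param object A `threshold_grid` tibble from [threshold_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_grid <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$flag == "ok"),
                  ggplot2::aes(.data$S, .data$threshold)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "selfing rate S",
                  y = "invasion threshold frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Ternary phase portrait of the one-generation displacement field
#'
#' Draws the genotype simplex as an equilateral triangle (M1M1 left corner,
#' M2M2 right, heterozygotes apex) with a displacement segment at each grid
#' point; optionally marks the analytic unstable equilibrium.
#'
#' @param field A tibble from [vector_field()].
#' @param equilibrium Optional `drive_equilibrium` to mark.
#' @return A ggplot object.
#' @export
plot_vector_field <- function(field, equilibrium = NULL) {
  stopifnot(all(c("tern_x", "tern_y", "dX", "dY", "dZ") %in% names(field)))
  end_state <- tibble(X = field$X + field$dX, Y = field$Y + field$dY,
                      Z = field$Z + field$dZ)
  ends <- ternary_coords(end_state)
  df <- dplyr::bind_cols(field, xend = ends$tern_x, yend = ends$tern_y)
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  gg <- ggplot2::ggplot(df) +
    ggplot2::geom_path(data = tri, ggplot2::aes(.data$x, .data$y),
                       colour = "grey40") +
    ggplot2::geom_segment(ggplot2::aes(.data$tern_x, .data$tern_y,
                                       xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          linewidth = 0.3, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(equilibrium) && !is.na(equilibrium$p_hat)) {
    st <- state_from_pq(equilibrium$p_hat, equilibrium$Y_hat)
    tc <- ternary_coords(st)
    gg <- gg + ggplot2::geom_point(data = tc,
                                   ggplot2::aes(.data$tern_x, .data$tern_y),
                                   colour = "red", size = 2)
  }
  gg
}
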