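#' Plot a mobility profile
#'
#' Line plot of mobility against residue id with detected hinge residues
#' marked.
#'
#' @param object A `mobility_profile`.
#' @param hinges Optional residue ids to mark (e.g. from [find_hinges()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mobility_profile <- function(object, hinges = NULL, ...) {
  df <- tibble::tibble(residue_id = object$residue_id,
                       mobility = object$mobility)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_id,
                                        y = .data$mobility)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "residue", y = "mobility") +
    ggplot2::theme_minimal()
  if (!is.null(hinges)) {
    p <- p + ggplot2::geom_point(
      data = df[df$residue_id %in% hinges, , drop = FALSE],
      colour = "red", size = 1.5)
  }
  p
}

#' Plot a perturbation-response map
#'
#' Heat map of the PRS response matrix (perturbed residue on the vertical
#' axis, responding residue on the horizontal).
#'
#' @param object A `prs_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prs_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$responding, y = .data$perturbed,
                               fill = .data$response)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "responding residue", y = "perturbed residue",
                  fill = "response") +
    ggplot2::theme_minimal()
}

#' Plot a coevolution score matrix
#'
#' @param object A `coev_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coev_result <- function(object, ...) {
  df <- tidy(object)
  df2 <- df
  names(df2)[1:2] <- c("col_b", "col_a")
  ggplot2::ggplot(dplyr::bind_rows(df, df2),
                  ggplot2::aes(x = .data$col_a, y = .data$col_b,
                               fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "column", y = "column", fill = object$method) +
    ggplot2::theme_minimal()
}

#' Plot cumulative interdomain coevolution propensity
#'
#' Per-residue propensity bars, faceted by domain group.
#'
#' @param propensity A [cumulative_propensity()] tibble.
#' @return A ggplot object.
#' @export
plot_propensity <- function(propensity) {
  ggplot2::ggplot(propensity,
                  ggplot2::aes(x = .data$residue_id,
                               y = .data$propensity)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "cumulative interdomain propensity") +
    ggplot2::theme_minimal()
}
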