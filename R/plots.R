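#' Heatmap of a dissimilarity matrix
#'
#' @param object A `trait_dm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trait_dm <- function(object, ...) {
  df <- as_tibble(unclass(object), rownames = "row") %>%
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "dissimilarity") %>%
    mutate(
      row = factor(.data$row, levels = rownames(object)),
      col = factor(.data$col, levels = rownames(object))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = NULL, y = NULL, title = attr(object, "type")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Null distribution of a permutation test
#'
#' Histogram of the permuted group differences in correspondence with
#' the observed difference marked.
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null), ggplot2::aes(.data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "magenta",
                        linewidth = 1) +
    ggplot2::labs(
      x = "permuted delta rho (control - ASD)", y = "count",
      title = sprintf("%s: observed = %.3f, p = %.3f",
                      object$trait, object$observed, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Loading heatmap of a factor solution
#'
#' @param object An `efa_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.efa_fit <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(subscale = factor(.data$subscale,
                             levels = rev(rownames(object$loadings))))
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$subscale,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Oblimin pattern loadings (%.1f%% variance)",
                      100 * object$variance_explained_total)
    ) +
    ggplot2::theme_minimal()
}

#' Dot-and-interval plot of IS-RSA simple slopes
#'
#' @param x An `isrsa_fit` or `interaction_fit`.
#' @return A ggplot of within-group slopes per factor with 95% normal
#'   intervals.
#' @export
plot_simple_slopes <- function(x) {
  stopifnot(inherits(x, "interaction_fit"))
  df <- x$simple_slopes
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$B,
                                   colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$B - 1.96 * .data$se,
                   ymax = .data$B + 1.96 * .data$se),
      width = 0.2, position = ggplot2::position_dodge(0.4)
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = sprintf("slope on %s", x$trait), x = NULL) +
    ggplot2::theme_minimal()
}
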