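#' Plot the WLS distributions of a cross-validated classifier
#'
#' Density of the per-subject weighted linear summation, split by true
#' label, with the decision threshold at WLS = 0.
#'
#' @param object An `fc_loocv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fc_loocv
#' @export
autoplot.fc_loocv <- function(object, ...) {
  d <- object$per_subject %>%
    mutate(group = ifelse(.data$label == 1, "case", "control"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wls, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "weighted linear summation (WLS)", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the active weights of a sparse logistic model
#'
#' @param object An `fc_slr` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fc_slr
#' @export
autoplot.fc_slr <- function(object, ...) {
  d <- tidy(object) %>% filter(.data$active, .data$term != "(bias)")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                  y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "weight (standardized scale)") +
    ggplot2::theme_minimal()
}

#' Plot a feature-selection accumulation vector
#'
#' @param object An `fc_feature_selection`.
#' @param top Show only the `top` largest accumulations (NULL for all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fc_feature_selection
#' @export
autoplot.fc_feature_selection <- function(object, top = 50, ...) {
  d <- tidy(object) %>% arrange(dplyr::desc(.data$xi))
  if (!is.null(top)) d <- head(d, top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(factor(.data$index), .data$xi),
                                  y = .data$xi)) +
    ggplot2::geom_segment(ggplot2::aes(xend = factor(.data$index), yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "connectivity index", y = expression(xi)) +
    ggplot2::theme_minimal()
}
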