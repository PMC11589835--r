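# ggplot2 displays for the main result types.

#' Quantile-quantile plot of association p-values
#'
#' Observed vs expected -log10 p per phenotype, the standard display for
#' judging test calibration and excess signal.
#'
#' @param object A `pwas_assoc` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwas_assoc <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(!is.na(.data$p)) %>%
    group_by(.data$phenotype) %>%
    arrange(.data$p, .by_group = TRUE) %>%
    mutate(expected = -log10((row_number() - 0.5) / dplyr::n()),
           observed = -log10(pmax(.data$p, 1e-300))) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed,
                                   colour = .data$phenotype)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Cross-validated performance of the trained models
#'
#' Histogram of CV correlation R across proteins with the retention gate
#' marked at R = 0.1.
#'
#' @param object A `model_db`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_db <- function(object, ...) {
  df <- object$performance %>% filter(!is.na(.data$r_cv))
  ggplot2::ggplot(df, ggplot2::aes(.data$r_cv, fill = .data$retained)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = 2) +
    ggplot2::labs(x = "cross-validated R", y = "proteins") +
    ggplot2::theme_minimal()
}

#' Model yield across hidden-factor counts
#'
#' @param object A `factor_sweep` tibble from [sweep_hidden_factors()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.factor_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$k, .data$n_models)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hidden factors", y = "models passing the gate") +
    ggplot2::theme_minimal()
}

#' Marginal vs conditional association Z
#'
#' @param object A `pwas_conditional` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwas_conditional <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$z_marginal, .data$z_adjusted,
                               colour = .data$independent)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "marginal Z", y = "conditional Z") +
    ggplot2::theme_minimal()
}
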