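# broom-style methods for fitted objects.

#' Tidy a robust bisquare fit
#'
#' @param x A `robust_fit` from [robust_r2()].
#' @param ... Unused.
#' @return Tibble with one row per model term (`term`, `estimate`).
#' @export
tidy.robust_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' Robust-fit summary
#'
#' @param x A `robust_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r_squared`, `n`, `p` (predictors),
#'   `iterations`, `converged`, `c` (tuning constant).
#' @export
glance.robust_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n, p = x$p,
                 iterations = x$iterations, converged = x$converged,
                 c = x$c)
}

#' Scatter plot of a cost-recall style association
#'
#' @param object A `recallnet_assoc` row from [spearman_assoc()] does not
#'   retain the data, so this method plots from the raw vectors instead.
#' @param x,y The residualized vectors that produced the association.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_association <- function(object, x, y, ...) {
  df <- tibble::tibble(x = x, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         colour = "#B2182B", linewidth = 0.6) +
    ggplot2::labs(
      x = "Residualized network cost", y = "Residualized recall",
      title = sprintf("Spearman r = %.3f (p = %.2g, 95%% CI [%.2f, %.2f])",
                      object$r, object$p, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal(base_size = 10)
}
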