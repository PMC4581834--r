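#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a carrier prediction
#'
#' Haplotype l-HAF scores ordered by rank, colored by predicted label,
#' with the fitted component means as horizontal lines. Shape marks the
#' simulation truth when available.
#'
#' @param object A `precioss` tibble from [predict_carriers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot precioss
#' @export
autoplot.precioss <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$rank <- rank(df$score, ties.method = "first")
  fit <- attr(object, "fit")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                        colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(carrier = "#c0392b", `non-carrier` = "#2c3e80")) +
    ggplot2::labs(x = "haplotype (ranked by score)",
                  y = paste0(attr(object, "ell"), "-HAF score"),
                  colour = "predicted") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_hline(yintercept = fit$means,
                                 linetype = "dashed", colour = "grey40")
  }
  if (!is.null(df[["carrier_truth"]])) {
    p <- p + ggplot2::aes(shape = .data$carrier_truth) +
      ggplot2::labs(shape = "true carrier")
  }
  p
}

#' Expected carrier and non-carrier 1-HAF over a sweep
#'
#' Curves of the strong-selection expectations for carriers and
#' non-carriers as the carrier fraction `nu` runs from 0 to 1, with the
#' neutral constant-size expectation as a reference line.
#'
#' @param params A [demography()].
#' @return A ggplot object.
#' @export
plot_sweep_expectation <- function(params) {
  nu <- seq(0, 1, by = 0.01)
  df <- tibble::tibble(
    nu = rep(nu, 2),
    expected = c(expected_haf_carrier(nu, params),
                 expected_haf_noncarrier(nu, params)),
    class = rep(c("carrier", "non-carrier"), each = length(nu)))
  neutral <- params$theta * (params$n - 1) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nu, y = .data$expected,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = neutral, linetype = "dotted") +
    ggplot2::labs(x = "carrier fraction ν", y = "expected 1-HAF") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
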