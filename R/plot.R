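## ggplot2 views of the result types.

#' Plot a nucleotide profile as a logo-style bar chart
#'
#' Per-position stacked bars whose total height is the column's information
#' content in bits (0 to 2) and whose segments are proportional to the
#' nucleotide probabilities — the bar-chart analogue of a sequence logo.
#'
#' @param object A `pwm` or `pssv` profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nt_profile <- function(object, ...) {
  m <- profile_matrix(object)
  info <- 2 + rowSums(m * ifelse(m > 0, log2(m), 0))
  df <- tidy(object) |>
    dplyr::mutate(height = .data$prob * info[match(.data$pos, profile_positions(object))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$height,
                                   fill = .data$nucleotide)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "position", y = "information (bits)", fill = NULL) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Plot fitted branch proximities
#'
#' Dot plot of the fitted proximity \eqn{\hat q} per branch, with q = 1 (no
#' evolution) as reference line.
#'
#' @param object A `branch_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.branch_fit <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(!is.na(.data$q))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$q),
                                   y = .data$q)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fitted proximity q = exp(-t)") +
    ggplot2::theme_minimal()
}

#' Plot a per-position Jensen-Shannon divergence profile
#'
#' @param jsd Tibble from [jsd_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_jsd_profile <- function(jsd, ...) {
  ggplot2::ggplot(jsd, ggplot2::aes(x = .data$pos, y = .data$jsd)) +
    ggplot2::geom_col(width = 0.85, fill = "#F7B32B") +
    ggplot2::labs(x = "position", y = "Jensen-Shannon divergence (bits)") +
    ggplot2::theme_minimal()
}
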