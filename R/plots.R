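#' Plot a normalized table as a ranked abundance scatter
#'
#' Normalized/expected ratios on a log10 scale, sequences ordered from
#' lowest to highest, with guide lines at the expected value (1), the
#' 2-fold band (0.5, 2) and the 10-fold-under line (0.1) — the standard way
#' to eyeball how tightly a library clusters around its expectation.
#'
#' @param object An `lb_normtab` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lb_normtab <- function(object, ...) {
  df <- as_tibble(object) |>
    arrange(.data$ratio) |>
    mutate(rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey30") +
    ggplot2::geom_hline(yintercept = c(0.5, 2), colour = "grey70",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.1, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sequence rank", y = "normalized reads / expected")
}

#' Plot positional nucleotide enrichment as a heat map
#'
#' @param object An `lb_enrich` table from [positional_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lb_enrich <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$nucleotide,
                               fill = .data$enrichment)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, na.value = "grey80") +
    ggplot2::labs(x = "position in randomized region", y = NULL,
                  fill = "RNnp - 25 (%)")
}

#' Plot a positional frequency matrix
#'
#' @param object An `lb_pfm` table from [positional_frequency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lb_pfm <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$freq,
                               fill = .data$nucleotide)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position", y = "frequency (%)", fill = NULL)
}

#' Bar plot of junction-category or group distributions
#'
#' @param distribution A tibble from [category_distribution()] or
#'   [group_distribution()].
#' @return A ggplot object.
#' @export
plot_distribution <- function(distribution) {
  key <- names(distribution)[1]
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = factor(.data[[key]]), y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = key, y = "percent")
}

#' Ratio distributions split by number of unfavorable attributes
#'
#' @param norm An `lb_normtab` tibble.
#' @param attrs An [attribute_vectors()] tibble for the same pool.
#' @return A ggplot object (points on a log scale per 0-4 group).
#' @export
plot_unfavorable_groups <- function(norm, attrs) {
  df <- as_tibble(norm) |>
    left_join(select(attrs, "id", "n_unfavorable"), by = "id")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_unfavorable),
                                   y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey30") +
    ggplot2::geom_hline(yintercept = c(0.5, 2), colour = "grey70",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.1, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.2, size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "unfavorable attributes", y = "normalized / expected")
}
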