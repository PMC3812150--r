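#' Volcano plot of M1/M2 differential expression
#'
#' Difference of mean log2 expression (HIGH minus LOW TAM class) against
#' -log10 p, colored by panel, with the reference p cutpoint as a dashed
#' line.
#'
#' @param diffexpr Result of [differential_expression()] or [volcano_table()].
#' @param reference_p Dashed reference line (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(diffexpr, reference_p = 0.05) {
  d <- if ("neg_log10_p" %in% names(diffexpr)) diffexpr else volcano_table(diffexpr, reference_p)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$diff_means, y = .data$neg_log10_p,
                                  color = .data$panel_class)) +
    ggplot2::geom_hline(yintercept = -log10(reference_p), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "difference of means (high - low TAM, log2)",
                  y = expression(-log[10]~p), color = "panel") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param km A [km_estimate()] table.
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  start <- km |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, estimate = 1)
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   color = .data$group)) +
    ggplot2::geom_step(data = dplyr::bind_rows(start, km)) +
    ggplot2::geom_point(data = dplyr::filter(km, .data$n_censor > 0), shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "recurrence-free survival", color = NULL) +
    ggplot2::theme_minimal()
}

#' Vote distribution of a surrogate model
#'
#' Candidate-pool vote counts with the selected probes highlighted.
#'
#' @param model A `tam_surrogate`.
#' @param top Number of top-voted probes to display.
#' @return A ggplot object.
#' @export
plot_votes <- function(model, top = 20) {
  v <- sort(model$votes, decreasing = TRUE)[seq_len(min(top, length(model$votes)))]
  d <- tibble(probe_id = factor(names(v), levels = rev(names(v))),
              votes = as.integer(v),
              selected = names(v) %in% model$selected_probes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$votes, y = .data$probe_id,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "votes", y = NULL, fill = "selected") +
    ggplot2::theme_minimal()
}

#' @method autoplot tam_surrogate
#' @export
autoplot.tam_surrogate <- function(object, ...) plot_votes(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
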