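#' Plot the filtering funnel of a cascade result
#'
#' A per-step surviving-variant count funnel on a log axis: from the full
#' variant set through the coding/non-silent, panel, frequency and
#' recessive-model filters.
#'
#' @param object An `rd_cascade` from [run_cascade()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rd_cascade
#' @export
autoplot.rd_cascade <- function(object, ...) {
  tr <- object$trace
  tr$step <- factor(tr$step, levels = tr$step)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = pmax(.data$count, 0.5))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = paste("Filtering cascade:", object$patient_id),
      x = NULL, y = "surviving variants (log scale)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot cohort diagnostic yield
#'
#' Candidate-gene counts per index patient, coloured by solved status.
#'
#' @param results A list of `rd_cascade` objects.
#' @return A ggplot object.
#' @export
plot_cohort_yield <- function(results) {
  d <- purrr::map(results, glance) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$patient_id,
                                  y = .data$n_candidate_genes,
                                  fill = .data$solved)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "index patient", y = "candidate genes",
                  fill = "solved") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
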