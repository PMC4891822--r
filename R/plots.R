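#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   scale_x_log10 scale_y_log10 labs theme_minimal position_dodge
NULL

#' Expression scatter of a differential expression fit
#'
#' TPM in treatment against control on log10 axes, colored by regulation
#' category; the diagonal marks no change.
#'
#' @param object a `mirtap_de` fit.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mirtap_de <- function(object, ...) {
  p <- tidy(object) |>
    mutate(tpm_c = substitute_zero(.data$tpm_c, object$thresholds$zero_substitute),
           tpm_t = substitute_zero(.data$tpm_t, object$thresholds$zero_substitute))
  ggplot(p, aes(x = .data$tpm_c, y = .data$tpm_t, colour = .data$category)) +
    geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "control TPM", y = "treatment TPM", colour = "regulation") +
    theme_minimal()
}

#' Read-length histogram plot
#'
#' Total read share per insert length for both libraries; the 21- and 24-nt
#' modes typical of plant sRNA libraries stand out here.
#'
#' @param length_dist tibble from [length_distribution()].
#' @return a ggplot.
#' @export
plot_length_distribution <- function(length_dist) {
  long <- length_dist |>
    select("length", control = "total_pct_c", treatment = "total_pct_t") |>
    tidyr::pivot_longer(-"length", names_to = "library",
                        values_to = "percent")
  ggplot(long, aes(x = factor(.data$length), y = .data$percent,
                   fill = .data$library)) +
    geom_col(position = position_dodge()) +
    labs(x = "insert length (nt)", y = "% of total reads") +
    theme_minimal()
}

#' Annotation-category composition plot
#'
#' @param summary tibble from [summarize_categories()].
#' @return a ggplot.
#' @export
plot_category_summary <- function(summary) {
  long <- summary |>
    select("category", control = "total_pct_c", treatment = "total_pct_t") |>
    tidyr::pivot_longer(-"category", names_to = "library",
                        values_to = "percent")
  ggplot(long, aes(x = .data$category, y = .data$percent,
                   fill = .data$library)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "% of total reads") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
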