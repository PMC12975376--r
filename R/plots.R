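#' Histogram panel of diet-index distributions
#'
#' One histogram per index (PDI, rMED, HNFI) across the scored cohort.
#'
#' @param scores Output of [score_diet_indices()].
#' @return A ggplot object.
#' @export
plot_index_distribution <- function(scores) {
  long <- tidyr::pivot_longer(
    scores, c("pdi", "rmed", "hnfi"),
    names_to = "index", values_to = "score"
  )
  long$index <- factor(long$index, levels = c("pdi", "rmed", "hnfi"),
                       labels = c("PDI", "rMED", "HNFI"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), scales = "free_x") +
    ggplot2::labs(x = "Index score", y = "Participants") +
    ggplot2::theme_minimal()
}

#' Heritability estimates with confidence intervals
#'
#' Bar plot of the chosen-model additive-genetic fraction per trait with its
#' 95% CI, the analogue of the per-trait variance-decomposition figures.
#'
#' @param result A `twin_ace_result` (or its tidied table).
#' @param top_n Show only the `top_n` most heritable traits (default all).
#' @return A ggplot object.
#' @export
plot_heritability <- function(result, top_n = Inf) {
  tab <- if (inherits(result, "twin_ace_result")) result$table else result
  tab <- tab[!is.na(tab$a2), ]
  tab <- tab[order(-tab$a2), ]
  if (is.finite(top_n)) tab <- head(tab, top_n)
  tab$trait <- factor(tab$trait, levels = rev(tab$trait))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$a2, y = .data$trait)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$a2_lower, xmax = .data$a2_upper),
      height = 0.3, na.rm = TRUE
    ) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = expression(a^2 ~ "(fraction of variance, additive genetic)"),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.twin_ace_result <- function(object, ...) plot_heritability(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
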