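#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot corrected-index posteriors per cross
#'
#' Crossbar plot of the 9/50/91 posterior percentiles of each corrected
#' index, crosses ordered by decreasing median CI strength and colored by
#' male genotype.
#'
#' @param object A `ci_index_draws` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ci_index_draws
#' @export
autoplot.ci_index_draws <- function(object, ...) {
  s <- object$summary |>
    mutate(
      cross = paste0(.data$female_genotype, " × ", .data$male_genotype),
      index = factor(.data$index, c("ci_corr", "md_corr", "fm_corr"))
    )
  order_by_ci <- s |>
    filter(.data$index == "ci_corr") |>
    arrange(dplyr::desc(.data$q50)) |>
    pull(.data$cross)
  s <- s |> mutate(cross = factor(.data$cross, levels = order_by_ci))
  ggplot2::ggplot(
    s,
    ggplot2::aes(
      x = .data$cross, y = .data$q50, ymin = .data$q09, ymax = .data$q91,
      colour = .data$male_genotype
    )
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), ncol = 1) +
    ggplot2::labs(
      x = NULL, y = "corrected index (q09 / median / q91)",
      colour = "male genotype"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a WAIC model comparison
#'
#' @param object A `ci_model_comparison` object.
#' @param ... Unused.
#' @return A ggplot of WAIC with one-SE intervals.
#' @method autoplot ci_model_comparison
#' @export
autoplot.ci_model_comparison <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(model = factor(.data$model, levels = rev(.data$model)))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$waic, y = .data$model,
      xmin = .data$waic - .data$se, xmax = .data$waic + .data$se
    )
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::labs(x = "WAIC (± 1 se)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot finite-population SDs of model terms
#'
#' @param object A `group_sd_draws` object.
#' @param ... Unused.
#' @return A ggplot of the per-term posterior SD intervals.
#' @method autoplot group_sd_draws
#' @export
autoplot.group_sd_draws <- function(object, ...) {
  d <- object$summary |>
    mutate(group = factor(.data$group, levels = rev(.data$group)))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$q50, y = .data$group, xmin = .data$q09, xmax = .data$q91
    )
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::labs(
      x = "finite-population SD (q09 / median / q91)", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the posterior of the high-MD mixture weight
#'
#' Density of the posterior draws of `w` with the Mendelian expectations
#' `0.5^k` marked as reference lines.
#'
#' @param object A `mixture_fit` object.
#' @param k_max Largest locus number to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, k_max = 3, ...) {
  d <- tibble(w = object$draws[, "w"])
  marks <- tibble(
    k = seq_len(k_max), w = expected_extreme_fraction(seq_len(k_max))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$w)) +
    ggplot2::geom_density(fill = "grey80", colour = NA) +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$w), linetype = 2
    ) +
    ggplot2::geom_text(
      data = marks,
      ggplot2::aes(x = .data$w, y = 0, label = paste0("k=", .data$k)),
      vjust = -0.5, hjust = -0.1, size = 3
    ) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "high-MD component weight w", y = "posterior density") +
    ggplot2::theme_minimal()
}
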