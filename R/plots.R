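# ggplot2 autoplot methods for the main result types.

#' Plot a randomization null distribution
#'
#' Histogram of the permutation null sample with the observed statistic
#' marked.
#'
#' @param object A `pi_randomization` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pi_randomization <- function(object, bins = 50, ...) {
  null_df <- tibble(statistic = object$null_sample[is.finite(object$null_sample)])
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = sprintf("null %s statistic", if (object$statistic_kind == "t_like") "t" else "F"),
      y = "permutations",
      title = sprintf("Randomization test: p = %.4g (%d permutations%s)",
                      object$p_value, object$n_permutations,
                      if (object$exhaustive) ", exhaustive" else "")
    ) +
    ggplot2::theme_minimal()
}

#' Plot metabolome PCA sample scores
#'
#' Scatter plot of sample projections on two components, coloured by
#' exposure and shaped by genotype.
#'
#' @param object A `metab_pca` object.
#' @param components Length-2 vector of component indices or names.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metab_pca <- function(object, components = c(1, 2), ...) {
  comp <- ifelse(grepl("^PC", as.character(components)),
                 as.character(components), paste0("PC", components))
  ev <- object$explained_variance / sum(object$explained_variance)
  df <- dplyr::bind_cols(
    object$samples,
    tibble(.x = object$scores[, comp[1]], .y = object$scores[, comp[2]])
  )
  idx <- match(comp, colnames(object$scores))
  ggplot2::ggplot(df, ggplot2::aes(.data$.x, .data$.y,
                                   colour = .data$exposure, shape = .data$genotype)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", comp[1], 100 * ev[idx[1]]),
      y = sprintf("%s (%.1f%%)", comp[2], 100 * ev[idx[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-component separation Z scores
#'
#' Observed Z per component with significant components (permutation
#' p-value below `alpha`) highlighted.
#'
#' @param object A `pc_separation` table.
#' @param alpha Significance level for highlighting.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pc_separation <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(
      component = factor(.data$component, levels = .data$component),
      significant = .data$p_value < alpha
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$z_observed,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = NULL, y = "separation Z",
      title = sprintf("Group separation by component (%s labels)", attr(object, "grouping"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot Kaplan-Meier curves
#'
#' Right-continuous step plot of the survivor function per group.
#'
#' @param object A `km_curve` table from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time, .data$survival, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "age", y = "fraction surviving") +
    ggplot2::theme_minimal()
}

#' Plot per-treatment weighted preference indices
#'
#' Weighted mean preference index per treatment with weighted standard
#' errors.
#'
#' @param object A `preference_summary` table (see
#'   [summarize_preference()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.preference_summary <- function(object, ...) {
  df <- as_tibble(object)
  if (!"treatment" %in% names(df)) df$treatment <- "all"
  ggplot2::ggplot(df, ggplot2::aes(.data$treatment, .data$weighted_mean_pi)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$weighted_mean_pi - .data$weighted_sem,
      ymax = .data$weighted_mean_pi + .data$weighted_sem
    )) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "preference index (weighted mean ± SEM)") +
    ggplot2::theme_minimal()
}
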