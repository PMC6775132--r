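# ggplot2 views of the main result types.

#' Plot regulator activity profiles with confidence bands
#'
#' @param object An `nca_fit`.
#' @param regulators Optional subset of regulators to show.
#' @param ... Unused.
#' @return A ggplot: z-scored mean activity over time with the ensemble 95%
#'   band, one facet per regulator.
#' @method autoplot nca_fit
#' @export
autoplot.nca_fit <- function(object, regulators = NULL, ...) {
  d <- tidy(object)
  if (!is.null(regulators)) d <- d %>% filter(.data$regulator %in% regulators)
  ggplot(d, aes(x = .data$time, y = .data$activity)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                fill = "steelblue", alpha = 0.25) +
    geom_line(colour = "steelblue") +
    facet_wrap(~regulator, scales = "free_y") +
    labs(x = "time (h)", y = "z-scored activity",
         title = "Inferred regulator activities (NCA ensemble)") +
    theme_minimal()
}

#' Plot one metabolite-TF Hill fit
#'
#' Scatter of TF activity against metabolite concentration with the fitted
#' Hill curve overlaid.
#'
#' @param x Metabolite concentrations.
#' @param y TF activities (same lag-adjusted pairing used for the fit).
#' @param fit One-row tibble from [fit_hill_pair()] (or one row of a
#'   `hill_screen`).
#' @return A ggplot.
#' @export
plot_hill_fit <- function(x, y, fit) {
  stopifnot(nrow(fit) == 1, is.finite(fit$K_H))
  grid <- seq(min(x), max(x), length.out = 200)
  curve <- fit$baseline + fit$y_max * hill_u(grid, fit$K_H, fit$h, fit$mode)
  ggplot(tibble(x = x, y = y), aes(x = .data$x, y = .data$y)) +
    geom_point(colour = "grey30") +
    geom_line(data = tibble(x = grid, y = curve), colour = "firebrick") +
    labs(x = "metabolite concentration (µM)", y = "TF activity",
         subtitle = sprintf("%s, K_H = %.3g µM, h = %.2f, R² = %.3f",
                            fit$mode, fit$K_H, fit$h, fit$r_squared)) +
    theme_minimal()
}

#' Plot clustered time-course dynamics
#'
#' @param clusters Output of [cluster_dynamics()].
#' @return A ggplot of per-cluster mean z-scored profiles.
#' @export
plot_cluster_profiles <- function(clusters) {
  ggplot(clusters$profiles,
         aes(x = .data$time, y = .data$mean_value,
             colour = factor(.data$cluster))) +
    geom_line() +
    labs(x = "time (h)", y = "mean z-scored value", colour = "cluster") +
    theme_minimal()
}
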