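#' Bland-Altman plot
#'
#' Scatter of the paired difference against the pairwise mean with
#' horizontal lines at the bias and both limits of agreement (solid) and
#' their confidence bounds (dashed). Line positions come from the same
#' computation as [analyze_agreement()], so figure and table always agree.
#'
#' @param dataset A non-empty `cohort_dataset`.
#' @param z LOA multiplier (default 1.96).
#' @param level Confidence level for the CI bands (default 0.95).
#' @param loa_ci_method `"mover"` (default) or `"delta"`.
#' @param file Optional path; when given the figure is also written there
#'   (format from the extension, e.g. `.png`, `.svg`).
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_bland_altman <- function(dataset, z = 1.96, level = 0.95,
                              loa_ci_method = c("mover", "delta"),
                              file = NULL) {
  loa_ci_method <- match.arg(loa_ci_method)
  d <- differences(dataset)
  vc <- variance_components(d)
  lims <- loa(vc, z)
  bci <- bias_ci(vc, level)
  lci <- suppressWarnings(loa_ci(vc, level, z, loa_ci_method))
  hl <- data.frame(
    y = c(vc$grand_mean_diff, lims),
    role = c("bias", "loa", "loa")
  )
  ci_lines <- data.frame(
    y = c(bci, lci$lower, lci$upper)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pair_mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(data = hl,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$role)) +
    ggplot2::geom_hline(data = ci_lines,
                        ggplot2::aes(yintercept = .data$y),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::scale_linetype_manual(values = c(bias = "solid",
                                              loa = "dashed"),
                                   guide = "none") +
    ggplot2::labs(
      x = expression(paste("Mean CI of methods (", L %.% min^-1 %.% m^-2, ")")),
      y = expression(paste("Difference, test - reference (",
                           L %.% min^-1 %.% m^-2, ")")),
      title = sprintf("%s vs %s", attr(dataset, "device_name"),
                      attr(dataset, "reference_name")),
      subtitle = sprintf("bias %.2f, LOA %.2f to %.2f",
                         vc$grand_mean_diff, lims[["lower"]],
                         lims[["upper"]])
    ) +
    ggplot2::theme_minimal()
  attr(p, "lines") <- list(bias = vc$grand_mean_diff, loa = lims,
                           bias_ci = bci, loa_ci = lci)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 5)
    return(invisible(p))
  }
  p
}

#' Four-quadrant trending plot
#'
#' Scatter of the test device's consecutive percent change against the
#' reference device's, with the identity line through the origin and the
#' central exclusion box. When every pair falls inside the exclusion zone
#' the plot is annotated rather than failing.
#'
#' @param deltas Tibble from [delta_pairs()].
#' @param exclusion Exclusion threshold in percent (default 10).
#' @param file Optional output path.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_four_quadrant <- function(deltas, exclusion = 10, file = NULL) {
  fq <- if (nrow(deltas) > 0) {
    four_quadrant(deltas, exclusion, "percent")
  } else NULL
  lim <- max(20, exclusion * 1.5,
             if (nrow(deltas) > 0) max(abs(c(deltas$pct_ref,
                                             deltas$pct_test))) else 0)
  p <- ggplot2::ggplot(deltas,
                       ggplot2::aes(x = .data$pct_ref, y = .data$pct_test)) +
    ggplot2::annotate("rect", xmin = -exclusion, xmax = exclusion,
                      ymin = -exclusion, ymax = exclusion,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey30") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
    ggplot2::labs(x = "Δ reference CI (%)", y = "Δ test CI (%)",
                  subtitle = if (!is.null(fq) && !is.na(fq$concordance_rate)) {
                    sprintf("concordance %.1f%% (n = %d retained, %d excluded)",
                            fq$concordance_rate, fq$n_retained, fq$n_excluded)
                  } else {
                    "no pairs outside the exclusion zone"
                  }) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5.5, height = 5.5)
    return(invisible(p))
  }
  p
}
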