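# Figure-style plots: the normalized D* histogram with the fitted mixture
# density, and the per-condition immobile-fraction bar chart with replicate
# points.

#' Plot the D* distribution with an optional fitted mixture overlay
#'
#' @param d_star Numeric vector or [compute_dstars()] table.
#' @param fit Optional `dstar_mixture_fit`; its component and total densities
#'   are drawn over the normalized histogram.
#' @param binwidth Histogram bin width, um^2/s.
#' @param xmax Upper axis limit, um^2/s.
#' @return A ggplot object.
#' @export
plot_dstar_distribution <- function(d_star, fit = NULL, binwidth = 0.05,
                                    xmax = 3) {
  if (is.data.frame(d_star)) d_star <- d_star$d_star_um2_s
  df <- data.frame(d_star = d_star)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d_star)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      binwidth = binwidth, boundary = 0,
      fill = "grey80", colour = "grey50", linewidth = 0.2
    ) +
    ggplot2::coord_cartesian(xlim = c(0, xmax)) +
    ggplot2::labs(
      x = expression(D * "*" ~ (mu * m^2 / s)),
      y = "Probability density"
    ) +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "dstar_mixture_fit"))
    grid <- seq(1e-4, xmax, length.out = 400)
    comp <- do.call(rbind, lapply(seq_len(nrow(fit$species)), function(i) {
      data.frame(
        x = grid,
        density = fit$species$occupancy[i] *
          dstar_density(grid, fit$species$d[i], fit$n_steps),
        component = sprintf("D = %.2f", fit$species$d[i])
      )
    }))
    total <- data.frame(
      x = grid,
      density = rowSums(vapply(seq_len(nrow(fit$species)), function(i) {
        fit$species$occupancy[i] * dstar_density(grid, fit$species$d[i], fit$n_steps)
      }, numeric(length(grid))))
    )
    p <- p +
      ggplot2::geom_line(
        data = comp,
        ggplot2::aes(x = .data$x, y = .data$density, colour = .data$component),
        linewidth = 0.5
      ) +
      ggplot2::geom_line(
        data = total,
        ggplot2::aes(x = .data$x, y = .data$density),
        colour = "black", linewidth = 0.8
      ) +
      ggplot2::labs(colour = "Species")
  }
  p
}

#' Bar plot of immobile fractions per condition
#'
#' Mean +/- SD bars with the individual replicate values overlaid, one bar
#' per condition.
#'
#' @param report An `spt_report` from [run_pipeline()], or a list of
#'   `replicate_summary` objects.
#' @return A ggplot object.
#' @export
plot_immobile_fractions <- function(report) {
  summaries <- if (inherits(report, "spt_report")) report$conditions else report
  stopifnot(all(vapply(summaries, inherits, logical(1), "replicate_summary")))
  bars <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition, mean = s$mean, sd = s$sd)
  }))
  pts <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition, fraction = s$replicate_fractions)
  }))
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15
    ) +
    ggplot2::geom_jitter(
      data = pts,
      ggplot2::aes(x = .data$condition, y = .data$fraction),
      width = 0.08, size = 1.8, shape = 21, fill = "white"
    ) +
    ggplot2::labs(x = NULL, y = "Immobile fraction (%)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 .data
NULL
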