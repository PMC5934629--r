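#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   facet_wrap labs theme_bw geom_hline geom_function geom_jitter
NULL

#' @export
ggplot2::autoplot

#' Plot a fitted percent-bulk-replication time course
#'
#' Observed per-time-point values with the fitted Gompertz curve overlaid.
#'
#' @param object A [fit_gompertz()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gompertz_fit
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(
    time = seq(min(dat$time), max(dat$time), length.out = 200)
  )
  grid$percent <- predict(object, grid)
  ggplot(dat, aes(x = .data$time, y = .data$percent)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point(size = 2) +
    labs(
      x = "Time after release (min)", y = "% bulk replication",
      title = sprintf(
        "Gompertz fit: A = %.1f%%, k = %.3f /min, t0 = %.1f min",
        object$A, object$k, object$t0
      )
    ) +
    theme_bw()
}

#' Plot a relative copy-number profile
#'
#' Per-bin dots against genomic position, one panel per chromosome, with
#' guide lines at 1x and 2x. Masked bins are dropped.
#'
#' @param object A `copy_number_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot copy_number_profile
#' @export
autoplot.copy_number_profile <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!d$masked, ]
  ggplot(d, aes(x = (.data$start + .data$end) / 2e3, y = .data$value)) +
    geom_hline(yintercept = c(1, 2), linetype = "dashed", colour = "grey70") +
    geom_point(size = 0.4, alpha = 0.6) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "Position (kb)", y = "Relative copy number") +
    theme_bw()
}

#' Plot an in-silico Southern lane
#'
#' Intensity against fragment length for a rendered lane profile.
#'
#' @param object A [render_lane()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lane_profile
#' @export
autoplot.lane_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$length, y = .data$intensity)) +
    geom_line() +
    labs(x = "Fragment length (bp)", y = "Relative intensity") +
    theme_bw()
}

#' Plot per-isolate terminal fragment lengths by strain
#'
#' Jittered per-isolate means per strain, the usual summary figure for a
#' telomere-length comparison.
#'
#' @param data Output of [isolate_mean_lengths()] (columns `strain`,
#'   `mean_length`).
#' @return A ggplot.
#' @export
plot_telomere_lengths <- function(data) {
  d <- as_tibble(data)
  ggplot(d, aes(x = .data$strain, y = .data$mean_length)) +
    geom_jitter(width = 0.08, height = 0, size = 2) +
    labs(x = NULL, y = "Terminal fragment length (bp)") +
    theme_bw()
}
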