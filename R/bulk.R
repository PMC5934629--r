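#' Percent bulk replication from mean DNA content
#'
#' Places a sample's mean DNA content linearly between the 1C and 2C
#' fluorescence references: `100 * (mean - c1) / (c2 - c1)`, clamped to
#' \[0, 100\] so that slight overshoot from measurement noise does not
#' error. Invariant under any common rescaling of fluorescence units
#' applied to all three arguments.
#'
#' @param mean_content Mean DNA-content value(s) of singlet cells
#'   (arbitrary fluorescence units); vectorised.
#' @param c1_reference 1C (unreplicated) reference value.
#' @param c2_reference 2C (fully replicated) reference value; must exceed
#'   `c1_reference`.
#' @return Percent bulk replication in \[0, 100\].
#' @examples
#' percent_bulk_from_mean(1.5, 1, 2)
#' @export
percent_bulk_from_mean <- function(mean_content, c1_reference, c2_reference) {
  if (!is.numeric(c1_reference) || !is.numeric(c2_reference) ||
    c1_reference <= 0 || c2_reference <= c1_reference) {
    abort("calibration error: need `c2_reference` > `c1_reference` > 0")
  }
  pmin(100, pmax(0, 100 * (mean_content - c1_reference) /
    (c2_reference - c1_reference)))
}

#' Evaluate a Gompertz bulk-replication curve
#'
#' `A * exp(-exp(-k * (t - t0)))`: strictly increasing in `t`, tending to 0
#' as `t -> -Inf` and to the asymptote `A` as `t -> Inf`, with value `A/e`
#' at the inflection time `t0`.
#'
#' @param t Time(s) in minutes; vectorised.
#' @param A Asymptote in percent (0 < A <= 100).
#' @param k Rate constant in 1/min (> 0).
#' @param t0 Inflection time in minutes.
#' @return Percent bulk replication at `t`.
#' @examples
#' gompertz(30, A = 100, k = 0.2, t0 = 30) # 100 / e
#' @export
gompertz <- function(t, A, k, t0) {
  if (inherits(A, "gompertz_fit")) {
    fit <- A
    A <- fit$A
    k <- fit$k
    t0 <- fit$t0
  }
  A * exp(-exp(-k * (t - t0)))
}

#' Fit a Gompertz curve to a percent-bulk-replication time course
#'
#' Least-squares fit of `A * exp(-exp(-k (t - t0)))` to per-time-point
#' percent-bulk values by Levenberg-Marquardt with box constraints
#' (0 < A <= 100, k > 0). Start values: `A` at the maximum observed value,
#' `t0` at the time the course first crosses half its maximum, and
#' `k = 4 / range(t)`.
#'
#' @param timepoints Data frame with columns `time` (minutes) and
#'   `percent` (percent bulk replication), at least 4 rows spanning both
#'   low (< 25) and high (> 50) values.
#' @return An object of class `gompertz_fit`: list with `A`, `k`, `t0`,
#'   the `nls` fit, and a `data` tibble carrying per-point fitted values
#'   and residuals. Supports [tidy()], [glance()], [predict()] and
#'   [autoplot()].
#' @examples
#' tc <- data.frame(time = seq(0, 80, 10))
#' tc$percent <- gompertz(tc$time, A = 95, k = 0.15, t0 = 35)
#' fit <- fit_gompertz(tc)
#' glance(fit)
#' @export
fit_gompertz <- function(timepoints) {
  tp <- as_tibble(timepoints)
  if (!all(c("time", "percent") %in% names(tp))) {
    abort("`timepoints` must have columns `time` and `percent`")
  }
  tp <- arrange(tp, .data$time)
  if (nrow(tp) < 4) abort("need at least 4 time points to fit")
  if (max(tp$percent) <= 50 || min(tp$percent) >= 25) {
    abort(paste0(
      "degenerate time course: values must span both low (< 25) and ",
      "high (> 50) percent bulk replication"
    ))
  }
  a0 <- max(tp$percent)
  half <- tp$time[which(tp$percent >= a0 / 2)[1]]
  k0 <- 4 / max(diff(range(tp$time)), 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      percent ~ A * exp(-exp(-k * (time - t0))),
      data = tp,
      start = list(A = min(a0, 100), k = k0, t0 = half),
      lower = c(A = 1e-6, k = 1e-6, t0 = min(tp$time) - diff(range(tp$time))),
      upper = c(A = 100, k = Inf, t0 = max(tp$time) + diff(range(tp$time))),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) {
      abort(paste0(
        "Gompertz fit failed to converge: ", conditionMessage(e),
        " [n = ", nrow(tp), ", percent range ",
        round(min(tp$percent), 2), "-", round(max(tp$percent), 2), "]"
      ))
    }
  )
  cf <- stats::coef(fit)
  data <- mutate(
    tp,
    fitted = gompertz(.data$time, cf[["A"]], cf[["k"]], cf[["t0"]]),
    residual = .data$percent - .data$fitted
  )
  structure(
    list(
      A = cf[["A"]], k = cf[["k"]], t0 = cf[["t0"]],
      fit = fit, data = data
    ),
    class = "gompertz_fit"
  )
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(
    "<gompertz_fit> A = ", signif(x$A, 5), " %, k = ", signif(x$k, 5),
    " /min, t0 = ", signif(x$t0, 5), " min (",
    nrow(x$data), " time points, RMS residual ",
    signif(sqrt(mean(x$data$residual^2)), 3), " %)\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a Gompertz fit
#'
#' @param x A `gompertz_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy gompertz_fit
#' @export
tidy.gompertz_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"])
  )
}

#' One-row summary of a Gompertz fit
#'
#' @param x A `gompertz_fit`.
#' @param ... Unused.
#' @return Tibble with `A`, `k`, `t0`, `sigma` (residual standard error),
#'   `n` and `deviance`.
#' @method glance gompertz_fit
#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble(
    A = x$A, k = x$k, t0 = x$t0,
    sigma = summary(x$fit)$sigma,
    n = nrow(x$data),
    deviance = sum(x$data$residual^2)
  )
}

#' Per-time-point fitted values and residuals
#'
#' @param x A `gompertz_fit`.
#' @param ... Unused.
#' @return The input time course with `fitted` and `residual` columns.
#' @method augment gompertz_fit
#' @export
augment.gompertz_fit <- function(x, ...) {
  x$data
}

#' Predict percent bulk replication at new times
#'
#' @param object A `gompertz_fit`.
#' @param newdata Optional data frame with a `time` column (default: the
#'   fitted time points).
#' @param ... Unused.
#' @return Numeric vector of percent-bulk values.
#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else newdata$time
  gompertz(t, object$A, object$k, object$t0)
}

#' Summarise a flow time course into percent bulk replication
#'
#' Takes long-format flow events (`time`, `content`), computes the mean
#' DNA content per time point, and converts it to percent bulk replication
#' against 1C/2C references. By default the 1C reference is the mean
#' content of the earliest (arrested) time point and the 2C reference is
#' twice that, the usual calibration when the t = 0 sample is G1-arrested.
#'
#' @param events Data frame with columns `time` and `content`.
#' @param c1_reference,c2_reference Optional explicit references in the
#'   same units as `content`.
#' @return Tibble (`time`, `mean_content`, `percent`).
#' @export
percent_bulk_course <- function(events, c1_reference = NULL,
                                c2_reference = NULL) {
  ev <- as_tibble(events)
  if (!all(c("time", "content") %in% names(ev))) {
    abort("`events` must have columns `time` and `content`")
  }
  means <- summarise(
    group_by(ev, .data$time),
    mean_content = mean(.data$content),
    .groups = "drop"
  )
  means <- arrange(means, .data$time)
  c1 <- c1_reference %||% means$mean_content[1]
  c2 <- c2_reference %||% (2 * c1)
  mutate(means, percent = percent_bulk_from_mean(.data$mean_content, c1, c2))
}
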