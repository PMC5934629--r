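#' Simulate flow-cytometry DNA-content events
#'
#' Each event is one cell's DNA content on a scale where an unreplicated
#' (1C) genome reads 1.0 and a fully replicated (2C) genome reads 2.0:
#' content = (1 + genome-wide replicated fraction) times multiplicative
#' measurement noise with the requested coefficient of variation. Noise is
#' lognormal with mean exactly 1, so events stay positive and `cv = 0`
#' reproduces the noiseless content exactly.
#'
#' @param population A [simulate_population()] result.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param n_events Number of events to record; cells are resampled with
#'   replacement when `n_events` exceeds the population size.
#' @param seed Integer seed.
#' @return Tibble (`event`, `content`) with attribute `time`.
#' @export
simulate_flow_cytometry <- function(population, cv = 0.05, n_events = 10000,
                                    seed = 1) {
  fr <- replicated_fractions(population)
  if (nrow(fr) == 0L) abort("empty population")
  if (!is.numeric(cv) || cv < 0) abort("`cv` must be >= 0")
  with_seed(seed, {
    cells <- sample.int(nrow(fr), n_events, replace = TRUE)
    base <- 1 + fr$fraction[cells]
    noise <- if (cv == 0) {
      rep(1, n_events)
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n_events, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    structure(
      tibble(event = seq_len(n_events), content = base * noise),
      time = attr(population, "time")
    )
  })
}

#' Simulate a flow-cytometry time course
#'
#' Runs [simulate_flow_cytometry()] over matched populations from
#' [simulate_time_course()] and stacks the events with a `time` column, the
#' long format consumed by [fit_gompertz()] after summarising with
#' [percent_bulk_from_mean()].
#'
#' @param course A list of populations from [simulate_time_course()].
#' @inheritParams simulate_flow_cytometry
#' @return Tibble (`time`, `event`, `content`).
#' @export
simulate_flow_time_course <- function(course, cv = 0.05, n_events = 10000,
                                      seed = 1) {
  purrr::map_dfr(course, function(pop) {
    ev <- simulate_flow_cytometry(
      pop, cv, n_events,
      seed = child_seed(seed, paste0("flow", attr(pop, "time")))
    )
    dplyr::mutate(ev, time = attr(pop, "time"), .before = 1)
  })
}
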