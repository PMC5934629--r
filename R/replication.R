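#' Draw per-cell origin firing times
#'
#' Each origin is licensed ("competent") with its competence probability;
#' licensed origins draw a firing time from a normal distribution with the
#' origin's median and spread, truncated at zero. A spread of zero gives
#' deterministic firing at the median. The draw is independent of the
#' observation time, so states computed from one draw at increasing times
#' describe the same cell progressing through S phase.
#'
#' @param genome A [genome_model()].
#' @param seed Integer seed.
#' @return Tibble with one row per origin: `chrom`, `pos`, `fired`
#'   (logical, licensed in this cell) and `t_fire` (minutes; `NA` when not
#'   licensed).
#' @export
draw_firing_times <- function(genome, seed) {
  stopifnot(inherits(genome, "genome_model"))
  ori <- genome$origins
  with_seed(seed, {
    fired <- stats::runif(nrow(ori)) < ori$competence
    # inverse-CDF sampling from the normal truncated at 0
    lo <- stats::pnorm(0, mean = ori$t_median, sd = ori$t_spread)
    lo[ori$t_spread == 0] <- 0
    u <- stats::runif(nrow(ori), min = lo, max = 1)
    t_fire <- ifelse(
      ori$t_spread == 0,
      ori$t_median,
      stats::qnorm(u, mean = ori$t_median, sd = ori$t_spread)
    )
    t_fire[!fired] <- NA_real_
    tibble(
      chrom = ori$chrom, pos = ori$pos,
      fired = fired, t_fire = t_fire
    )
  })
}

# Replicated intervals of one cell at time t given its firing draw.
# Passive replication needs no special casing: an origin overtaken by a
# fork before its own firing time would only create an interval already
# contained in the overtaking fork's span, so the union is identical.
replication_intervals <- function(genome, firing, t) {
  v <- genome$fork_speed
  purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(i) {
    chrom <- genome$chromosomes$chrom[i]
    len <- genome$chromosomes$length[i]
    f <- firing[firing$chrom == chrom & firing$fired &
      !is.na(firing$t_fire) & firing$t_fire <= t, ]
    if (nrow(f) == 0L) {
      return(tibble(chrom = character(0), start = numeric(0), end = numeric(0)))
    }
    half <- v * (t - f$t_fire)
    iv <- merge_intervals(pmax(0, f$pos - half), pmin(len, f$pos + half))
    tibble(chrom = chrom, start = iv$start, end = iv$end)
  })
}

#' Simulate the replication state of a single cell
#'
#' Stochastic origin firing with bidirectional fork progression: licensed
#' origins fire at their drawn times, forks extend at the genome's fork
#' speed, and overlapping replicated stretches are merged. Intervals are
#' 0-based, half-open, clipped to chromosome bounds.
#'
#' @param genome A [genome_model()].
#' @param t Time in minutes after release (>= 0).
#' @param seed Integer seed for the firing draw.
#' @return Tibble of replicated intervals (`chrom`, `start`, `end`),
#'   disjoint and sorted within each chromosome, with attribute `time`.
#' @examples
#' gm <- genome_model(
#'   data.frame(chrom = "chrI", length = 200000),
#'   data.frame(chrom = "chrI", pos = 100000, t_median = 10, t_spread = 0,
#'              competence = 1)
#' )
#' simulate_cell_replication(gm, t = 20, seed = 1)
#' @export
simulate_cell_replication <- function(genome, t, seed) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    abort("`t` must be a single non-negative time in minutes")
  }
  firing <- draw_firing_times(genome, seed)
  out <- replication_intervals(genome, firing, t)
  attr(out, "time") <- t
  out
}

#' Simulate a population of replicating cells
#'
#' Draws independent firing times for `n_cells` cells and returns their
#' replicated intervals at time `t`, stacked with a `cell` index. The
#' result carries the genome, time and cell count as attributes and is the
#' population object consumed by [sample_read_counts()] and
#' [simulate_flow_cytometry()].
#'
#' @param genome A [genome_model()].
#' @param t Time in minutes after release.
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed; fans out deterministically per cell.
#' @return Tibble (`cell`, `chrom`, `start`, `end`) of class
#'   `replication_population`.
#' @export
simulate_population <- function(genome, t, n_cells = 100, seed = 1) {
  stopifnot(inherits(genome, "genome_model"), n_cells >= 1)
  firings <- purrr::map(
    seq_len(n_cells),
    function(c) draw_firing_times(genome, child_seed(seed, paste0("cell", c)))
  )
  pop <- purrr::map_dfr(seq_len(n_cells), function(c) {
    iv <- replication_intervals(genome, firings[[c]], t)
    if (nrow(iv) == 0L) return(iv[, c("chrom", "start", "end")])
    dplyr::mutate(iv, cell = c, .before = 1)
  })
  if (!"cell" %in% names(pop)) {
    pop <- tibble(
      cell = integer(0), chrom = character(0),
      start = numeric(0), end = numeric(0)
    )
  }
  structure(
    pop,
    class = c("replication_population", class(pop)),
    genome = genome, time = t, n_cells = n_cells
  )
}

#' Per-cell genome-wide replicated fractions of a population
#'
#' @param population A [simulate_population()] result.
#' @return Tibble (`cell`, `fraction`) with one row per cell, including
#'   cells with nothing replicated (fraction 0).
#' @export
replicated_fractions <- function(population) {
  genome <- attr(population, "genome")
  n_cells <- attr(population, "n_cells")
  if (is.null(genome) || is.null(n_cells)) {
    abort("`population` must come from simulate_population()")
  }
  total <- sum(genome$chromosomes$length)
  done <- dplyr::summarise(
    dplyr::group_by(as_tibble(population), .data$cell),
    bp = sum(.data$end - .data$start),
    .groups = "drop"
  )
  out <- tibble(cell = seq_len(n_cells))
  out <- left_join(out, done, by = "cell")
  out$fraction <- ifelse(is.na(out$bp), 0, out$bp / total)
  out[, c("cell", "fraction")]
}

#' Simulate matched populations across an S-phase time course
#'
#' Uses one firing draw per cell reused at every time point, so each cell's
#' replicated fraction is non-decreasing along the course (the population
#' is literally the same set of cells observed later).
#'
#' @inheritParams simulate_population
#' @param times Numeric vector of times (minutes after release).
#' @return Named list of `replication_population` objects, one per time.
#' @export
simulate_time_course <- function(genome, times, n_cells = 100, seed = 1) {
  stopifnot(inherits(genome, "genome_model"), length(times) >= 1)
  firings <- purrr::map(
    seq_len(n_cells),
    function(c) draw_firing_times(genome, child_seed(seed, paste0("cell", c)))
  )
  out <- purrr::map(times, function(t) {
    pop <- purrr::map_dfr(seq_len(n_cells), function(c) {
      iv <- replication_intervals(genome, firings[[c]], t)
      if (nrow(iv) == 0L) return(iv[, c("chrom", "start", "end")])
      dplyr::mutate(iv, cell = c, .before = 1)
    })
    if (!"cell" %in% names(pop)) {
      pop <- tibble(
        cell = integer(0), chrom = character(0),
        start = numeric(0), end = numeric(0)
      )
    }
    structure(
      pop,
      class = c("replication_population", class(pop)),
      genome = genome, time = t, n_cells = n_cells
    )
  })
  names(out) <- paste0("t", times)
  out
}

#' True per-bin replicated fraction of a population
#'
#' The ground truth that a copy-number profile estimates: for each bin, the
#' mean (over cells) fraction of the bin's bases that are replicated.
#'
#' @param population A [simulate_population()] result.
#' @param bin_size Bin width in bp (default 1000).
#' @return Tibble (`chrom`, `start`, `end`, `fraction`, `partial`).
#' @export
bin_replicated_fraction <- function(population, bin_size = 1000) {
  genome <- attr(population, "genome")
  n_cells <- attr(population, "n_cells")
  if (is.null(genome)) abort("`population` must come from simulate_population()")
  pop <- as_tibble(population)
  purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(i) {
    chrom <- genome$chromosomes$chrom[i]
    len <- genome$chromosomes$length[i]
    grid <- bin_grid(len, bin_size)
    iv <- pop[pop$chrom == chrom, ]
    cov <- accumulate_bin_coverage(iv$start, iv$end, len, bin_size)
    tibble(
      chrom = chrom, start = grid$start, end = grid$end,
      fraction = cov / (n_cells * (grid$end - grid$start)),
      partial = grid$partial
    )
  })
}

# Bin grid over [0, len): 0-based half-open bins of width bin_size, with a
# trailing partial bin when len is not a multiple.
bin_grid <- function(len, bin_size) {
  starts <- bin_size * (seq_len(ceiling(len / bin_size)) - 1)
  ends <- pmin(starts + bin_size, len)
  tibble(start = starts, end = ends, partial = (ends - starts) < bin_size)
}

# Sum of replicated bp per bin over a stack of intervals on one chromosome.
accumulate_bin_coverage <- function(start, end, len, bin_size) {
  nb <- ceiling(len / bin_size)
  cov <- numeric(nb)
  if (length(start) == 0L) return(cov)
  for (k in seq_along(start)) {
    s <- start[k]
    e <- min(end[k], len)
    if (e <= s) next
    fb <- floor(s / bin_size) + 1L
    lb <- ceiling(e / bin_size)
    if (fb == lb) {
      cov[fb] <- cov[fb] + (e - s)
    } else {
      cov[fb] <- cov[fb] + (fb * bin_size - s)
      cov[lb] <- cov[lb] + (e - (lb - 1L) * bin_size)
      if (lb - fb > 1L) {
        mid <- (fb + 1L):(lb - 1L)
        cov[mid] <- cov[mid] + bin_size
      }
    }
  }
  cov
}
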