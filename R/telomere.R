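#' Strain parameters for telomere TG-tract simulation
#'
#' @param strain Strain label(s).
#' @param mean_tg Wild-type mean TG tract length in bp (> 0; default 300,
#'   a typical budding-yeast figure).
#' @param sd_tg Standard deviation of TG length across telomeres in bp
#'   (>= 0; default 75).
#' @param elongation Elongation offset in bp relative to wild type
#'   (default 0; e.g. ~600 for a mutant that over-extends its telomeres).
#' @param site_offset Distance in bp from the diagnostic restriction site
#'   to the TG tract start (default 0); used by
#'   [terminal_fragment_length()].
#' @return Tibble with one row per strain.
#' @export
telomere_strain_params <- function(strain, mean_tg = 300, sd_tg = 75,
                                   elongation = 0, site_offset = 0) {
  if (any(mean_tg <= 0)) abort("`mean_tg` must be > 0")
  if (any(sd_tg < 0)) abort("`sd_tg` must be >= 0")
  if (any(site_offset < 0)) abort("`site_offset` must be >= 0")
  tibble(
    strain = strain, mean_tg = mean_tg, sd_tg = sd_tg,
    elongation = elongation, site_offset = site_offset
  )
}

#' Simulate per-telomere TG tract lengths
#'
#' Draws each telomere's TG tract length, per isolate, from a normal
#' distribution with mean `mean_tg + elongation` and standard deviation
#' `sd_tg`, truncated at zero (a tract cannot be negative).
#'
#' @param params A [telomere_strain_params()] tibble (one or more strains).
#' @param n_telomeres Telomeres per isolate (>= 1; a haploid yeast strain
#'   has 32 chromosome ends, the default).
#' @param n_isolates Independent isolates per strain (default 3).
#' @param seed Integer seed.
#' @return Tibble (`strain`, `isolate`, `telomere`, `tg_length`,
#'   `site_offset`).
#' @export
simulate_telomere_lengths <- function(params, n_telomeres = 32,
                                      n_isolates = 3, seed = 1) {
  params <- as_tibble(params)
  need <- c("strain", "mean_tg", "sd_tg", "elongation", "site_offset")
  if (!all(need %in% names(params))) {
    abort("`params` must come from telomere_strain_params()")
  }
  if (n_telomeres < 1) abort("`n_telomeres` must be >= 1")
  purrr::map_dfr(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    mu <- p$mean_tg + p$elongation
    purrr::map_dfr(seq_len(n_isolates), function(iso) {
      s <- child_seed(seed, paste0(p$strain, "_iso", iso))
      lens <- with_seed(s, {
        if (p$sd_tg == 0) {
          rep(mu, n_telomeres)
        } else {
          # inverse-CDF draw from the normal truncated at 0
          lo <- stats::pnorm(0, mean = mu, sd = p$sd_tg)
          u <- stats::runif(n_telomeres, min = lo, max = 1)
          stats::qnorm(u, mean = mu, sd = p$sd_tg)
        }
      })
      tibble(
        strain = p$strain, isolate = iso,
        telomere = seq_len(n_telomeres),
        tg_length = pmax(lens, 0),
        site_offset = p$site_offset
      )
    })
  })
}

#' Terminal restriction fragment length
#'
#' The fragment detected on a telomere Southern blot runs from the
#' diagnostic restriction site through the chromosome terminus, so its
#' length is the fixed subtelomeric offset plus the TG tract length.
#'
#' @param site_offset Distance from restriction site to TG tract start in
#'   bp (>= 0); vectorised.
#' @param tg_length TG tract length in bp (>= 0); vectorised.
#' @return Fragment length(s) in bp.
#' @examples
#' terminal_fragment_length(1234, 300) # PvuII-style construct
#' @export
terminal_fragment_length <- function(site_offset, tg_length) {
  if (any(site_offset < 0)) abort("`site_offset` must be >= 0")
  if (any(tg_length < 0)) abort("`tg_length` must be >= 0")
  site_offset + tg_length
}

#' Render an in-silico Southern lane from fragment lengths
#'
#' A Gaussian kernel density over fragment length stands in for the blot
#' smear; no gel-migration physics is modelled, the lane lives directly in
#' length space. The profile integrates to 1 over its grid.
#'
#' @param lengths Fragment lengths in bp (>= 1 value).
#' @param bandwidth Kernel bandwidth in bp (default 25).
#' @param n_grid Grid points (default 512).
#' @return A `lane_profile` tibble (`length`, `intensity`) with attribute
#'   `bandwidth`.
#' @export
render_lane <- function(lengths, bandwidth = 25, n_grid = 512) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 1 || anyNA(lengths)) {
    abort("`lengths` must contain at least one fragment length")
  }
  if (bandwidth <= 0) abort("`bandwidth` must be > 0")
  d <- stats::density(
    lengths,
    bw = bandwidth, n = n_grid,
    from = max(0, min(lengths) - 4 * bandwidth),
    to = max(lengths) + 4 * bandwidth
  )
  structure(
    tibble(length = d$x, intensity = d$y),
    class = c("lane_profile", class(tibble())),
    bandwidth = bandwidth
  )
}

#' Estimate mean fragment length from a lane profile or raw lengths
#'
#' Intensity-weighted mean of a rendered lane, or the plain sample mean of
#' raw lengths. The symmetric kernel of [render_lane()] preserves the
#' mean, so the two routes agree within grid tolerance.
#'
#' @param x A `lane_profile` or a numeric vector of lengths.
#' @return Mean length in bp.
#' @export
estimate_mean_length <- function(x) {
  if (inherits(x, "lane_profile")) {
    sum(x$length * x$intensity) / sum(x$intensity)
  } else {
    x <- as.numeric(x)
    if (length(x) < 1) abort("empty input")
    mean(x)
  }
}

#' Compare terminal fragment lengths between two strains
#'
#' Two-sample t test on per-isolate mean lengths (classic pooled-variance
#' Student's test by default; Welch via `var_equal = FALSE`). The reported
#' difference is first group minus second group, in order of appearance,
#' so exchanging the groups flips its sign and leaves the p-value
#' unchanged. Significance stars: `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, `ns` otherwise.
#'
#' @param data Data frame with one row per isolate.
#' @param value Name of the numeric column of per-isolate mean lengths
#'   (default `"mean_length"`).
#' @param group Name of the grouping column (default `"strain"`); must
#'   contain exactly two groups with >= 2 isolates each.
#' @param var_equal Pooled variance (TRUE, default) or Welch (FALSE).
#' @return One-row tibble: `group1`, `group2`, `n1`, `n2`, `mean1`,
#'   `mean2`, `difference`, `statistic`, `df`, `p_value`, `stars`.
#' @examples
#' d <- data.frame(
#'   strain = rep(c("wt", "mut"), each = 3),
#'   mean_length = c(1500, 1510, 1490, 1200, 1210, 1190)
#' )
#' compare_strains(d)
#' @export
compare_strains <- function(data, value = "mean_length", group = "strain",
                            var_equal = TRUE) {
  d <- as_tibble(data)
  if (!all(c(value, group) %in% names(d))) {
    abort(sprintf("`data` must have columns `%s` and `%s`", value, group))
  }
  g <- as.character(d[[group]])
  levels <- unique(g)
  if (length(levels) != 2) abort("`group` must contain exactly two groups")
  x <- d[[value]][g == levels[1]]
  y <- d[[value]][g == levels[2]]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 isolates")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  p <- tt$p.value
  stars <- if (is.na(p)) {
    NA_character_
  } else if (p < 0.001) {
    "***"
  } else if (p < 0.01) {
    "**"
  } else if (p < 0.05) {
    "*"
  } else {
    "ns"
  }
  tibble(
    group1 = levels[1], group2 = levels[2],
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), mean2 = mean(y),
    difference = mean(x) - mean(y),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = p,
    stars = stars
  )
}

#' Per-isolate mean terminal fragment lengths
#'
#' Summarises a [simulate_telomere_lengths()] table (or any table of
#' per-telomere TG lengths with a `site_offset` column) into one terminal
#' fragment mean per strain and isolate — the unit on which
#' [compare_strains()] operates.
#'
#' @param lengths Tibble with `strain`, `isolate`, `tg_length` and
#'   `site_offset` columns.
#' @return Tibble (`strain`, `isolate`, `mean_length`).
#' @export
isolate_mean_lengths <- function(lengths) {
  d <- as_tibble(lengths)
  need <- c("strain", "isolate", "tg_length", "site_offset")
  if (!all(need %in% names(d))) {
    abort("`lengths` must have columns strain, isolate, tg_length, site_offset")
  }
  summarise(
    group_by(d, .data$strain, .data$isolate),
    mean_length = mean(
      terminal_fragment_length(.data$site_offset, .data$tg_length)
    ),
    .groups = "drop"
  )
}
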