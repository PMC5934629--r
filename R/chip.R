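#' Percent input from ChIP-qPCR Ct values
#'
#' The standard delta-Ct quantification with explicit primer efficiency:
#' `100 * input_fraction * efficiency^(ct_input - ct_chip)`. The input
#' fraction is the share of total chromatin represented by the input
#' aliquot, so a ChIP that recovers exactly the input aliquot's template
#' amount (`ct_chip == ct_input`) at `input_fraction = 0.1` reads 10%.
#' Vectorised over all arguments; `ct_chip = Inf` (no template ever
#' amplified) yields 0.
#'
#' @param ct_chip,ct_input Ct values of the ChIP and input reactions
#'   (cycles).
#' @param efficiency Fold amplification per cycle, in (1, 2\].
#' @param input_fraction Fraction of material in the input aliquot,
#'   in (0, 1\].
#' @return Percent input (numeric vector).
#' @examples
#' percent_input_qpcr(ct_chip = 23, ct_input = 20, efficiency = 2) # 12.5
#' @export
percent_input_qpcr <- function(ct_chip, ct_input, efficiency = 2,
                               input_fraction = 1) {
  if (any(efficiency <= 1)) {
    abort("`efficiency` must exceed 1 (fold amplification per cycle)")
  }
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    abort("`input_fraction` must be in (0, 1]")
  }
  100 * input_fraction * efficiency^(ct_input - ct_chip)
}

#' Percent input from ChIP dot-blot intensities
#'
#' `100 * input_fraction * chip_signal / input_signal`: the ChIP signal as
#' a percentage of the total chromatin it was drawn from, reconstructed
#' from the input aliquot's signal. Invariant to any common rescaling of
#' the two intensities. Vectorised.
#'
#' @param chip_signal,input_signal Blot intensities (arbitrary units,
#'   `input_signal` > 0).
#' @param input_fraction Fraction of material in the input aliquot.
#' @return Percent input (numeric vector).
#' @examples
#' percent_input_dotblot(0.13, 1.0) # 13
#' @export
percent_input_dotblot <- function(chip_signal, input_signal,
                                  input_fraction = 1) {
  if (any(input_signal <= 0)) abort("`input_signal` must be positive")
  if (any(chip_signal < 0)) abort("`chip_signal` must be >= 0")
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    abort("`input_fraction` must be in (0, 1]")
  }
  100 * input_fraction * chip_signal / input_signal
}

#' Telomere-length-corrected per-telomere binding
#'
#' Strains with longer telomeres carry proportionally more telomeric
#' repeat sequence per chromosome end, so equal percent-input pulldown
#' implies more bound protein per telomere. The correction divides the
#' test strain's input by the fold TG-length increase — equivalently,
#' multiplies its percent input by `tg_length_factor` — and reports the
#' result relative to the reference strain (reference = 1.0).
#'
#' @param test_percent_input Percent input of the test strain.
#' @param reference_percent_input Percent input of the reference strain
#'   (> 0).
#' @param tg_length_factor Fold increase in TG tract length of the test
#'   strain versus the reference (> 0; 1 means equal lengths).
#' @return Normalised per-telomere binding of the test strain (numeric).
#' @examples
#' per_telomere_binding(12, 13, tg_length_factor = 2.17)
#' @export
per_telomere_binding <- function(test_percent_input, reference_percent_input,
                                 tg_length_factor = 1) {
  if (any(tg_length_factor <= 0)) abort("`tg_length_factor` must be > 0")
  if (any(reference_percent_input <= 0)) {
    abort("`reference_percent_input` must be > 0")
  }
  (test_percent_input * tg_length_factor) / reference_percent_input
}

#' Probability that two loci co-fragment after sonication
#'
#' Under memoryless Poisson breakage at rate `1 / mean_fragment_length`,
#' two positions `distance` bp apart remain on one fragment exactly when no
#' break falls between them: `exp(-distance / mean_fragment_length)`.
#' Equals 1 at distance 0 and decreases strictly with distance. This is
#' the declared idealisation behind the length-dependent ChIP-qPCR bias
#' model; [simulate_sonication()] with `method = "poisson"` is its
#' generative counterpart.
#'
#' @param distance Distance in bp (>= 0); vectorised.
#' @param sonication A [sonication_model()].
#' @return Co-fragmentation probability in (0, 1\].
#' @examples
#' cofragment_probability(250, sonication_model(mean_fragment_length = 250))
#' @export
cofragment_probability <- function(distance, sonication = sonication_model()) {
  stopifnot(inherits(sonication, "sonication_model"))
  if (any(distance < 0)) abort("`distance` must be >= 0")
  exp(-distance / sonication$mean_fragment_length)
}

#' Expected ChIP-qPCR signal distortion from telomere elongation
#'
#' When the bound protein sits at the chromosome end and the qPCR amplicon
#' at a fixed subtelomeric position, elongating the telomere moves the
#' protein away from the amplicon and lowers the chance they share a
#' sonicated fragment. The predicted apparent-signal ratio is
#' `cofragment_probability(test) / cofragment_probability(ref)` — the
#' factor by which elongation alone depresses the test strain's apparent
#' ChIP-qPCR enrichment even at unchanged true occupancy.
#'
#' @param probe_distance_ref Distance (bp) between protein and amplicon in
#'   the reference strain.
#' @param probe_distance_test Same distance in the test strain.
#' @param sonication A [sonication_model()].
#' @return Expected apparent-signal ratio (test / reference).
#' @examples
#' predict_qpcr_bias(100, 700, sonication_model(mean_fragment_length = 250))
#' @export
predict_qpcr_bias <- function(probe_distance_ref, probe_distance_test,
                              sonication = sonication_model()) {
  cofragment_probability(probe_distance_test, sonication) /
    cofragment_probability(probe_distance_ref, sonication)
}

#' Simulate paired ChIP/input signals from true occupancies
#'
#' Forward model inverted by the percent-input quantifications: for each
#' site with true occupancy (fraction of its chromatin immunoprecipitated)
#' the generator emits a dot-blot intensity pair and an equivalent qPCR Ct
#' pair. At zero noise both routes recover the occupancy exactly
#' (`percent_input == 100 * occupancy`). Noise is multiplicative lognormal
#' (mean 1, coefficient of variation `noise_cv`) applied to template
#' amounts, which for the Ct route becomes additive jitter of
#' `-log(noise) / log(efficiency)` cycles.
#'
#' @param occupancy True per-site occupancies in \[0, 1\].
#' @param input_fraction Input aliquot fraction(s) in (0, 1\].
#' @param noise_cv Coefficient of variation of signal noise (>= 0).
#' @param efficiency qPCR primer efficiency in (1, 2\].
#' @param ct_input_base Noiseless input-reaction Ct (cycles).
#' @param total_signal Total chromatin blot signal (arbitrary units).
#' @param seed Integer seed.
#' @return Tibble with one row per site: `site`, `occupancy`,
#'   `chip_signal`, `input_signal`, `ct_chip`, `ct_input`, `efficiency`,
#'   `input_fraction`. Zero occupancy gives `chip_signal = 0` and
#'   `ct_chip = Inf`.
#' @export
simulate_chip_signals <- function(occupancy, input_fraction = 1,
                                  noise_cv = 0, efficiency = 2,
                                  ct_input_base = 20, total_signal = 1000,
                                  seed = 1) {
  if (any(occupancy < 0 | occupancy > 1)) {
    abort("`occupancy` values must be in [0, 1]")
  }
  if (any(noise_cv < 0)) abort("`noise_cv` must be >= 0")
  if (any(efficiency <= 1)) abort("`efficiency` must exceed 1")
  n <- length(occupancy)
  input_fraction <- rep_len(input_fraction, n)
  efficiency <- rep_len(efficiency, n)
  with_seed(seed, {
    noise <- function() {
      if (noise_cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    chip_template <- occupancy * noise()
    input_template <- input_fraction * noise()
    tibble(
      site = seq_len(n),
      occupancy = occupancy,
      chip_signal = total_signal * chip_template,
      input_signal = total_signal * input_template,
      ct_chip = ifelse(
        chip_template == 0, Inf,
        ct_input_base - log(chip_template / input_fraction) / log(efficiency)
      ),
      ct_input = ct_input_base -
        log(input_template / input_fraction) / log(efficiency),
      efficiency = efficiency,
      input_fraction = input_fraction
    )
  })
}

#' Quantify a table of ChIP measurements
#'
#' Tidy front end over the percent-input quantifications: detects the
#' measurement type from the columns present (`ct_chip`/`ct_input` for
#' qPCR, `chip_signal`/`input_signal` for dot-blot — a table carrying both
#' gets both) and appends the corresponding percent-input column(s).
#'
#' @param data Data frame of measurements; missing `efficiency` or
#'   `input_fraction` columns default to 2 and 1.
#' @return The input as a tibble with `percent_input_qpcr` and/or
#'   `percent_input_dotblot` columns added.
#' @export
quantify_chip <- function(data) {
  d <- as_tibble(data)
  eff <- if ("efficiency" %in% names(d)) d$efficiency else 2
  inf <- if ("input_fraction" %in% names(d)) d$input_fraction else 1
  has_any <- FALSE
  if (all(c("ct_chip", "ct_input") %in% names(d))) {
    d$percent_input_qpcr <- percent_input_qpcr(d$ct_chip, d$ct_input, eff, inf)
    has_any <- TRUE
  }
  if (all(c("chip_signal", "input_signal") %in% names(d))) {
    d$percent_input_dotblot <-
      percent_input_dotblot(d$chip_signal, d$input_signal, inf)
    has_any <- TRUE
  }
  if (!has_any) {
    abort(paste0(
      "`data` must carry qPCR columns (ct_chip, ct_input) and/or ",
      "dot-blot columns (chip_signal, input_signal)"
    ))
  }
  d
}
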