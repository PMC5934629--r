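#' Sample sequencing read counts from a replicating population
#'
#' Emulates what binning of uniquely mapped reads from a sequencing library
#' would yield: each bin attracts reads with probability proportional to
#' its mean copy number (1 + mean replicated fraction across cells), times
#' an optional per-bin mappability weight, times the bin width (so a
#' trailing partial bin attracts proportionally fewer reads). Counts are a
#' single multinomial draw and always sum exactly to `total_reads`.
#'
#' @param population A [simulate_population()] result.
#' @param bin_size Bin width in bp (default 1000).
#' @param total_reads Total number of reads to distribute (>= 0).
#' @param seed Integer seed.
#' @param mappability Optional numeric vector of per-bin weights in genome
#'   order (default 1 everywhere), standing in for the fraction of
#'   uniquely mappable positions in each bin.
#' @return A `bin_counts` tibble (`chrom`, `start`, `end`, `count`,
#'   `partial`) with attributes `bin_size` and `total_reads`.
#' @export
sample_read_counts <- function(population, bin_size = 1000, total_reads,
                               seed, mappability = NULL) {
  genome <- attr(population, "genome")
  n_cells <- attr(population, "n_cells")
  if (is.null(genome) || is.null(n_cells) || n_cells < 1) {
    abort("`population` must be a non-empty simulate_population() result")
  }
  if (!is.numeric(total_reads) || length(total_reads) != 1L || total_reads < 0) {
    abort("`total_reads` must be a single non-negative count")
  }
  frac <- bin_replicated_fraction(population, bin_size)
  w <- mappability %||% rep(1, nrow(frac))
  if (length(w) != nrow(frac)) {
    abort("`mappability` must have one weight per bin")
  }
  if (any(w < 0)) abort("`mappability` weights must be >= 0")
  p <- (1 + frac$fraction) * w * (frac$end - frac$start)
  if (sum(p) <= 0) abort("all bins have zero sampling weight")
  counts <- with_seed(
    seed,
    as.integer(stats::rmultinom(1, size = total_reads, prob = p / sum(p)))
  )
  out <- tibble(
    chrom = frac$chrom, start = frac$start, end = frac$end,
    count = counts, partial = frac$partial
  )
  new_bin_counts(out, bin_size = bin_size)
}

new_bin_counts <- function(tbl, bin_size) {
  structure(
    tbl,
    class = c("bin_counts", class(tibble())),
    bin_size = bin_size,
    total_reads = sum(tbl$count)
  )
}

#' Bin mapped read positions into fixed-width windows
#'
#' Counts reads per `[k * bin_size, (k + 1) * bin_size)` window (0-based,
#' half-open). The trailing partial bin of each chromosome is included and
#' flagged in the `partial` column.
#'
#' @param reads Data frame of mapped read positions with columns `chrom`
#'   and `pos` (bp, 0-based).
#' @param genome A [genome_model()] supplying chromosome lengths, or a data
#'   frame with columns `chrom` and `length`.
#' @param bin_size Bin width in bp (default 1000).
#' @return A `bin_counts` tibble as in [sample_read_counts()].
#' @examples
#' gm <- data.frame(chrom = "chrI", length = 2000)
#' bin_reads(data.frame(chrom = "chrI", pos = c(0, 999, 1000)), gm)
#' @export
bin_reads <- function(reads, genome, bin_size = 1000) {
  chroms <- if (inherits(genome, "genome_model")) {
    genome$chromosomes
  } else {
    as_tibble(genome)
  }
  if (!all(c("chrom", "length") %in% names(chroms))) {
    abort("`genome` must supply chromosome names and lengths")
  }
  reads <- as_tibble(reads)
  if (!all(c("chrom", "pos") %in% names(reads))) {
    abort("`reads` must have columns `chrom` and `pos`")
  }
  len <- chroms$length[match(reads$chrom, chroms$chrom)]
  bad <- which(is.na(len) | reads$pos < 0 | reads$pos >= len)
  if (length(bad) > 0) {
    b <- bad[1]
    abort(sprintf(
      "read %d (%s:%g) lies outside the genome",
      b, reads$chrom[b], reads$pos[b]
    ))
  }
  out <- purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
    chrom <- chroms$chrom[i]
    grid <- bin_grid(chroms$length[i], bin_size)
    pos <- reads$pos[reads$chrom == chrom]
    idx <- floor(pos / bin_size) + 1L
    counts <- tabulate(idx, nbins = nrow(grid))
    tibble(
      chrom = chrom, start = grid$start, end = grid$end,
      count = counts, partial = grid$partial
    )
  })
  new_bin_counts(out, bin_size = bin_size)
}
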