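#' Define a genome model for S-phase simulation
#'
#' A genome model couples a set of chromosomes with a table of replication
#' origins and a fork speed. Origins fire stochastically: each origin has a
#' median firing time, a firing-time spread, and a competence probability
#' (the chance that the origin is licensed and able to fire at all in a
#' given cell). Coordinates are 0-based, half-open throughout.
#'
#' A chromosome may carry no origins at all, which emulates origin-deletion
#' constructs (for example the "delta-4ARS" chromosome VI right arm, from
#' which all four subtelomeric ARS elements are removed so that the
#' terminal region can only be replicated by forks travelling in from the
#' centromere-proximal side).
#'
#' @param chromosomes Data frame with columns `chrom` (character) and
#'   `length` (bp, positive).
#' @param origins Data frame with columns `chrom`, `pos` (bp), `t_median`
#'   (minutes, median firing time), `t_spread` (minutes, standard deviation
#'   of the firing-time distribution, >= 0) and `competence` (probability in
#'   \[0, 1\]). May have zero rows.
#' @param fork_speed Replication fork speed in bp/min (> 0). Default 1500,
#'   a standard budding-yeast figure.
#'
#' @return An object of class `genome_model`: a list with tibbles
#'   `chromosomes` and `origins` plus `fork_speed`.
#' @examples
#' gm <- genome_model(
#'   chromosomes = data.frame(chrom = "chrVI", length = 270000),
#'   origins = data.frame(
#'     chrom = "chrVI", pos = 135000, t_median = 20,
#'     t_spread = 5, competence = 0.9
#'   )
#' )
#' gm
#' @export
genome_model <- function(chromosomes, origins, fork_speed = 1500) {
  chromosomes <- as_tibble(chromosomes)
  origins <- as_tibble(origins)
  need_c <- c("chrom", "length")
  if (!all(need_c %in% names(chromosomes))) {
    abort(paste0(
      "`chromosomes` must have columns: ",
      paste(need_c, collapse = ", ")
    ))
  }
  need_o <- c("chrom", "pos", "t_median", "t_spread", "competence")
  if (!all(need_o %in% names(origins))) {
    abort(paste0("`origins` must have columns: ", paste(need_o, collapse = ", ")))
  }
  if (any(chromosomes$length <= 0)) abort("chromosome lengths must be positive")
  if (anyDuplicated(chromosomes$chrom)) abort("duplicated chromosome names")
  if (!is.numeric(fork_speed) || length(fork_speed) != 1L || fork_speed <= 0) {
    abort("`fork_speed` must be a single positive number (bp/min)")
  }
  bad <- setdiff(origins$chrom, chromosomes$chrom)
  if (length(bad) > 0) {
    abort(paste0(
      "origin refers to unknown chromosome(s): ",
      paste(unique(bad), collapse = ", ")
    ))
  }
  if (nrow(origins) > 0) {
    len <- chromosomes$length[match(origins$chrom, chromosomes$chrom)]
    if (any(origins$pos < 0 | origins$pos >= len)) {
      abort("origin positions must lie within chromosome bounds [0, length)")
    }
    if (any(origins$competence < 0 | origins$competence > 1)) {
      abort("origin competence must be in [0, 1]")
    }
    if (any(origins$t_spread < 0)) abort("origin t_spread must be >= 0")
  }
  structure(
    list(
      chromosomes = chromosomes[, need_c],
      origins = origins[, need_o],
      fork_speed = fork_speed
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(
    "<genome_model> ", nrow(x$chromosomes), " chromosome(s), ",
    nrow(x$origins), " origin(s), fork speed ", x$fork_speed, " bp/min\n",
    sep = ""
  )
  invisible(x)
}

#' Delete origins from a genome model
#'
#' Convenience for building origin-deletion variants: removes every origin
#' on `chrom` whose position falls in `[from, to)`.
#'
#' @param genome A [genome_model()].
#' @param chrom Chromosome name.
#' @param from,to Region bounds in bp (0-based, half-open). Defaults cover
#'   the whole chromosome.
#' @return A new `genome_model` without the deleted origins.
#' @export
delete_origins <- function(genome, chrom, from = 0, to = Inf) {
  stopifnot(inherits(genome, "genome_model"))
  keep <- !(genome$origins$chrom == chrom &
    genome$origins$pos >= from & genome$origins$pos < to)
  genome_model(genome$chromosomes, genome$origins[keep, ], genome$fork_speed)
}
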