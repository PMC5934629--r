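#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows across row_number n
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Deterministic fan-out of one user seed into per-operation child seeds.
# Keeps every stream independent while staying reproducible from a single
# integer, and keeps results below .Machine$integer.max.
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587 + 1)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Merge possibly-overlapping half-open intervals. `start`, `end` numeric
# vectors; returns a tibble with disjoint sorted intervals where touching
# intervals ([a,b) + [b,c)) are coalesced.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble(start = numeric(0), end = numeric(0)))
  }
  keep <- end > start
  start <- start[keep]
  end <- end[keep]
  if (length(start) == 0L) {
    return(tibble(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Total length covered by a merged interval set clipped to [lo, hi).
interval_overlap <- function(start, end, lo, hi) {
  sum(pmax(0, pmin(end, hi) - pmax(start, lo)))
}

`%||%` <- rlang::`%||%`
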