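#' Write a copy-number profile as fixedStep wig text
#'
#' Serialises the profile in the fixedStep wiggle dialect used for
#' replication-timing browser tracks: one or more blocks per chromosome
#' with `step` = `span` = the bin size, 1-based start positions per the
#' wig convention (internal coordinates are 0-based and converted on the
#' way out). Masked bins are omitted, splitting the surrounding block in
#' two; trailing partial bins (narrower than the bin size) are likewise
#' omitted, since a fixedStep block cannot change span.
#'
#' @param profile A `copy_number_profile` (or any tibble with `chrom`,
#'   `start`, `end`, `value`, `masked`).
#' @param path File to write, or `NULL` to return the lines invisibly.
#' @param name Track name for the header line.
#' @param digits Decimal places written per value (default 6).
#' @return Invisibly, the character vector of wig lines.
#' @export
write_wig <- function(profile, path = NULL, name = "relative_copy_number",
                      digits = 6) {
  p <- as_tibble(profile)
  if (!all(c("chrom", "start", "end", "value", "masked") %in% names(p))) {
    abort("`profile` must have columns chrom, start, end, value, masked")
  }
  bin_size <- attr(profile, "bin_size") %||% max(p$end - p$start)
  keep <- !p$masked & !is.na(p$value) & (p$end - p$start) == bin_size
  p <- p[keep, ]
  lines <- sprintf("track type=wiggle_0 name=\"%s\"", name)
  for (chrom in unique(p$chrom)) {
    pc <- arrange(p[p$chrom == chrom, ], .data$start)
    if (nrow(pc) == 0L) next
    # contiguous runs of bins become one fixedStep block each
    block <- cumsum(c(1, diff(pc$start) != bin_size))
    for (b in unique(block)) {
      pb <- pc[block == b, ]
      lines <- c(
        lines,
        sprintf(
          "fixedStep chrom=%s start=%d step=%d span=%d",
          chrom, as.integer(pb$start[1]) + 1L,
          as.integer(bin_size), as.integer(bin_size)
        ),
        sprintf("%.*f", digits, pb$value)
      )
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a fixedStep wig file into a profile tibble
#'
#' Counterpart of [write_wig()]: parses fixedStep blocks back into 0-based
#' half-open bins.
#'
#' @param path Wig file path (or a character vector of wig lines).
#' @return Tibble (`chrom`, `start`, `end`, `value`, `masked`) with
#'   `masked = FALSE` everywhere (masked bins are absent from wig).
#' @export
read_wig <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path)
  } else {
    path
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  out <- list()
  chrom <- NULL
  start <- step <- span <- NA_real_
  vals <- numeric(0)
  flush <- function() {
    if (is.null(chrom) || length(vals) == 0L) return(NULL)
    s <- start - 1 + step * (seq_along(vals) - 1)
    tibble(
      chrom = chrom, start = s, end = s + span,
      value = vals, masked = FALSE
    )
  }
  for (ln in lines) {
    if (startsWith(ln, "fixedStep")) {
      out <- c(out, list(flush()))
      kv <- strsplit(strsplit(ln, "\\s+")[[1]][-1], "=")
      kv <- stats::setNames(
        vapply(kv, `[`, "", 2),
        vapply(kv, `[`, "", 1)
      )
      chrom <- kv[["chrom"]]
      start <- as.numeric(kv[["start"]])
      step <- as.numeric(kv[["step"]] %||% "1")
      span <- as.numeric(kv[["span"]] %||% kv[["step"]] %||% "1")
      vals <- numeric(0)
    } else {
      vals <- c(vals, as.numeric(ln))
    }
  }
  out <- c(out, list(flush()))
  res <- bind_rows(out)
  arrange(res, .data$chrom, .data$start)
}

#' Write per-bin counts as 4-column BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `count`; no header, tab-separated,
#' 0-based half-open coordinates.
#'
#' @param counts A `bin_counts` tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bin_counts <- function(counts, path) {
  tbl <- as_tibble(counts)[, c("chrom", "start", "end", "count")]
  readr::write_tsv(tbl, path, col_names = FALSE)
  invisible(path)
}

#' Read per-bin counts from 4-column BED-like TSV
#'
#' @param path Input file (chrom, start, end, count; no header).
#' @return A `bin_counts` tibble.
#' @export
read_bin_counts <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "count"),
    col_types = "ciii", progress = FALSE
  )
  tbl <- arrange(tbl, .data$chrom, .data$start)
  width <- tbl$end - tbl$start
  bin_size <- max(width)
  tbl$partial <- width < bin_size
  if (any(tbl$count < 0)) abort("negative counts in bin-count file")
  new_bin_counts(tbl, bin_size = bin_size)
}
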