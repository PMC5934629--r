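#' Read and validate a scenario configuration file
#'
#' A scenario is a flat YAML file describing one simulated experiment:
#' genome and origin table, S-phase time points, sequencing depth, flow
#' and sonication parameters, strain telomere parameters and a seed. The
#' file is validated against the documented schema before any stage runs;
#' every violation is reported with its field path.
#'
#' @param path YAML file path.
#' @return A validated scenario config (named list) of class
#'   `scenario_config`.
#' @seealso [run_scenario()]; a worked example config ships at
#'   `system.file("extdata", "delta4ars.yaml", package = "telotiming")`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  validate_scenario_config(yaml::read_yaml(path))
}

#' Validate a scenario configuration
#'
#' @param config Named list with the scenario schema (see
#'   [read_scenario_config()]).
#' @return The config, invisibly validated, classed `scenario_config`.
#' @export
validate_scenario_config <- function(config) {
  errs <- character(0)
  need <- function(ok, path_str, what) {
    if (!isTRUE(ok)) errs <<- c(errs, sprintf("%s: %s", path_str, what))
  }
  scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  need(is.list(config), "(root)", "config must be a mapping")
  need(scalar_num(config$seed), "seed", "required integer seed")
  need(is.list(config$genome), "genome", "required mapping")
  if (is.list(config$genome)) {
    g <- config$genome
    need(
      scalar_num(g$fork_speed) && g$fork_speed > 0,
      "genome.fork_speed", "required positive number (bp/min)"
    )
    need(
      is.list(g$chromosomes) && length(g$chromosomes) >= 1,
      "genome.chromosomes", "required non-empty list"
    )
    if (is.list(g$chromosomes)) {
      for (i in seq_along(g$chromosomes)) {
        ch <- g$chromosomes[[i]]
        need(
          !is.null(ch$chrom) && scalar_num(ch$length) && ch$length > 0,
          sprintf("genome.chromosomes[%d]", i),
          "needs `chrom` and positive `length`"
        )
      }
    }
    # an empty origin list is legal (full origin-deletion variant)
    if (!is.null(g$origins)) {
      for (i in seq_along(g$origins)) {
        o <- g$origins[[i]]
        for (f in c("pos", "t_median", "t_spread", "competence")) {
          need(
            scalar_num(o[[f]]),
            sprintf("genome.origins[%d].%s", i, f), "required number"
          )
        }
        need(
          !is.null(o$chrom),
          sprintf("genome.origins[%d].chrom", i), "required"
        )
      }
    }
  }
  need(
    is.numeric(config$time_points) && length(config$time_points) >= 4,
    "time_points", "required numeric vector with >= 4 time points"
  )
  need(
    scalar_num(config$n_cells) && config$n_cells >= 1,
    "n_cells", "required positive count"
  )
  need(is.list(config$sequencing), "sequencing", "required mapping")
  if (is.list(config$sequencing)) {
    s <- config$sequencing
    need(scalar_num(s$depth) && s$depth > 0, "sequencing.depth",
      "required mean reads per bin")
    need(scalar_num(s$bin_size) && s$bin_size >= 1, "sequencing.bin_size",
      "required bin size (bp)")
    need(scalar_num(s$time_point), "sequencing.time_point",
      "required late-S time point")
    if (scalar_num(s$time_point) && is.numeric(config$time_points)) {
      need(
        s$time_point %in% config$time_points,
        "sequencing.time_point", "must be one of time_points"
      )
    }
  }
  need(is.list(config$flow), "flow", "required mapping")
  if (is.list(config$flow)) {
    need(
      scalar_num(config$flow$cv) && config$flow$cv >= 0,
      "flow.cv", "required coefficient of variation >= 0"
    )
    need(
      scalar_num(config$flow$events) && config$flow$events >= 1,
      "flow.events", "required events per sample"
    )
  }
  if (!is.null(config$sonication)) {
    so <- config$sonication
    need(
      scalar_num(so$mean_fragment_length) && so$mean_fragment_length > 0,
      "sonication.mean_fragment_length", "must be > 0"
    )
    need(
      scalar_num(so$n_fragments) && so$n_fragments >= 1,
      "sonication.n_fragments", "required count"
    )
  }
  if (!is.null(config$strains)) {
    for (i in seq_along(config$strains)) {
      st <- config$strains[[i]]
      need(
        !is.null(st$strain),
        sprintf("strains[%d].strain", i), "required label"
      )
      need(
        scalar_num(st$mean_tg) && st$mean_tg > 0,
        sprintf("strains[%d].mean_tg", i), "required positive mean TG length"
      )
    }
  }
  if (length(errs) > 0) {
    abort(paste0(
      "invalid scenario config:\n",
      paste0("  - ", errs, collapse = "\n")
    ))
  }
  structure(config, class = c("scenario_config", "list"))
}

scenario_genome <- function(config) {
  chroms <- purrr::map_dfr(
    config$genome$chromosomes,
    ~ tibble(chrom = .x$chrom, length = .x$length)
  )
  origins <- if (length(config$genome$origins %||% list()) > 0) {
    purrr::map_dfr(
      config$genome$origins,
      ~ tibble(
        chrom = .x$chrom, pos = .x$pos, t_median = .x$t_median,
        t_spread = .x$t_spread, competence = .x$competence
      )
    )
  } else {
    tibble(
      chrom = character(0), pos = numeric(0), t_median = numeric(0),
      t_spread = numeric(0), competence = numeric(0)
    )
  }
  genome_model(chroms, origins, config$genome$fork_speed)
}

log_stage <- function(stage, ...) {
  message(sprintf("[telotiming] %s: %s", stage, paste0(..., collapse = "")))
}

#' Run a complete simulated scenario
#'
#' Orchestrates every analysis stage from one validated configuration:
#' simulates matched S-phase populations across the time course, generates
#' flow-cytometry events and fits the Gompertz bulk-replication curve,
#' samples replicating and non-replicating read counts, computes the
#' relative copy-number profile and region replication ranks, simulates
#' sonication fragments, telomere length distributions and (optionally)
#' ChIP signal pairs, and writes every artifact plus a checksum manifest
#' to the output directory. All randomness fans out deterministically from
#' the config seed, so a rerun with the same config is byte-identical.
#' Stage progress is logged to standard error.
#'
#' @param config A `scenario_config` (from [read_scenario_config()]) or a
#'   path to a YAML config file.
#' @param out_dir Output directory (created if needed); overrides the
#'   config's `output_dir`.
#' @return Invisibly, a list with the fitted Gompertz object, the
#'   copy-number profile, the region ranks and the manifest tibble.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_scenario_config(config)
  config <- validate_scenario_config(unclass(config))
  out_dir <- out_dir %||% config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  paths <- character(0)
  emit <- function(file) {
    p <- file.path(out_dir, file)
    paths <<- c(paths, p)
    p
  }

  genome <- scenario_genome(config)
  log_stage("genome", nrow(genome$chromosomes), " chromosome(s), ",
    nrow(genome$origins), " origin(s), seed ", seed)

  times <- sort(unique(config$time_points))
  course <- simulate_time_course(
    genome, times,
    n_cells = config$n_cells, seed = child_seed(seed, "course")
  )
  log_stage("s-phase", "simulated ", config$n_cells, " cells at ",
    length(times), " time points")

  events <- simulate_flow_time_course(
    course,
    cv = config$flow$cv, n_events = config$flow$events,
    seed = child_seed(seed, "flow")
  )
  readr::write_csv(events, emit("flow_events.csv"))
  bulk <- percent_bulk_course(events)
  readr::write_csv(bulk, emit("bulk_course.csv"))
  fit <- fit_gompertz(bulk)
  readr::write_csv(glance(fit), emit("bulk_fit.csv"))
  log_stage("bulk", sprintf(
    "Gompertz A = %.1f%%, k = %.3f /min, t0 = %.1f min",
    fit$A, fit$k, fit$t0
  ))

  sq <- config$sequencing
  n_bins <- sum(ceiling(genome$chromosomes$length / sq$bin_size))
  total_reads <- round(sq$depth * n_bins)
  rep_pop <- course[[paste0("t", sq$time_point)]]
  nonrep_pop <- course[[paste0("t", times[1])]]
  rep_counts <- sample_read_counts(
    rep_pop, sq$bin_size, total_reads,
    seed = child_seed(seed, "reads_rep")
  )
  nonrep_counts <- sample_read_counts(
    nonrep_pop, sq$bin_size, total_reads,
    seed = child_seed(seed, "reads_nonrep")
  )
  write_bin_counts(rep_counts, emit("counts_rep.tsv"))
  write_bin_counts(nonrep_counts, emit("counts_nonrep.tsv"))
  pb <- bulk$percent[bulk$time == sq$time_point]
  ratios <- raw_ratio(rep_counts, nonrep_counts,
    min_count = sq$min_count %||% 10)
  profile <- normalize_by_bulk(ratios, pb,
    label = paste0("t", sq$time_point))
  readr::write_tsv(as_tibble(profile), emit("profile.tsv"))
  write_wig(profile, emit("profile.wig"))
  ranks <- rank_replication_order(profile,
    window_size = config$rank_window %||% 10000)
  readr::write_csv(ranks, emit("region_ranks.csv"))
  log_stage("timing", sprintf(
    "%d bins at %d bp, %.0f%% bulk, latest window %s:%d-%d",
    n_bins, sq$bin_size, pb,
    ranks$chrom[nrow(ranks)], ranks$start[nrow(ranks)],
    ranks$end[nrow(ranks)]
  ))

  if (!is.null(config$sonication)) {
    so <- config$sonication
    model <- sonication_model(
      so$mean_fragment_length %||% 250,
      so$molecule_length %||% 10000,
      so$min_fragment %||% 50
    )
    frag <- simulate_sonication(model, so$n_fragments,
      seed = child_seed(seed, "sonication"))
    readr::write_csv(tibble(length = frag), emit("fragments.csv"))
    log_stage("sonication", sprintf(
      "%d fragments, mean %.0f bp, %.1f%% in 50-500 bp",
      length(frag), mean(frag), 100 * mean(frag >= 50 & frag <= 500)
    ))
  }

  if (!is.null(config$strains)) {
    params <- purrr::map_dfr(config$strains, ~ telomere_strain_params(
      .x$strain,
      mean_tg = .x$mean_tg %||% 300, sd_tg = .x$sd_tg %||% 75,
      elongation = .x$elongation %||% 0,
      site_offset = .x$site_offset %||% 0
    ))
    lens <- simulate_telomere_lengths(
      params,
      n_telomeres = config$telomeres$n_telomeres %||% 32,
      n_isolates = config$telomeres$n_isolates %||% 3,
      seed = child_seed(seed, "telomeres")
    )
    readr::write_csv(lens, emit("telomere_lengths.csv"))
    means <- isolate_mean_lengths(lens)
    readr::write_csv(means, emit("telomere_isolate_means.csv"))
    if (length(unique(means$strain)) == 2) {
      cmp <- compare_strains(means)
      readr::write_csv(cmp, emit("telomere_comparison.csv"))
      log_stage("southern", sprintf(
        "%s vs %s: difference %.0f bp, p = %.2g %s",
        cmp$group1, cmp$group2, cmp$difference, cmp$p_value, cmp$stars
      ))
    }
  }

  if (!is.null(config$chip)) {
    chip <- simulate_chip_signals(
      occupancy = config$chip$occupancies,
      input_fraction = config$chip$input_fraction %||% 1,
      noise_cv = config$chip$noise_cv %||% 0,
      seed = child_seed(seed, "chip")
    )
    readr::write_csv(quantify_chip(chip), emit("chip.csv"))
    log_stage("chip", length(config$chip$occupancies), " sites quantified")
  }

  manifest <- tibble(
    file = basename(paths),
    bytes = file.size(paths),
    md5 = unname(tools::md5sum(paths))
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  log_stage("done", nrow(manifest), " artifacts in ", out_dir)
  invisible(list(
    gompertz = fit, profile = profile, ranks = ranks, manifest = manifest
  ))
}
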