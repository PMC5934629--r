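# Shared fixtures: small genomes built in code.

# One chromosome, one deterministic origin: closed-form triangle profiles.
single_origin_genome <- function(length = 200000, pos = floor(length / 2),
                                 t_fire = 10, fork_speed = 1500) {
  genome_model(
    chromosomes = data.frame(chrom = "chrI", length = length),
    origins = data.frame(
      chrom = "chrI", pos = pos, t_median = t_fire,
      t_spread = 0, competence = 1
    ),
    fork_speed = fork_speed
  )
}

# Two-chromosome genome mirroring the bundled example scenario: chrA with
# origins throughout, chrB with no origin distal of 180 kb. When
# `distal_origins` is TRUE the four telomere-proximal chrB origins are
# present (the intact-chromosome contrast); `shift` moves every origin's
# median firing time (negative = earlier, the precocious-firing contrast).
two_chrom_genome <- function(distal_origins = FALSE, shift = 0) {
  chroms <- data.frame(
    chrom = c("chrA", "chrB"),
    length = c(316000, 270000)
  )
  ori <- data.frame(
    chrom = c(rep("chrA", 7), rep("chrB", 5)),
    pos = c(
      15000, 75000, 115000, 165000, 225000, 275000, 305000,
      20000, 60000, 100000, 140000, 180000
    ),
    t_median = c(22, 20, 26, 22, 28, 24, 30, 24, 20, 24, 22, 26),
    t_spread = 5,
    competence = 0.9
  )
  if (distal_origins) {
    ori <- rbind(ori, data.frame(
      chrom = "chrB",
      pos = c(200000, 222000, 244000, 266000),
      t_median = c(30, 32, 32, 34),
      t_spread = 5,
      competence = 0.9
    ))
  }
  ori$t_median <- pmax(ori$t_median + shift, 1)
  genome_model(chroms, ori, fork_speed = 1500)
}

# Simulate one sequencing experiment and return the normalized profile
# plus the true per-bin fractions. Depth = mean reads per 1 kb bin.
simulate_profile <- function(genome, t, seed, n_cells = 100, depth = 100,
                             bin_size = 1000) {
  pop <- simulate_population(genome, t, n_cells = n_cells, seed = seed)
  nonrep <- simulate_population(genome, 0, n_cells = n_cells, seed = seed + 1)
  truth <- bin_replicated_fraction(pop, bin_size)
  total <- round(depth * nrow(truth))
  rep_counts <- sample_read_counts(pop, bin_size, total, seed = seed + 2)
  nonrep_counts <- sample_read_counts(nonrep, bin_size, total, seed = seed + 3)
  pb <- 100 * mean(replicated_fractions(pop)$fraction)
  profile <- normalize_by_bulk(raw_ratio(rep_counts, nonrep_counts), pb)
  list(profile = profile, truth = truth, percent_bulk = pb)
}
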