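# Example scenario: an origin-deleted right chromosome arm replicates last.
#
# Two chromosomes. "chrA" carries origins along its whole length; "chrB"
# has every origin distal of 180 kb deleted, so its right-terminal region
# is only reached by a fork travelling ~90 kb from the last remaining
# origin. At the late-S sequencing time point that fork is still inside
# the terminal windows in most cells, making the right terminus the last
# region of the genome to replicate. Coordinates are 0-based bp; times in
# minutes after release from G1 arrest.
name: delta4ars
seed: 42
genome:
  fork_speed: 1500          # bp/min
  chromosomes:
    - {chrom: chrA, length: 316000}
    - {chrom: chrB, length: 270000}
  origins:
    - {chrom: chrA, pos: 15000,  t_median: 22, t_spread: 5, competence: 0.9}
    - {chrom: chrA, pos: 75000,  t_median: 20, t_spread: 5, competence: 0.9}
    - {chrom: chrA, pos: 115000, t_median: 26, t_spread: 5, competence: 0.9}
    - {chrom: chrA, pos: 165000, t_median: 22, t_spread: 5, competence: 0.9}
    - {chrom: chrA, pos: 225000, t_median: 28, t_spread: 5, competence: 0.9}
    - {chrom: chrA, pos: 275000, t_median: 24, t_spread: 5, competence: 0.9}
    - {chrom: chrA, pos: 305000, t_median: 30, t_spread: 5, competence: 0.9}
    - {chrom: chrB, pos: 20000,  t_median: 24, t_spread: 5, competence: 0.9}
    - {chrom: chrB, pos: 60000,  t_median: 20, t_spread: 5, competence: 0.9}
    - {chrom: chrB, pos: 100000, t_median: 24, t_spread: 5, competence: 0.9}
    - {chrom: chrB, pos: 140000, t_median: 22, t_spread: 5, competence: 0.9}
    - {chrom: chrB, pos: 180000, t_median: 26, t_spread: 5, competence: 0.9}
time_points: [0, 15, 25, 35, 45, 55, 65, 75]
n_cells: 100
sequencing:
  depth: 100                # mean reads per bin
  bin_size: 1000
  time_point: 75            # late S: only extremely late regions unreplicated
  min_count: 10
flow:
  cv: 0.05
  events: 5000
sonication:
  mean_fragment_length: 250
  molecule_length: 10000
  min_fragment: 50
  n_fragments: 10000
strains:
  - {strain: wt,     mean_tg: 300, sd_tg: 75, elongation: 0,   site_offset: 1234}
  - {strain: mutant, mean_tg: 300, sd_tg: 75, elongation: 600, site_offset: 1234}
telomeres:
  n_telomeres: 32
  n_isolates: 3
chip:
  occupancies: [0.13, 0.12]
  noise_cv: 0
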