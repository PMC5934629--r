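test_that("no origin has fired at t = 0", {
  gm <- two_chrom_genome()
  st <- simulate_cell_replication(gm, t = 0, seed = 1)
  expect_equal(nrow(st), 0)
})

test_that("single deterministic origin expands as a closed-form interval", {
  gm <- single_origin_genome(pos = 100000, t_fire = 10, fork_speed = 1500)
  st <- simulate_cell_replication(gm, t = 20, seed = 1)
  # 1500 bp/min x 10 min on each side of the origin
  expect_equal(st$start, 85000)
  expect_equal(st$end, 115000)

  # before firing: nothing
  expect_equal(nrow(simulate_cell_replication(gm, t = 9, seed = 1)), 0)
})

test_that("whole chromosome is replicated long after the last firing", {
  gm <- two_chrom_genome()
  # force full competence so every chromosome is guaranteed an origin
  gm$origins$competence <- 1
  t_sat <- max(gm$origins$t_median) + 6 * max(gm$origins$t_spread) +
    max(gm$chromosomes$length) / gm$fork_speed
  st <- simulate_cell_replication(gm, t = t_sat, seed = 3)
  done <- vapply(
    seq_len(nrow(gm$chromosomes)),
    function(i) {
      ch <- gm$chromosomes$chrom[i]
      sum(st$end[st$chrom == ch] - st$start[st$chrom == ch])
    },
    numeric(1)
  )
  expect_equal(done, gm$chromosomes$length)
})

test_that("replicated intervals are disjoint, sorted, merged and in bounds", {
  gm <- two_chrom_genome()
  for (seed in 1:8) {
    st <- simulate_cell_replication(gm, t = 35, seed = seed)
    for (ch in unique(st$chrom)) {
      iv <- st[st$chrom == ch, ]
      len <- gm$chromosomes$length[gm$chromosomes$chrom == ch]
      expect_true(all(iv$start < iv$end))
      expect_true(all(iv$start >= 0) && all(iv$end <= len))
      if (nrow(iv) > 1) {
        # strictly separated: merged intervals never touch
        expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
      }
    }
  }
})

test_that("replicated fraction is non-decreasing in time for a fixed draw", {
  gm <- two_chrom_genome()
  total <- sum(gm$chromosomes$length)
  for (seed in 1:5) {
    firing <- draw_firing_times(gm, seed)
    done <- vapply(seq(0, 80, by = 5), function(t) {
      iv <- telotiming:::replication_intervals(gm, firing, t)
      sum(iv$end - iv$start) / total
    }, numeric(1))
    expect_true(all(diff(done) >= 0))
  }
})

test_that("matched time-course populations progress monotonically", {
  gm <- two_chrom_genome()
  course <- simulate_time_course(gm, times = c(10, 25, 40, 60),
    n_cells = 20, seed = 9)
  mean_frac <- vapply(
    course,
    function(p) mean(replicated_fractions(p)$fraction),
    numeric(1)
  )
  expect_true(all(diff(mean_frac) >= 0))
})

test_that("genome validation rejects bad configurations", {
  chroms <- data.frame(chrom = "chrI", length = 1000)
  expect_error(
    genome_model(chroms, data.frame(
      chrom = "chrX", pos = 10, t_median = 1, t_spread = 0, competence = 1
    )),
    "unknown chromosome"
  )
  expect_error(
    genome_model(chroms, data.frame(
      chrom = "chrI", pos = 5000, t_median = 1, t_spread = 0, competence = 1
    )),
    "bounds"
  )
  expect_error(
    genome_model(chroms, data.frame(
      chrom = "chrI", pos = 10, t_median = 1, t_spread = 0, competence = 1.4
    )),
    "competence"
  )
  # an origin-free chromosome is legal
  expect_s3_class(
    genome_model(chroms, data.frame(
      chrom = character(0), pos = numeric(0), t_median = numeric(0),
      t_spread = numeric(0), competence = numeric(0)
    )),
    "genome_model"
  )
})

test_that("delete_origins removes exactly the targeted region", {
  gm <- two_chrom_genome(distal_origins = TRUE)
  del <- delete_origins(gm, "chrB", from = 185000)
  expect_equal(nrow(del$origins), nrow(gm$origins) - 4)
  expect_true(all(del$origins$pos[del$origins$chrom == "chrB"] < 185000))
  expect_equal(del$origins$pos[del$origins$chrom == "chrA"],
    gm$origins$pos[gm$origins$chrom == "chrA"])
})
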