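test_that("read counts always sum exactly to the requested total", {
  gm <- two_chrom_genome()
  pop <- simulate_population(gm, 30, n_cells = 20, seed = 4)
  for (total in c(0, 17, 5000)) {
    rc <- sample_read_counts(pop, 1000, total, seed = total + 1)
    expect_identical(sum(rc$count), as.integer(total))
  }
})

test_that("unreplicated cells give uniform counts (goodness of fit)", {
  gm <- single_origin_genome(length = 200000)
  pop <- simulate_population(gm, 0, n_cells = 10, seed = 1)
  # pool several seeds so a single unlucky multinomial cannot dominate
  pvals <- vapply(1:5, function(s) {
    rc <- sample_read_counts(pop, 1000, 2e5, seed = s)
    suppressWarnings(stats::chisq.test(rc$count)$p.value)
  }, numeric(1))
  expect_gt(median(pvals), 0.01)
})

test_that("a bin replicated in every cell attracts twice the reads", {
  # deterministic origin at the left end, observed when the fork has
  # covered exactly the first 1 kb bin: that bin is copy 2, all others 1
  gm <- single_origin_genome(length = 20000, pos = 0, t_fire = 0)
  pop <- simulate_population(gm, 1000 / 1500, n_cells = 10, seed = 2)
  frac <- bin_replicated_fraction(pop, 1000)
  expect_equal(frac$fraction, c(1, rep(0, 19)))
  counts <- Reduce(`+`, lapply(1:20, function(s) {
    sample_read_counts(pop, 1000, 2e4, seed = s)$count
  }))
  expect_equal(counts[1] / mean(counts[-1]), 2, tolerance = 0.05)
})

test_that("tiny multinomial matches brute-force outcome enumeration", {
  # 2 bins with copy ratio 2:1, 3 reads: enumerate all 3^3 assignments of
  # reads to bins to get the exact distribution of bin-1 counts
  gm <- single_origin_genome(length = 2000, pos = 0, t_fire = 0)
  # at t = 1000/1500 min the fork has covered exactly the first 1 kb bin
  pop <- simulate_population(gm, 1000 / 1500, n_cells = 5, seed = 1)
  frac <- bin_replicated_fraction(pop, 1000)
  expect_equal(frac$fraction, c(1, 0))

  p1 <- 2 / 3
  draws <- expand.grid(r1 = 1:2, r2 = 1:2, r3 = 1:2)
  probs <- apply(draws, 1, function(r) prod(ifelse(r == 1, p1, 1 - p1)))
  k1 <- apply(draws, 1, function(r) sum(r == 1))
  exact <- vapply(0:3, function(k) sum(probs[k1 == k]), numeric(1))

  counts <- vapply(1:10000, function(s) {
    sample_read_counts(pop, 1000, 3, seed = s)$count[1]
  }, integer(1))
  emp <- tabulate(counts + 1, nbins = 4) / length(counts)
  se <- sqrt(exact * (1 - exact) / length(counts))
  expect_true(all(abs(emp - exact) < 4 * se + 1e-12))
})

test_that("mappability weights scale sampling probabilities", {
  gm <- single_origin_genome(length = 10000)
  pop <- simulate_population(gm, 0, n_cells = 5, seed = 1)
  w <- c(rep(1, 5), rep(0, 5))
  rc <- sample_read_counts(pop, 1000, 1000, seed = 3, mappability = w)
  expect_true(all(rc$count[6:10] == 0))
  expect_error(
    sample_read_counts(pop, 1000, 10, seed = 1, mappability = c(1, 2)),
    "one weight per bin"
  )
})

test_that("bin_reads uses half-open bins and conserves reads", {
  gm <- data.frame(chrom = "chrI", length = 2000)
  rc <- bin_reads(data.frame(chrom = "chrI", pos = c(0, 999, 1000)), gm, 1000)
  expect_equal(rc$count, c(2L, 1L))

  empty <- bin_reads(
    data.frame(chrom = character(0), pos = numeric(0)), gm, 1000
  )
  expect_true(all(empty$count == 0))

  set.seed(11)
  pos <- data.frame(chrom = "chrI", pos = floor(runif(10000, 0, 2000)))
  expect_equal(sum(bin_reads(pos, gm, 1000)$count), 10000L)
})

test_that("bin_reads names the offending out-of-bounds record", {
  gm <- data.frame(chrom = "chrI", length = 2000)
  expect_error(
    bin_reads(data.frame(chrom = "chrI", pos = c(10, 2000)), gm, 1000),
    "read 2.*chrI:2000"
  )
  expect_error(
    bin_reads(data.frame(chrom = "chrZ", pos = 1), gm, 1000),
    "chrZ"
  )
})

test_that("trailing partial bins are included and flagged", {
  gm <- data.frame(chrom = "chrI", length = 2500)
  rc <- bin_reads(data.frame(chrom = "chrI", pos = 2400), gm, 1000)
  expect_equal(nrow(rc), 3)
  expect_equal(rc$partial, c(FALSE, FALSE, TRUE))
  expect_equal(rc$end[3] - rc$start[3], 500)
  expect_equal(rc$count[3], 1L)
})
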