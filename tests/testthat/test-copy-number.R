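make_counts <- function(counts, bin_size = 1000, chrom = "chrI") {
  n <- length(counts)
  telotiming:::new_bin_counts(
    tibble::tibble(
      chrom = chrom,
      start = bin_size * (seq_len(n) - 1),
      end = bin_size * seq_len(n),
      count = as.integer(counts),
      partial = FALSE
    ),
    bin_size = bin_size
  )
}

test_that("identical samples give unit ratios whatever the totals", {
  r <- raw_ratio(make_counts(c(50, 80, 120)), make_counts(c(50, 80, 120)))
  expect_equal(r$ratio, rep(1, 3))
  # same bin-wise profile, different depth: library-size correction exact
  r2 <- raw_ratio(make_counts(3 * c(50, 80, 120)), make_counts(c(50, 80, 120)))
  expect_equal(r2$ratio, rep(1, 3))
})

test_that("ratios follow the library-size-corrected formula", {
  r <- raw_ratio(make_counts(c(200, 100)), make_counts(c(100, 100)))
  expect_equal(r$ratio, c(4 / 3, 2 / 3))
})

test_that("low-coverage bins are masked without division errors", {
  r <- raw_ratio(make_counts(c(10, 10, 10)), make_counts(c(100, 0, 5)),
    min_count = 10)
  expect_equal(r$masked, c(FALSE, TRUE, TRUE))
  expect_true(all(is.na(r$ratio[r$masked])))
  expect_false(anyNA(r$ratio[!r$masked]))
})

test_that("mismatched bin grids are refused", {
  a <- make_counts(c(1, 2, 3))
  b <- make_counts(c(1, 2))
  expect_error(raw_ratio(a, b), "mismatched bin grids")
  c2 <- make_counts(c(1, 2, 3), chrom = "chrII")
  expect_error(raw_ratio(a, c2), "mismatched bin grids")
})

test_that("bulk normalization anchors the profile mean at 1 + f", {
  flat <- raw_ratio(make_counts(rep(100, 4)), make_counts(rep(100, 4)))
  expect_equal(normalize_by_bulk(flat, 0)$value, rep(1, 4))
  expect_equal(normalize_by_bulk(flat, 100)$value, rep(2, 4))

  # mean-1 ratios with one bin at 4/3: that bin lands at 4/3 * 1.5 = 2
  two <- raw_ratio(make_counts(c(200, 100)), make_counts(c(100, 100)))
  prof <- normalize_by_bulk(two, 50)
  expect_equal(prof$value, c(2, 1))
})

test_that("normalization invariant: coverage-weighted mean equals 1 + f", {
  set.seed(41)
  rep_c <- make_counts(rpois(200, 150))
  non_c <- make_counts(rpois(200, 100))
  ratios <- raw_ratio(rep_c, non_c)
  for (pb in c(0, 33.3, 50, 100)) {
    prof <- normalize_by_bulk(ratios, pb)
    ok <- !prof$masked
    wm <- stats::weighted.mean(prof$value[ok], ratios$weight[ok])
    expect_lt(abs(wm - (1 + pb / 100)), 1e-9)
  }
  expect_error(normalize_by_bulk(ratios, 120), "percent_bulk")
})

test_that("profiles are invariant to rescaling both samples' counts", {
  set.seed(42)
  rep_c <- rpois(100, 200)
  non_c <- rpois(100, 150)
  p1 <- normalize_by_bulk(
    raw_ratio(make_counts(rep_c), make_counts(non_c)), 60
  )
  p2 <- normalize_by_bulk(
    raw_ratio(make_counts(5 * rep_c), make_counts(5 * non_c)), 60
  )
  expect_equal(p1$value, p2$value, tolerance = 1e-12)
})

test_that("fully masked input is an error", {
  r <- raw_ratio(make_counts(c(5, 5)), make_counts(c(1, 2)), min_count = 10)
  expect_error(normalize_by_bulk(r, 50), "masked")
})

test_that("simulated profiles stay within physical bounds at high coverage", {
  gm <- two_chrom_genome()
  sim <- simulate_profile(gm, 35, seed = 51, n_cells = 100, depth = 1000)
  v <- sim$profile$value[!sim$profile$masked]
  expect_gte(mean(v >= 0.8 & v <= 2.2), 0.99)
})

test_that("replication ranks put a uniform profile in a single tie", {
  flat <- normalize_by_bulk(
    raw_ratio(make_counts(rep(100, 30)), make_counts(rep(100, 30))), 50
  )
  rk <- rank_replication_order(flat, window_size = 10000)
  expect_true(all(rk$rank == 1))
  expect_true(all(rk$tied))
})

test_that("the window holding a unique minimum ranks last", {
  vals <- rep(100, 30)
  vals[25] <- 40 # bin 25 sits in window [20000, 30000)
  prof <- normalize_by_bulk(
    raw_ratio(make_counts(vals), make_counts(rep(100, 30))), 50
  )
  rk <- rank_replication_order(prof, window_size = 10000)
  expect_equal(rk$start[which.max(rk$rank)], 20000)
  expect_false(rk$tied[which.max(rk$rank)])
})

test_that("origin-deleted terminal region ranks last in a simulated profile", {
  gm <- two_chrom_genome() # no chrB origin distal of 180 kb
  sim <- simulate_profile(gm, 75, seed = 61, n_cells = 100, depth = 100)
  rk <- rank_replication_order(sim$profile, window_size = 10000)
  last <- rk[which.max(rk$rank), ]
  expect_equal(last$chrom, "chrB")
  expect_equal(last$start, 260000)
})
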