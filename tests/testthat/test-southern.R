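test_that("terminal fragment length is offset plus TG tract", {
  expect_equal(terminal_fragment_length(1234, 300), 1534)
  expect_equal(terminal_fragment_length(1210, 0), 1210)
  expect_equal(terminal_fragment_length(0, 412), 412)
  expect_equal(
    terminal_fragment_length(c(1234, 1210), c(300, 650)),
    c(1534, 1860)
  )
  expect_error(terminal_fragment_length(-1, 10), "site_offset")
  expect_error(terminal_fragment_length(10, -1), "tg_length")
})

test_that("a single fragment renders as a unimodal peak at its length", {
  lane <- render_lane(1534, bandwidth = 25)
  expect_lt(abs(lane$length[which.max(lane$intensity)] - 1534),
    diff(lane$length[1:2]) + 1e-9)
  # density integrates to ~1 over the grid
  expect_equal(
    sum(lane$intensity) * diff(lane$length[1:2]), 1,
    tolerance = 0.01
  )
})

test_that("two distant lengths give a bimodal lane", {
  lane <- render_lane(c(rep(1000, 50), rep(2000, 50)), bandwidth = 25)
  y <- lane$intensity
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  tall <- peaks[y[peaks] > 0.25 * max(y)]
  expect_length(tall, 2)
  expect_equal(sort(lane$length[tall]), c(1000, 2000), tolerance = 0.01)
})

test_that("the kernel preserves the sample mean", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(200, mean = runif(1, 800, 2000), sd = runif(1, 20, 150))
    lane <- render_lane(x, bandwidth = 30)
    expect_equal(estimate_mean_length(lane), mean(x), tolerance = 1e-3)
  }
  expect_equal(estimate_mean_length(1534), 1534)
  expect_equal(estimate_mean_length(c(10, 20, 30)), 20)
})

test_that("telomere length draws honour mean, offset and truncation", {
  p0 <- telomere_strain_params("wt", mean_tg = 300, sd_tg = 0)
  fixed <- simulate_telomere_lengths(p0, n_telomeres = 8, n_isolates = 2,
    seed = 1)
  expect_true(all(fixed$tg_length == 300))

  # large-sample mean difference recovers the elongation offset
  p <- telomere_strain_params(c("wt", "mut"), mean_tg = 300, sd_tg = 75,
    elongation = c(0, 600))
  d <- simulate_telomere_lengths(p, n_telomeres = 2000, n_isolates = 1,
    seed = 2)
  diff_hat <- mean(d$tg_length[d$strain == "mut"]) -
    mean(d$tg_length[d$strain == "wt"])
  se <- 75 * sqrt(2 / 2000)
  expect_lt(abs(diff_hat - 600), 3 * se)

  # truncation: a distribution pushed against zero never goes negative
  pneg <- telomere_strain_params("short", mean_tg = 40, sd_tg = 80)
  short <- simulate_telomere_lengths(pneg, n_telomeres = 500, n_isolates = 1,
    seed = 3)
  expect_true(all(short$tg_length >= 0))
})

test_that("strain comparison reproduces the closed-form t statistic", {
  d <- tibble::tibble(
    strain = rep(c("wt", "mut"), each = 3),
    mean_length = c(1500, 1510, 1490, 1200, 1210, 1190)
  )
  cmp <- compare_strains(d)
  expect_equal(cmp$difference, 300)
  # pooled t from the definition: sd 10 in each group of 3
  expect_equal(cmp$statistic, 300 / (10 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$stars, "***")
})

test_that("identical groups give zero difference and zero t", {
  d <- tibble::tibble(
    strain = rep(c("a", "b"), each = 3),
    mean_length = rep(c(1500, 1520, 1480), 2)
  )
  cmp <- compare_strains(d)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$stars, "ns")
})

test_that("comparison is antisymmetric in group order", {
  d <- tibble::tibble(
    strain = rep(c("wt", "mut"), each = 4),
    mean_length = c(1500, 1480, 1530, 1490, 1710, 1650, 1700, 1720)
  )
  ab <- compare_strains(d)
  ba <- compare_strains(d[rev(seq_len(nrow(d))), ])
  expect_equal(ba$difference, -ab$difference)
  expect_equal(ba$statistic, -ab$statistic)
  expect_equal(ba$p_value, ab$p_value)
})

test_that("t statistic matches a brute-force implementation on random data", {
  brute_t <- function(x, y) {
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  set.seed(17)
  for (i in 1:200) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    x <- rnorm(nx, 1500, 50)
    y <- rnorm(ny, 1500 + runif(1, -400, 400), 50)
    d <- tibble::tibble(
      strain = rep(c("x", "y"), c(nx, ny)),
      mean_length = c(x, y)
    )
    expect_equal(compare_strains(d)$statistic, brute_t(x, y),
      tolerance = 1e-12)
  }
})

test_that("undersized groups are rejected", {
  d <- tibble::tibble(strain = c("a", "a", "b"), mean_length = c(1, 2, 3))
  expect_error(compare_strains(d), "at least 2")
  d3 <- tibble::tibble(strain = c("a", "a", "b", "b", "c", "c"),
    mean_length = 1:6)
  expect_error(compare_strains(d3), "exactly two")
})

test_that("a simulated 600 bp elongation is recovered from lanes", {
  p <- telomere_strain_params(c("wt", "mut"), mean_tg = 300, sd_tg = 75,
    elongation = c(0, 600), site_offset = 1234)
  lens <- simulate_telomere_lengths(p, n_telomeres = 32, n_isolates = 3,
    seed = 23)
  means <- isolate_mean_lengths(lens)
  cmp <- compare_strains(means)
  # summarising orders groups alphabetically, so "mut" is group1
  expect_equal(cmp$group1, "mut")
  expect_lt(abs(cmp$difference - 600), 50)
  expect_lt(cmp$p_value, 0.001)

  # same estimate through the rendered-lane route
  wt_lane <- render_lane(terminal_fragment_length(
    1234, lens$tg_length[lens$strain == "wt"]
  ))
  mut_lane <- render_lane(terminal_fragment_length(
    1234, lens$tg_length[lens$strain == "mut"]
  ))
  expect_lt(
    abs(estimate_mean_length(mut_lane) - estimate_mean_length(wt_lane) - 600),
    50
  )
})
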