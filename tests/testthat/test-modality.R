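# Dip statistic, null calibration and the modality screen.

test_that("dip matches hand-derived exact values", {
  expect_equal(dipStatistic(c(0, 0, 0, 1, 1, 1)), 0.25, tolerance = 1e-10)
  expect_equal(dipStatistic(c(0, 0, 0, 1)), 0.125, tolerance = 1e-10)
  expect_equal(dipStatistic(c(0, 1, 2, 3)), 0.125, tolerance = 1e-10)
  expect_equal(dipStatistic(c(0, 1)), 0.25, tolerance = 1e-10)
  expect_identical(dipStatistic(rep(3.2, 10)), 0)
  expect_error(dipStatistic(numeric()), "empty")
  expect_error(dipStatistic(c(1, NA)), "non-finite")
  expect_error(dipStatistic(c(1, Inf)), "non-finite")
})

test_that("dip equals the LP brute-force oracle on tiny samples", {
  # frozen oracle values, computed once with dipLP (helper-dip-oracle.R)
  frozen <- list(
    list(x = c(0, 0, 1, 2), d = 0.125),
    list(x = c(0, 0.1, 0.5, 0.9, 1), d = 1 / 6),
    list(x = c(0, 0, 1, 1, 2, 2), d = 1 / 6),
    list(x = c(0.1, 0.2, 0.25, 0.7, 0.8), d = 0.163636363636364))
  for (cs in frozen)
    expect_equal(dipStatistic(cs$x), cs$d, tolerance = 1e-9)
  set.seed(421)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    x <- switch(sample(3, 1),
                round(runif(n), sample(0:2, 1)),
                rbeta(n, 0.3, 0.3),
                sample(0:3, n, replace = TRUE))
    expect_equal(dipStatistic(x), dipLP(x), tolerance = 1e-9)
  }
})

test_that("dip is affine invariant and respects its bounds", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rbeta(50, 0.4, 0.4)
    d <- dipStatistic(x)
    expect_equal(d, dipStatistic(2.5 * x - 3), tolerance = 1e-10)
    expect_lte(d, 0.25)
    expect_gte(d, 1 / (2 * length(x)) - 1e-12)
  }
})

test_that("pure-R reference implementation agrees with the solver", {
  set.seed(11)
  for (rep in 1:15) {
    x <- c(rnorm(sample(10:40, 1)), rnorm(sample(5:20, 1), 4))
    expect_equal(dipStatistic(x), xewas:::dipStatisticR(x),
                 tolerance = 1e-9)
  }
})

test_that("null tables are reproducible, bounded, and sized correctly", {
  t1 <- buildNullTable(50, nSim = 1000, seed = 9)
  t2 <- buildNullTable(50, nSim = 1000, seed = 9)
  expect_identical(t1@dips, t2@dips)
  expect_length(t1@dips, 1000)
  expect_false(is.unsorted(t1@dips))
  expect_gte(min(t1@dips), 1 / (2 * 50) - 1e-12)
  expect_lte(max(t1@dips), 0.25)
  expect_error(buildNullTable(50, nSim = 10), "at least 1000")
  expect_error(buildNullTable(2, nSim = 1000), "n >= 4")
})

test_that("null-table median matches the independent implementation", {
  tab <- buildNullTable(50, nSim = 2000, seed = 13)
  set.seed(99)
  other <- replicate(300, xewas:::dipStatisticR(runif(50)))
  # medians agree within Monte-Carlo error of the smaller replicate set
  se <- 1.25 * sd(other) / sqrt(length(other))  # approx SE of a median
  expect_lt(abs(median(tab@dips) - median(other)), 4 * se)
})

test_that("empirical p-values behave as rank statistics with a floor", {
  tab <- buildNullTable(60, nSim = 1000, seed = 1)
  p0 <- dipPvalue(0, tab)
  expect_equal(p0$empirical_p, 1)
  expect_false(p0$p_is_bound)
  pBig <- dipPvalue(0.26, tab)
  expect_true(pBig$p_is_bound)
  expect_equal(pBig$empirical_p, 1 / 1001)
  med <- median(tab@dips)
  pm <- dipPvalue(med, tab)
  expect_equal(pm$empirical_p, (1 + sum(tab@dips >= med)) / 1001)
  expect_gt(pm$empirical_p, 0.4); expect_lt(pm$empirical_p, 0.6)
})

test_that("modality screen separates multimodal from unimodal sites", {
  set.seed(33)
  n <- 80
  b <- rbind(
    matrix(rbeta(20 * n, 8, 80), 20),            # unimodal low
    matrix(0.55 * (runif(6 * n) < 0.5) + rbeta(6 * n, 8, 80), 6))
  rownames(b) <- c(sprintf("uni%02d", 1:20), sprintf("bi%02d", 1:6))
  colnames(b) <- sprintf("S%03d", 1:n)
  scr <- modalityScreen(b, nSim = 2000, seed = 4)
  expect_true(all(scr$unimodal_call[1:20]))
  expect_true(all(!scr$unimodal_call[21:26]))
  expect_equal(scr$n, rep(n, 26))
  # alpha = 0: nothing can be called multimodal
  scr0 <- suppressWarnings(
    modalityScreen(b, alpha = 0, nSim = 2000, seed = 4,
                   nullTables = attr(scr, "nullTables")))
  expect_true(all(scr0$unimodal_call))
})

test_that("a third separated mode keeps the dip far above null levels", {
  set.seed(8)
  x2 <- c(rnorm(50, 0, 0.2), rnorm(50, 5, 0.2))
  x3 <- c(x2, rnorm(50, 10, 0.2))
  tab <- buildNullTable(150, nSim = 1000, seed = 2)
  expect_gt(dipStatistic(x3), max(tab@dips))
  expect_true(dipPvalue(dipStatistic(x3), tab)$p_is_bound)
})

test_that("null tables round-trip through the disk cache", {
  dir <- tempfile()
  b <- matrix(runif(5 * 30), 5, 30,
              dimnames = list(paste0("cg", 1:5), paste0("S", 1:30)))
  s1 <- modalityScreen(b, nSim = 1000, seed = 2, cacheDir = dir)
  expect_true(length(list.files(dir, pattern = "^dipnull_")) == 1)
  s2 <- modalityScreen(b, nSim = 1000, seed = 2, cacheDir = dir)
  expect_identical(s1$empirical_p, s2$empirical_p)
  tab <- attr(s1, "nullTables")[["30"]]
  cached <- xewas:::.readNullTable(list.files(dir, full.names = TRUE)[1])
  expect_identical(tab@dips, cached@dips)
  expect_identical(tab@n, cached@n)
})
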