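# ACE decomposition and the discordant-MZ paired design.

test_that("falconer closed form matches hand arithmetic", {
  # exact closed form on given twin correlations
  expect_equal(xewas:::.falconer(0.8, 0.4), c(0.8, 0, 0.2))
  expect_equal(xewas:::.falconer(0.6, 0.5), c(0.2, 0.4, 0.4))
  expect_equal(xewas:::.falconer(0, 0), c(0, 0, 1))
  # negative raw components truncate to the simplex
  w <- xewas:::.falconer(0.2, 0.4)
  expect_true(all(w >= 0)); expect_equal(sum(w), 1)
  # sampling version approaches the truth at large n
  set.seed(31)
  got <- aceDecompose(rpairs(20000, 0.8), rpairs(20000, 0.4), "falconer")
  expect_lt(abs(got$a2 - 0.8), 0.06)
  expect_lt(abs(got$c2 - 0.0), 0.06)
  expect_lt(abs(got$e2 - 0.2), 0.03)
  # independent pairs: everything is unique environment (truncation keeps
  # the familial components small, not exactly zero, at finite n)
  ind <- aceDecompose(rpairs(5000, 0), rpairs(5000, 0), "falconer")
  expect_lt(ind$a2, 0.1); expect_lt(ind$c2, 0.1); expect_gt(ind$e2, 0.9)
})

test_that("ML fit recovers a shared-environment truth and is invariant", {
  set.seed(32)
  mz <- rpairs(500, 0.4); dz <- rpairs(500, 0.4)   # a2=0, c2=0.4, e2=0.6
  ml <- aceDecompose(mz, dz, "ml")
  fal <- aceDecompose(mz, dz, "falconer")
  expect_equal(ml$a2 + ml$c2 + ml$e2, 1, tolerance = 1e-6)
  expect_lt(abs(ml$c2 - 0.4), 0.1)
  expect_lt(abs(ml$e2 - 0.6), 0.1)
  expect_lt(abs(ml$a2 - fal$a2), 0.06)   # methods agree on interior truth
  # invariance: member order within pairs and affine trait rescaling
  ml2 <- aceDecompose(mz[, 2:1], dz[, 2:1], "ml")
  ml3 <- aceDecompose(10 + 3 * mz, 10 + 3 * dz, "ml")
  expect_equal(ml$a2, ml2$a2, tolerance = 1e-4)
  expect_equal(ml$c2, ml3$c2, tolerance = 1e-4)
})

test_that("pure-E twins yield near-zero familial components", {
  set.seed(33)
  reps <- replicate(20, {
    ml <- aceDecompose(rpairs(200, 0), rpairs(200, 0), "ml")
    c(ml$a2, ml$c2)
  })
  expect_lt(mean(reps[1, ]), 0.05)
  expect_lt(mean(reps[2, ]), 0.05)
})

test_that("degenerate and undersized pair inputs raise errors", {
  expect_error(aceDecompose(rpairs(3, 0.5), rpairs(3, 0.5), "ml"),
               "at least 5")
  expect_error(aceDecompose(matrix(1, 10, 2), matrix(1, 10, 2), "ml"),
               "zero variance")
})

test_that("paired t-test matches the textbook formula", {
  d <- c(0.05, 0.06, 0.04)
  got <- discordantMzTest(c(0.55, 0.56, 0.54), c(0.50, 0.50, 0.50))
  tExp <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(got$mean_diff, 0.05)
  expect_equal(got$t_stat, tExp, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(-abs(tExp), 2), tolerance = 1e-10)
  # zero-variance differences are degenerate, not significant
  deg <- discordantMzTest(c(0.5, 0.6), c(0.45, 0.55))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(discordantMzTest(0.5, 0.4), "at least 2")
})

test_that("discordant pairs are extracted from the sheet correctly", {
  sheet <- data.frame(
    sample_id = paste0("S", 1:6), sex = "male", age = 50,
    smoking_status = c("current", "never", "never", "never", "current",
                       "current"),
    pair_id = rep(c("P1", "P2", "P3"), each = 2),
    zygosity = c("MZ", "MZ", "MZ", "MZ", "DZ", "DZ"))
  v <- c(0.6, 0.5, 0.4, 0.45, 0.7, 0.8)
  pr <- discordantMzPairs(v, sheet)
  # P1 discordant MZ; P2 concordant never; P3 discordant but DZ
  expect_equal(length(pr$exposed), 1)
  expect_equal(unname(pr$exposed), 0.6)
  expect_equal(unname(pr$unexposed), 0.5)
})
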