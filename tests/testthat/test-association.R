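# Site-wise association modelling, FDR and scan diagnostics.

test_that("OLS path equals the closed-form normal equations", {
  set.seed(41)
  sheet <- makeSheet(40)
  y <- runif(40, 0.2, 0.8)
  spec <- modelSpec(covariates = c("age", "bmi"), stratum = NULL)
  got <- fitSite(y, sheet, spec)
  X <- cbind(1, as.numeric(sheet$smoking_status == "current"),
             sheet$age, sheet$bmi)
  cf <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% cf
  s2 <- sum(res^2) / (40 - 4)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(got$estimate, cf[2], tolerance = 1e-8)
  expect_equal(got$se, se, tolerance = 1e-8)
  expect_equal(got$p, 2 * pt(-abs(cf[2] / se), 36), tolerance = 1e-8)
})

test_that("degenerate designs are reported, not fitted", {
  sheet <- makeSheet(30)
  sheet$smoking_status <- "never"
  got <- fitSite(runif(30), sheet, modelSpec(stratum = NULL))
  expect_equal(got$note, "constant_exposure")
  got2 <- fitSite(runif(5), makeSheet(5), modelSpec(stratum = NULL))
  expect_equal(got2$note, "too_few_complete_cases")
})

test_that("mixed model recovers an injected effect with twin/batch terms", {
  specs <- sitePanel(causalEffects = 0.058, nNull = 0)
  sim <- simulateCohort(specs, cohortDesign(nMale = 139), seed = 14)
  spec <- modelSpec(randomTerms = c("batch", "pair"))
  got <- fitSite(betaValues(sim$mset)[1, ], sim$sheet, spec)
  expect_lt(abs(got$estimate - 0.058), 2 * got$se)
  expect_lt(got$p, 1e-4)
})

test_that("vectorised scan equals the per-site fit and ranks scales alike", {
  specs <- sitePanel(nNull = 30, causalEffects = c(0.058, -0.02))
  sim <- simulateCohort(specs, cohortDesign(nMale = 120, twinFraction = 0),
                        seed = 15)
  spec <- modelSpec(stratum = NULL)
  tb <- ewas(sim$mset, sim$sheet, spec)
  one <- fitSite(betaValues(sim$mset)[5, ], sim$sheet, spec)
  expect_equal(tb$estimate[5], one$estimate, tolerance = 1e-10)
  expect_equal(tb$p[5], one$p, tolerance = 1e-10)
  # beta- and M-scale analyses agree on significance
  tbM <- ewas(sim$mset, sim$sheet, modelSpec(outcomeScale = "M",
                                             stratum = NULL))
  expect_gt(cor(rank(tb$p), rank(tbM$p), method = "spearman"), 0.9)
  expect_identical(tb$probe_id[!is.na(tb$q) & tb$q < 0.05],
                   tbM$probe_id[!is.na(tbM$q) & tbM$q < 0.05])
})

test_that("conditional adjustment attenuates a status-driven pack-years signal", {
  set.seed(16)
  sheet <- makeSheet(300, pCurrent = 0.35, seed = 16)
  cur <- sheet$smoking_status == "current"
  y <- 0.4 + 0.05 * cur + rnorm(300, 0, 0.03)   # current status drives y
  py <- modelSpec(exposure = "pack_years", covariates = "age",
                  stratum = NULL)
  pyAdj <- modelSpec(exposure = "pack_years", covariates = "age",
                     stratum = NULL, extraCovariates = "smoking_current")
  b1 <- fitSite(y, sheet, py)
  b2 <- fitSite(y, sheet, pyAdj)
  expect_lt(abs(b2$estimate), abs(b1$estimate))
})

test_that("BH q-values match the step-up hand computation", {
  expect_equal(bhFdr(0.02), 0.02)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(17)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bhFdr(p)[perm], bhFdr(p[perm]))   # order invariance
  expect_true(all(bhFdr(p) >= p - 1e-12))
})

test_that("genomic lambda is calibrated under the null and inflates", {
  expect_equal(genomicLambda(rep(0.5, 11)), 1)
  set.seed(18)
  p <- runif(1e5)
  expect_equal(genomicLambda(p), 1, tolerance = 0.02)
  expect_gt(genomicLambda(p^2), 1)
})

test_that("QQ/Manhattan tables carry definitional quantiles and thresholds", {
  specs <- sitePanel(nNull = 20, causalEffects = 0.058)
  sim <- simulateCohort(specs, cohortDesign(nMale = 120, twinFraction = 0),
                        seed = 19)
  tb <- ewas(sim$mset, sim$sheet, modelSpec(stratum = NULL))
  qm <- qqManhattanData(tb, sim$annotation)
  m <- nrow(tb)
  expect_equal(qm$qq$expected, -log10((seq_len(m) - 0.5) / m))
  expect_false(is.unsorted(rev(qm$qq$observed)))   # decreasing in rank
  sig <- !is.na(tb$q) & tb$q < 0.05      # manhattan rows share tb's order
  expect_true(any(sig))
  expect_true(all(qm$manhattan$neglog10_p[sig] >= qm$fdr_line))
})

test_that("type-I error is calibrated over null sites", {
  # 1000 independent null sites at n = 150, vectorised OLS
  sheet <- makeSheet(150, pCurrent = 0.33, seed = 20)
  set.seed(20)
  B <- matrix(rbeta(1000 * 150, 40 * 0.45, 40 * 0.55), 1000, 150,
              dimnames = list(sprintf("cg%04d", 1:1000),
                              sheet$sample_id))
  tb <- ewas(B, sheet, modelSpec(covariates = "age", stratum = NULL))
  rate <- mean(tb$p < 0.05)
  expect_gt(rate, 0.035); expect_lt(rate, 0.065)
})
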