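# The synthetic X-methylome generator.

test_that("site specs validate their parameters", {
  expect_error(siteSpec("cg1", ace_weights = c(0.5, 0.5, 0.5)), "summing")
  expect_error(siteSpec("cg1", base_mean_male = 1.2), "strictly")
  expect_error(siteSpec("cg1", dispersion = 0), "positive")
})

test_that("ACE structure shows in within-pair correlations", {
  set.seed(21)
  n <- 500
  sheet <- data.frame(
    sample_id = sprintf("S%04d", 1:(4 * n)), sex = "male", age = 55,
    smoking_status = "never",
    pair_id = rep(sprintf("P%04d", 1:(2 * n)), each = 2),
    zygosity = rep(c("MZ", "DZ"), each = 2 * n))
  spec <- siteSpec("cg1", "male-unmethylated", base_mean_male = 0.4,
                   dispersion = 5000, latent_sd = 0.5,
                   ace_weights = c(1, 0, 0))
  v <- simulateSiteBetas(spec, sheet, seed = 2)
  pt <- pairTable(v, sheet)
  rMz <- cor(pt$mz[, 1], pt$mz[, 2])
  rDz <- cor(pt$dz[, 1], pt$dz[, 2])
  expect_gt(rMz, 0.85)          # identical up to beta noise
  expect_gt(rMz, rDz + 0.2)     # MZ resemblance exceeds DZ
  expect_gt(rDz, 0.2)           # DZ share half the genetic liability
})

test_that("null sites show no smoking contrast; injected effects do", {
  sheet <- makeSheet(800, pCurrent = 0.4, seed = 3)
  cur <- sheet$smoking_status == "current"
  null <- simulateSiteBetas(siteSpec("cg0", base_mean_male = 0.4), sheet,
                            seed = 4)
  expect_lt(abs(mean(null[cur]) - mean(null[!cur])), 0.01)
  eff <- simulateSiteBetas(
    siteSpec("cg1", base_mean_male = 0.45, smoking_effect_beta = 0.058),
    sheet, seed = 5)
  expect_lt(abs(mean(eff[cur]) - mean(eff[!cur]) - 0.058), 0.012)
})

test_that("cohorts honour the design marginals and are seed-deterministic", {
  specs <- sitePanel(nNull = 10)
  des <- cohortDesign(nMale = 139, currentSmokerFraction = 0.34)
  sim1 <- simulateCohort(specs, des, seed = 7)
  sim2 <- simulateCohort(specs, des, seed = 7)
  expect_identical(betaValues(sim1$mset), betaValues(sim2$mset))
  expect_identical(sim1$sheet, sim2$sheet)
  frac <- mean(sim1$sheet$smoking_status == "current")
  se <- sqrt(0.34 * 0.66 / 139)
  expect_lt(abs(frac - 0.34), 3 * se)
  expect_true(all(range(betaValues(sim1$mset)) > 0))
  # no twins requested -> empty pair column
  sim0 <- simulateCohort(specs, cohortDesign(nMale = 30, twinFraction = 0),
                         seed = 8)
  expect_true(all(is.na(sim0$sheet$pair_id)))
})

test_that("cell reference separates markers and closes with deconvolution", {
  R <- simulateCellReference(6, 40, seed = 9)
  expect_identical(colnames(R),
                   c("granulocyte", "monocyte", "NK", "B", "CD4T", "CD8T"))
  sep <- apply(R, 1, function(r) max(r) - min(r))
  expect_true(all(sep >= 0.3))
  R2 <- simulateCellReference(2, 1, seed = 10)
  expect_identical(dim(R2), c(1L, 2L))
  expect_gte(abs(R2[1, 1] - R2[1, 2]), 0.3)
  # closure: a pure reference column deconvolves to proportion 1
  cp <- estimateCellProportions(cbind(s1 = R[, 2]), R)
  expect_equal(as.numeric(cp[1, -1]),
               as.numeric(1:6 == 2), tolerance = 1e-6)
})

test_that("XCI sites are bimodal pooled but unimodal within males", {
  specs <- sitePanel(nNull = 6, nXci = 6)
  sim <- simulateCohort(specs, cohortDesign(nMale = 100, nFemale = 100,
                                            twinFraction = 0), seed = 12)
  male <- sim$sheet$sex == "male"
  b <- betaValues(sim$mset)
  xci <- grep("XCI", rownames(b))
  dipsPooled <- apply(b[xci, ], 1, dipStatistic)
  dipsMale <- apply(b[xci, male], 1, dipStatistic)
  expect_gt(min(dipsPooled), max(dipsMale))
})
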