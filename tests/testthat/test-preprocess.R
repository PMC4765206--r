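# Transforms, QC filters and cell-type deconvolution.

test_that("beta from intensities follows the offset formula", {
  expect_equal(betaFromIntensities(0, 500, 100), 0)
  expect_equal(betaFromIntensities(300, 300, 0), 0.5)
  expect_equal(betaFromIntensities(900, 0, 100), 0.9)
  expect_true(is.na(betaFromIntensities(0, 0, 0)))
  expect_error(betaFromIntensities(1, 1, -1), "nonnegative")
  set.seed(1)
  b <- betaFromIntensities(runif(50, 0, 5000), runif(50, 0, 5000))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("M transform is the clipped logit2 with exact inverse", {
  expect_equal(mFromBeta(0.5), 0)
  expect_equal(mFromBeta(0.8), 2)
  expect_equal(mFromBeta(1), log2((1 - 1e-6) / 1e-6))
  expect_equal(mFromBeta(0.2), -mFromBeta(0.8))
  set.seed(2)
  b <- runif(100, 1e-6, 1 - 1e-6)
  expect_equal(betaFromM(mFromBeta(b)), b, tolerance = 1e-10)
  expect_true(all(diff(mFromBeta(sort(b))) >= 0))
})

test_that("sample QC masks failed detections and drops bad samples", {
  mset <- makeMset(10, 5, detection = TRUE)
  dp <- detectionP(mset)
  dp[, 2] <- 0.5          # sample 2 fails everywhere
  dp[1, 3] <- 0.5         # sample 3 fails one probe (10% > 5%)
  mset2 <- MethylationSet(betaValues(mset), sampleSheet(mset),
                          probeAnnotation(mset), detectionP = dp)
  res <- qcFilterSamples(mset2, detectionPCutoff = 0.001,
                         maxMissingRate = 0.05)
  expect_setequal(res$report$excluded_samples$sample_id, c("S002", "S003"))
  expect_equal(ncol(res$mset), 3)
  # looser missing-rate: the single-failure sample survives
  res2 <- qcFilterSamples(mset2, 0.001, maxMissingRate = 0.10)
  expect_false("S003" %in% res2$report$excluded_samples$sample_id)
})

test_that("probe QC applies precedence missing > SNP > mapping", {
  mset <- makeMset(6, 5)
  b <- betaValues(mset)
  b[1, ] <- NA                       # all-missing probe
  b[2, 1:3] <- NA                    # 60% missing AND snp overlap
  ann <- probeAnnotation(mset)
  ann$snp_overlap[c(2, 3)] <- TRUE
  ann$unique_mapping[c(3, 4)] <- FALSE
  mset2 <- MethylationSet(b, sampleSheet(mset), ann)
  res <- qcFilterProbes(mset2, maxMissingRate = 0.05)
  rep_ <- res$report$excluded_probes
  expect_equal(rep_$reason[rep_$probe_id == "cg001"], "missing")
  expect_equal(rep_$reason[rep_$probe_id == "cg002"], "missing")
  expect_equal(rep_$reason[rep_$probe_id == "cg003"], "snp_overlap")
  expect_equal(rep_$reason[rep_$probe_id == "cg004"], "non_unique_mapping")
  expect_equal(nrow(res$mset), 2)
  expect_equal(sum(rep_$probe_id == "cg002"), 1)  # counted exactly once
})

test_that("phenotype outlier rule is a one-pass z-score", {
  sheet <- data.frame(sample_id = paste0("S", 1:5),
                      bmi = c(25, 26, 27, 28, 60))
  z <- abs(60 - mean(sheet$bmi)) / sd(sheet$bmi)
  res <- removePhenotypeOutliers(sheet, "bmi", 3)
  if (z > 3) {
    expect_equal(res$sheet$sample_id, paste0("S", 1:4))
  } else {
    expect_equal(nrow(res$sheet), 5)
  }
  # direct arithmetic on a clearer case
  sheet2 <- data.frame(sample_id = paste0("S", 1:11),
                       bmi = c(rep(c(27, 29), 5), 80))
  res2 <- removePhenotypeOutliers(sheet2, "bmi", 3)
  expect_equal(nrow(res2$report$excluded_samples), 1)
  # degenerate cases
  same <- data.frame(sample_id = paste0("S", 1:4), bmi = rep(25, 4))
  expect_equal(nrow(removePhenotypeOutliers(same, "bmi", 3)$sheet), 4)
  expect_equal(nrow(removePhenotypeOutliers(sheet2, "bmi", Inf)$sheet), 11)
})

test_that("deconvolution recovers pure columns and mixtures on the simplex", {
  R <- simulateCellReference(6, 40, seed = 5)
  # pure sample = reference column 3
  b <- cbind(R[, 3], 0.6 * R[, 1] + 0.4 * R[, 2],
             runif(nrow(R)))
  colnames(b) <- c("pure", "mix", "noise")
  cp <- estimateCellProportions(b, R)
  W <- as.matrix(cp[, -1]); rownames(W) <- cp$sample_id
  expect_equal(unname(W["pure", 3]), 1, tolerance = 1e-6)
  expect_equal(unname(W["mix", 1]), 0.6, tolerance = 0.05)
  expect_equal(unname(W["mix", 2]), 0.4, tolerance = 0.05)
  expect_equal(unname(rowSums(W)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(W >= -1e-9))
})

test_that("deconvolution recovers Dirichlet mixtures within MAE 0.05", {
  set.seed(6)
  R <- simulateCellReference(6, 50, seed = 6)
  W <- xewas:::rdirichlet(20, c(18, 2.4, 1.5, 1.5, 4.5, 2.4))
  B <- R %*% t(W) + matrix(rnorm(50 * 20, 0, 0.02), 50, 20)
  colnames(B) <- paste0("S", 1:20)
  est <- as.matrix(estimateCellProportions(B, R)[, -1])
  expect_lt(mean(abs(est - W)), 0.05)
})
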