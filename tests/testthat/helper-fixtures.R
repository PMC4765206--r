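# Shared in-code fixtures.

# small unrelated-cohort sample sheet (no twins)
makeSheet <- function(n = 60, pCurrent = 0.3, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    sex = "male",
    age = round(rnorm(n, 55, 4), 1),
    bmi = round(rnorm(n, 28, 4), 1),
    smoking_status = sample(c("never", "past", "current"), n, TRUE,
                            prob = c(0.5, 1 - 0.5 - pCurrent, pCurrent)),
    stringsAsFactors = FALSE) |>
    within({
      pack_years <- ifelse(smoking_status == "never", NA,
                           round(pmax(rnorm(n, 25, 12), 0.5), 1))
    })
}

# tiny MethylationSet with annotation
makeMset <- function(nProbes = 8, nSamples = 6, seed = 1,
                     detection = FALSE) {
  set.seed(seed)
  b <- matrix(runif(nProbes * nSamples), nProbes, nSamples,
              dimnames = list(sprintf("cg%03d", seq_len(nProbes)),
                              sprintf("S%03d", seq_len(nSamples))))
  ann <- data.frame(probe_id = rownames(b), chromosome = "chrX",
                    position = seq(1000, by = 100,
                                   length.out = nProbes),
                    snp_overlap = FALSE, unique_mapping = TRUE)
  sheet <- makeSheet(nSamples)
  dp <- if (detection)
    matrix(1e-5, nProbes, nSamples)
  else NULL
  MethylationSet(b, sampleSheet = sheet, probeAnnotation = ann,
                 detectionP = dp)
}

# bivariate-normal twin pairs with given within-pair correlation
rpairs <- function(nPairs, r) {
  z1 <- rnorm(nPairs); z2 <- rnorm(nPairs)
  cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
}
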