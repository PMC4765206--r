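# Synthetic X-methylome generator: XCI-driven sex dimorphism, twin ACE
# covariance, smoking effects, chip/batch artifacts and cell-composition
# confounding, with a ground-truth table for every simulated site.

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

.siteClasses <- c("male-unmethylated", "male-methylated",
                  "female-hemimethylated-XCI", "multimodal", "escape")

#' Specification of one simulated CpG site
#'
#' @param probe_id site identifier.
#' @param site_class one of `"male-unmethylated"`, `"male-methylated"`,
#'   `"female-hemimethylated-XCI"` (males at one pole, females near 0.5 from
#'   X inactivation), `"multimodal"` (two-component male mixture) or
#'   `"escape"` (site escaping XCI: both sexes at the same pole).
#' @param base_mean_male,base_mean_female baseline beta means in (0, 1); when
#'   `NULL`, class-typical defaults are used (poles at 0.05 / 0.90,
#'   hemimethylation at 0.5).
#' @param dispersion beta-distribution concentration of the measurement
#'   noise (larger = less noise).
#' @param smoking_effect_beta signed beta-scale shift for current smokers
#'   (0 for null sites).
#' @param ace_weights numeric `(a2, c2, e2)`, nonnegative, summing to 1:
#'   additive-genetic, common- and unique-environment fractions of the latent
#'   (logit-scale) person-to-person variance.
#' @param latent_sd SD of the latent logit-scale liability (0 disables
#'   person-level variation beyond measurement noise).
#' @param snp_overlap,unique_mapping annotation flags for the QC filters.
#' @param mix_prop,mix_mean2 for `"multimodal"`: mass and mean of the second
#'   male component.
#' @return one-row `data.frame` (a site spec); rbind specs to form a panel.
#' @export
siteSpec <- function(probe_id, site_class = "male-unmethylated",
                     base_mean_male = NULL, base_mean_female = NULL,
                     dispersion = 200, smoking_effect_beta = 0,
                     ace_weights = c(0, 0.4, 0.6), latent_sd = 0.3,
                     snp_overlap = FALSE, unique_mapping = TRUE,
                     mix_prop = 0.5, mix_mean2 = NULL) {
  site_class <- match.arg(site_class, .siteClasses)
  defaults <- switch(site_class,
    "male-unmethylated"         = c(m = 0.05, f = 0.10),
    "male-methylated"           = c(m = 0.90, f = 0.85),
    "female-hemimethylated-XCI" = c(m = 0.05, f = 0.50),
    "multimodal"                = c(m = 0.05, f = 0.50),
    "escape"                    = c(m = 0.07, f = 0.09))
  if (is.null(base_mean_male)) base_mean_male <- defaults[["m"]]
  if (is.null(base_mean_female)) base_mean_female <- defaults[["f"]]
  if (is.null(mix_mean2)) mix_mean2 <- 0.90
  ace_weights <- as.numeric(ace_weights)
  if (length(ace_weights) != 3 || any(ace_weights < -1e-9) ||
      abs(sum(ace_weights) - 1) > 1e-6)
    stop("ace_weights must be three nonnegative fractions summing to 1")
  if (base_mean_male <= 0 || base_mean_male >= 1 ||
      base_mean_female <= 0 || base_mean_female >= 1)
    stop("base means must lie strictly in (0, 1)")
  if (dispersion <= 0) stop("dispersion must be positive")
  data.frame(probe_id = probe_id, site_class = site_class,
             base_mean_male = base_mean_male,
             base_mean_female = base_mean_female,
             dispersion = dispersion,
             smoking_effect_beta = smoking_effect_beta,
             a2 = ace_weights[1], c2 = ace_weights[2], e2 = ace_weights[3],
             latent_sd = latent_sd, snp_overlap = snp_overlap,
             unique_mapping = unique_mapping,
             mix_prop = mix_prop, mix_mean2 = mix_mean2,
             stringsAsFactors = FALSE)
}

# ACE-structured standard-normal liabilities: correlation 1 within MZ pairs
# for the genetic part, 0.5 within DZ pairs, 1 for the shared environment.
.aceLiability <- function(sheet, a2, c2, e2) {
  n <- nrow(sheet)
  pid <- if ("pair_id" %in% names(sheet)) sheet$pair_id else rep(NA, n)
  zyg <- if ("zygosity" %in% names(sheet)) sheet$zygosity else rep(NA, n)
  upair <- unique(pid[!is.na(pid)])
  aPair <- stats::setNames(stats::rnorm(length(upair)), upair)
  cPair <- stats::setNames(stats::rnorm(length(upair)), upair)
  A <- stats::rnorm(n); C <- stats::rnorm(n)
  paired <- !is.na(pid)
  if (any(paired)) {
    C[paired] <- cPair[pid[paired]]
    mz <- paired & !is.na(zyg) & zyg == "MZ"
    dz <- paired & !is.na(zyg) & zyg == "DZ"
    A[mz] <- aPair[pid[mz]]
    A[dz] <- sqrt(0.5) * aPair[pid[dz]] + sqrt(0.5) * stats::rnorm(sum(dz))
  }
  E <- stats::rnorm(n)
  sqrt(a2) * A + sqrt(c2) * C + sqrt(e2) * E
}

#' Simulate beta-values for one site across a cohort
#'
#' Per-sample beta means start at the sex-specific baseline on the logit
#' scale, shifted by an ACE-structured latent liability (correlation 1 for
#' the genetic component within MZ pairs, 0.5 within DZ pairs, shared
#' environment common to both co-twins), are mapped back through the
#' inverse logit, then measurement noise is drawn from a beta distribution
#' with the spec's concentration. Current smokers are shifted by
#' `smoking_effect_beta` on the beta scale (the scale on which array effect
#' sizes are reported) and values are clipped to (1e-6, 1 - 1e-6).
#' Multimodal sites draw males from a two-component mixture.
#'
#' @param spec one-row site spec from [siteSpec()].
#' @param sheet sample sheet with at least `sex`; twin columns (`pair_id`,
#'   `zygosity`) and `smoking_status` are used when present.
#' @param seed optional integer seed.
#' @return numeric vector of beta-values, one per sheet row.
#' @export
simulateSiteBetas <- function(spec, sheet, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!"sex" %in% names(sheet) || anyNA(sheet$sex))
    stop("sheet must give sex for every sample")
  n <- nrow(sheet)
  male <- sheet$sex == "male"
  mu <- ifelse(male, spec$base_mean_male, spec$base_mean_female)
  if (spec$site_class == "multimodal") {
    comp2 <- male & (stats::runif(n) < spec$mix_prop)
    mu[comp2] <- spec$mix_mean2
  }
  z <- .aceLiability(sheet, spec$a2, spec$c2, spec$e2)
  eta <- stats::qlogis(mu) + spec$latent_sd * z
  m <- stats::plogis(eta)
  phi <- spec$dispersion
  beta <- stats::rbeta(n, m * phi, (1 - m) * phi)
  if (spec$smoking_effect_beta != 0 && "smoking_status" %in% names(sheet)) {
    cur <- !is.na(sheet$smoking_status) & sheet$smoking_status == "current"
    beta[cur] <- beta[cur] + spec$smoking_effect_beta
  }
  pmin(pmax(beta, 1e-6), 1 - 1e-6)
}

#' Cohort design for the simulator
#'
#' Defaults mirror the discovery twin cohort the framework targets: 139
#' middle-aged male twins with 34% current smokers, an MZ:DZ ratio of 3:1
#' (81 MZ and 27 DZ pairs in the modelled study), methylation chips of 12
#' samples, and six leukocyte subtypes.
#'
#' @param nMale,nFemale samples per sex.
#' @param twinFraction fraction of samples belonging to a complete same-sex
#'   twin pair.
#' @param mzRatio fraction of twin pairs that are monozygotic.
#' @param currentSmokerFraction,pastSmokerFraction smoking-status marginals.
#' @param meanAge,sdAge,meanBmi,sdBmi phenotype distributions (years, kg/m2).
#' @param batchSize samples per chip/batch.
#' @param batchSdM SD of the additive per-batch offset on the M scale.
#' @param nCellTypes leukocyte subtypes for the cell-mixture model.
#' @param cellAlpha Dirichlet concentration of the per-sample cell
#'   proportions (defaults give granulocyte-dominated blood).
#' @return a `CohortDesign` (named list).
#' @export
cohortDesign <- function(nMale = 139, nFemale = 0, twinFraction = 1,
                         mzRatio = 0.75, currentSmokerFraction = 0.34,
                         pastSmokerFraction = 0.33, meanAge = 55.7,
                         sdAge = 3.3, meanBmi = 28.9, sdBmi = 4.3,
                         batchSize = 12, batchSdM = 0.15, nCellTypes = 6,
                         cellAlpha = c(18, 2.4, 1.5, 1.5, 4.5, 2.4)) {
  stopifnot(nMale + nFemale >= 1, twinFraction >= 0, twinFraction <= 1,
            mzRatio >= 0, mzRatio <= 1,
            currentSmokerFraction + pastSmokerFraction <= 1)
  out <- list(nMale = nMale, nFemale = nFemale, twinFraction = twinFraction,
              mzRatio = mzRatio,
              currentSmokerFraction = currentSmokerFraction,
              pastSmokerFraction = pastSmokerFraction,
              meanAge = meanAge, sdAge = sdAge, meanBmi = meanBmi,
              sdBmi = sdBmi, batchSize = batchSize, batchSdM = batchSdM,
              nCellTypes = nCellTypes,
              cellAlpha = rep_len(cellAlpha, nCellTypes))
  class(out) <- "CohortDesign"
  out
}

.simulateSheet <- function(design) {
  n <- design$nMale + design$nFemale
  sex <- c(rep("male", design$nMale), rep("female", design$nFemale))
  sheet <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age = round(stats::rnorm(n, design$meanAge, design$sdAge), 1),
    bmi = round(stats::rnorm(n, design$meanBmi, design$sdBmi), 1),
    smoking_status = sample(.smokingLevels, n, replace = TRUE,
                            prob = c(1 - design$currentSmokerFraction -
                                       design$pastSmokerFraction,
                                     design$pastSmokerFraction,
                                     design$currentSmokerFraction)),
    pair_id = NA_character_, zygosity = NA_character_,
    stringsAsFactors = FALSE)
  smoker <- sheet$smoking_status != "never"
  sheet$years_smoked <- ifelse(smoker,
                               round(pmax(stats::rnorm(n, 25, 8), 1)), NA)
  sheet$cigarettes_per_day <- ifelse(smoker,
                                     round(pmax(stats::rnorm(n, 18, 8), 1)),
                                     NA)
  # same-sex twin pairs within sex strata
  pairCounter <- 0L
  for (sx in c("male", "female")) {
    idx <- which(sheet$sex == sx)
    nPairs <- floor(length(idx) * design$twinFraction / 2)
    if (nPairs < 1) next
    members <- idx[seq_len(2 * nPairs)]
    pids <- sprintf("P%04d", pairCounter + rep(seq_len(nPairs), each = 2))
    zyg <- rep(ifelse(stats::runif(nPairs) < design$mzRatio, "MZ", "DZ"),
               each = 2)
    sheet$pair_id[members] <- pids
    sheet$zygosity[members] <- zyg
    pairCounter <- pairCounter + nPairs
  }
  # co-twins ride the same chip only sometimes: assign batches by sample
  sheet$batch_id <- sprintf("chip%02d",
                            ceiling(sample.int(n) / design$batchSize))
  validateSampleSheet(sheet)
}

#' Simulate a cell-type reference profile
#'
#' Marker beta means are drawn so that each marker separates its designated
#' discriminating pair of cell types by at least 0.3, emulating the
#' cell-type-specific CpGs a reference-based deconvolution relies on.
#'
#' @param kCellTypes number of cell types (>= 2); six get canonical
#'   leukocyte labels.
#' @param nMarkers number of marker sites.
#' @param seed optional integer seed.
#' @return `nMarkers` x `kCellTypes` matrix with marker probe ids as
#'   rownames.
#' @export
simulateCellReference <- function(kCellTypes = 6, nMarkers = 60,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (kCellTypes < 2) stop("need at least two cell types")
  labels <- if (kCellTypes == 6)
    c("granulocyte", "monocyte", "NK", "B", "CD4T", "CD8T")
  else paste0("cell", seq_len(kCellTypes))
  R <- matrix(stats::runif(nMarkers * kCellTypes, 0.35, 0.65),
              nMarkers, kCellTypes,
              dimnames = list(sprintf("cgMARK%04d", seq_len(nMarkers)),
                              labels))
  hi <- sample.int(kCellTypes, nMarkers, replace = TRUE)
  for (i in seq_len(nMarkers)) {
    R[i, hi[i]] <- stats::runif(1, 0.75, 0.95)
    lo <- sample(setdiff(seq_len(kCellTypes), hi[i]), 1)
    R[i, lo] <- stats::runif(1, 0.05, 0.25)
  }
  R
}

#' Simulate a full cohort with ground truth
#'
#' Assembles the beta matrix site by site via [simulateSiteBetas()], then
#' adds an additive per-chip offset on the M scale (intensity artifacts are
#' approximately additive in logit space), and overwrites designated marker
#' sites with per-sample mixtures of the cell-type reference profile drawn
#' from a Dirichlet.
#'
#' @param specs site-spec `data.frame` (rbind of [siteSpec()] rows).
#' @param design a [cohortDesign()].
#' @param seed integer seed; the whole cohort is reproducible under it.
#' @param cellReference optional marker-by-cell-type matrix (see
#'   [simulateCellReference()]); marker rows are appended to the matrix.
#' @param markerNoiseSd Gaussian noise SD added to marker-site mixtures.
#' @return `list(mset =, sheet =, annotation =, truth =, cellProportions =)`;
#'   `truth` records each site's class, smoking effect and ACE weights,
#'   `cellProportions` the per-sample simulated mixing fractions.
#' @export
simulateCohort <- function(specs, design = cohortDesign(), seed = 1L,
                           cellReference = NULL, markerNoiseSd = 0.02) {
  set.seed(as.integer(seed))
  sheet <- .simulateSheet(design)
  n <- nrow(sheet)
  beta <- matrix(NA_real_, nrow(specs), n,
                 dimnames = list(specs$probe_id, sheet$sample_id))
  for (i in seq_len(nrow(specs)))
    beta[i, ] <- simulateSiteBetas(specs[i, ], sheet)
  # chip/batch offsets on the M scale
  batches <- unique(sheet$batch_id)
  off <- stats::setNames(stats::rnorm(length(batches), 0, design$batchSdM),
                         batches)
  M <- mFromBeta(beta) + matrix(off[sheet$batch_id], nrow(beta), n,
                                byrow = TRUE)
  beta <- betaFromM(M)
  cellProp <- NULL
  if (!is.null(cellReference)) {
    k <- ncol(cellReference)
    W <- rdirichlet(n, design$cellAlpha[seq_len(k)])
    colnames(W) <- colnames(cellReference)
    mix <- cellReference %*% t(W) +
      matrix(stats::rnorm(nrow(cellReference) * n, 0, markerNoiseSd),
             nrow(cellReference), n)
    mix <- pmin(pmax(mix, 1e-6), 1 - 1e-6)
    colnames(mix) <- sheet$sample_id
    beta <- rbind(beta, mix)
    cellProp <- data.frame(sample_id = sheet$sample_id, as.data.frame(W),
                           check.names = FALSE)
  }
  annotation <- data.frame(
    probe_id = rownames(beta),
    chromosome = "chrX",
    position = seq(40000000L, by = 997L, length.out = nrow(beta)),
    gene_symbol = NA_character_,
    snp_overlap = c(specs$snp_overlap,
                    rep(FALSE, nrow(beta) - nrow(specs))),
    unique_mapping = c(specs$unique_mapping,
                       rep(TRUE, nrow(beta) - nrow(specs))),
    stringsAsFactors = FALSE)
  truth <- specs[, c("probe_id", "site_class", "smoking_effect_beta",
                     "a2", "c2", "e2")]
  mset <- MethylationSet(beta, sampleSheet = sheet,
                         probeAnnotation = annotation)
  list(mset = mset, sheet = sheet, annotation = annotation, truth = truth,
       cellProportions = cellProp)
}

#' Convenience panel of site specs
#'
#' Builds a mixed panel: `nNull` unimodal null sites (classes alternating
#' between the male poles), plus optional XCI-hemimethylated, multimodal and
#' causal (smoking-affected) sites.
#'
#' @param nNull,nXci,nMultimodal numbers of sites per class.
#' @param causalEffects numeric vector of beta-scale smoking effects; one
#'   causal site is added per element.
#' @param dispersion,latent_sd passed to [siteSpec()]. The defaults are
#'   calibrated so that a current-smoking contrast at the discovery design
#'   (139 males, 47 current smokers) has a sampling SE near 0.009 on the
#'   beta scale, the precision the modelled study reports for its top site.
#' @return site-spec `data.frame`.
#' @export
sitePanel <- function(nNull = 100, nXci = 0, nMultimodal = 0,
                      causalEffects = numeric(), dispersion = 300,
                      latent_sd = 0.15) {
  specs <- list(); k <- 0
  add <- function(s) { k <<- k + 1; specs[[k]] <<- s }
  for (i in seq_len(nNull))
    add(siteSpec(sprintf("cgNULL%04d", i),
                 if (i %% 2) "male-unmethylated" else "male-methylated",
                 dispersion = dispersion, latent_sd = latent_sd))
  for (i in seq_len(nXci))
    add(siteSpec(sprintf("cgXCI%04d", i), "female-hemimethylated-XCI",
                 dispersion = dispersion, latent_sd = latent_sd))
  for (i in seq_len(nMultimodal))
    add(siteSpec(sprintf("cgMULTI%04d", i), "multimodal",
                 dispersion = dispersion, latent_sd = latent_sd))
  for (i in seq_along(causalEffects))
    add(siteSpec(sprintf("cgCAUSAL%02d", i),
                 if (causalEffects[i] >= 0) "male-unmethylated"
                 else "male-methylated",
                 base_mean_male = if (causalEffects[i] >= 0) 0.45 else 0.75,
                 base_mean_female = 0.5,
                 smoking_effect_beta = causalEffects[i],
                 dispersion = dispersion, latent_sd = latent_sd))
  do.call(rbind, specs)
}
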