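---
title: "Methods: sex-aware X chromosome-wide methylation association"
author: "xewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-aware X chromosome-wide methylation association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

X chromosome inactivation (XCI) silences one female X copy; at many
X-linked CpG sites the silenced copy is methylated and the active copy is
not, so female beta-values concentrate near 0.5 while male beta-values —
one X copy — sit near 0 or 1. A pooled-sex sample therefore mixes two
sex-specific distributions and is frequently bimodal, violating the
single-population assumption behind site-wise regression. `xewas`
operationalises the resulting analysis recipe: verify unimodality *within
a sex stratum*, model the exposure association stratified by sex, use twin
structure to partition variance and isolate the unique-environment
(exposure) component, and combine cohorts by fixed-effect meta-analysis.

# Measurement scales

Raw intensities give beta = max(I_meth, 0) / (|I_meth| + |I_unmeth| + α)
with α = 100 by default (the platform's customary regulariser; the offset
only matters for low-intensity probes). Models can run on beta (effects in
absolute methylation-fraction units, directly interpretable) or on
M = log2(beta/(1−beta)) (approximately homoscedastic). Beta-values are
clipped to [1e-6, 1−1e-6] before the logit so |M| ≤ ~19.93; the clip keeps
the transform finite without perturbing ordering. Both scales are first-
class throughout; significance agrees closely between them except at
pole-proximal sites, where beta-scale heteroscedasticity adds rank noise
among null sites (the test suite asserts rank correlation > 0.9 and exact
agreement of the FDR hit sets rather than near-perfect global rank
agreement).

# The dip statistic and its empirical null

The dip of a sample is `inf_{F unimodal} sup_x |F(x) − F_n(x)|`. The
solver works directly from this definition. For a candidate value d the
question "is some unimodal CDF within d of F_n everywhere?" reduces, on
the distinct sorted values t_1 < … < t_K with cumulative fractions c_k, to
a band-feasibility problem: a unimodal CDF is convex before its mode and
concave after (an atom is allowed only at the mode), so for each candidate
mode index the left piece must be a nondecreasing convex chain through the
bands [c_k/n − d, c_{k−1}/n + d] and the right piece its concave mirror
image, joined monotonically at the mode. The binding lower bounds on a
convex chain are the pairwise "forcing lines" through an earlier upper
band corner and a later lower band corner (steeper cascaded bounds are
convex combinations of pairwise ones, hence dominated); feasibility and
the extremal junction values come from a single sweep with a convex-hull
tangent structure and a line-envelope tree, and d is then bisected to
below 1e-12. Ties enter as single jumps of mass k/n, which is why the
bands use cumulative counts rather than ranks.

Correctness is anchored three ways: hand-derived exact values (two equal
point masses give dip 0.25, the maximum; {0,0,0,1} gives 1/8; an
equally-spaced grid gives 1/(2n)); a brute-force oracle that minimises
max|F − F_n| over piecewise-linear unimodal CDFs by explicit linear
programming per candidate mode (tests assert agreement to 1e-9 on
hundreds of random tiny samples); and an independently coded pure-R
implementation used to cross-check null-table medians at moderate n.

P-values are empirical: dips of `n_sim` uniform samples of the same size
(the asymptotically least favourable unimodal distribution) are tabulated
and `p = (1 + #{null ≥ observed}) / (n_sim + 1)` — the +1 is the standard
Monte-Carlo guard against p = 0. When the observed dip exceeds every
tabulated null the p-value is reported as the *bound* 1/(n_sim+1) with an
explicit flag, never as an exact value; this generalises the practice of
capping extreme empirical p-values at the resolution of the simulation.
The default `n_sim` is 1e4 in the screen (1e5 in `buildNullTable`);
a warning fires when the Bonferroni threshold α/m is unattainable at the
configured resolution. Tables are built per distinct complete-case size;
when a probe's missingness leaves a size with no table, the nearest
tabulated size is used and recorded in `null_n` — a documented desk-scale
concession to the ideal of simulating every size. Tables can be persisted
to disk as plain TSV and reloaded (`cacheDir`).

One caution about calibration testing: p-values derived from a single
finite null table are uniform only marginally over the table's own
randomness. Conditioned on one table, a one-sample
Kolmogorov–Smirnov test against the exact uniform will over-reject,
because the table's Monte-Carlo error (~n_sim^−1/2) is comparable to the
KS critical value at large replicate counts. The calibration check is
therefore formulated as the equivalent two-sample KS between fresh null
dips and the table, plus a nominal-rate check at α = 0.05.

A related mathematical note: the dip does not increase monotonically with
the number of modes. Three equal point masses have dip 1/6, *less* than
the 1/4 of two equal masses, because a central mode absorbs more mass.
What holds — and what the tests assert — is that well-separated
multimodality keeps the dip far above unimodal-null levels.

# Modality screening policy

Screening runs within a sex stratum (males by default: a single X makes
every site's biology unimodal unless something interesting is happening)
with Bonferroni correction at α = 0.05 across the screened sites.
Sites flagged multimodal are reported, not silently dropped; SNP-
overlapping probes should be excluded upstream by the probe QC, which is
why the screen sits after filtering in the pipeline order.

# Quality control

Order: detection-p masking (cells with p > 0.001 become missing) →
sample missing-rate filter (> 5% excluded) → probe filters → BMI outlier
exclusion. Probe filters apply in the fixed precedence *missing rate >
SNP overlap > non-unique mapping*, each probe counted once under its
first matching rule, so exclusion tallies are reproducible. The BMI rule
removes samples more than 3 SD from the mean, computed once on the full
sheet — deliberately non-iterative so the exclusion set cannot depend on
itself. Every exclusion carries exactly one primary reason in the QC
report, and the pipeline report's counts satisfy input = retained +
excluded at each stage.

# Cell-type adjustment

Reference-based deconvolution estimates the six leukocyte subtype
proportions (granulocyte, monocyte, NK, B, CD4+ T, CD8+ T) per sample by
minimising ||beta_markers − R w||² subject to w ≥ 0 and Σw = 1. With k ≤ 6
the solver enumerates all 2^k − 1 support sets and solves each
equality-constrained subproblem by Lagrange elimination — exact for this
size, no iterative QP needed. The sum-to-one constraint is imposed (some
variants leave the sum free) because the proportions enter the
association models as compositional covariates; there, one category —
granulocyte by default, the majority type — is dropped to avoid exact
collinearity. A rank-deficient reference is an error, not a warning.

# Association models

The site model regresses beta or M on the exposure (current vs
non-current smoking, i.e. current against past-plus-never; or pack-years
= years smoked × cigarettes/20 per day, restricted by default to current
and past smokers with positive pack-years) with age, BMI and k−1 cell
proportions as covariates. With chip/batch or co-twin grouping available
the model adds independent random intercepts per grouping, *crossed* not
nested — co-twins share a chip only sometimes, so the crossed structure
is the safe general case. Mixed models are fitted by REML (lme4); the
Wald statistic uses residual degrees of freedom n − p rather than a
Satterthwaite approximation — simple, stable at these sample sizes, and
slightly conservative; documented as an approximation. Without random
terms the fit is ordinary least squares, and when all sites share one
complete-case design the scan is solved by a single multi-response QR
decomposition (algebraically identical to the per-site fit, asserted in
the tests to 1e-10).

Per-site missing data are handled by complete-case analysis within each
fit, with the n actually used recorded per site; covariate sets are
configurable per cohort because replication datasets often lack BMI or
batch information. Degenerate designs (constant exposure, too few
complete cases, singular fits) are reported per site and the scan
continues. Multiple testing uses Benjamini–Hochberg FDR at 0.05;
the genomic-control factor λ (median χ²₁ statistic / 0.4549) is exposed
as a scan diagnostic, and QQ/Manhattan/forest tables are exported as
plain data for plotting rather than rendered figures.

# Twin analyses

The ACE model standardises the trait and treats co-twin pairs as
unit-variance bivariate normals with correlation a² + c² (MZ) and
a²/2 + c² (DZ). The ML fit maximises the Gaussian pair likelihood over
the 2-simplex, parameterised by softmax coordinates so boundary solutions
(a² = 0 is common for methylation) are reachable without constraint
violations; four starts (three fixed plus the Falconer point) guard
against local optima, ties break by likelihood then by smaller a².
Components below 1e-6 are snapped to exact zero. The Falconer closed form
a² = 2(r_MZ − r_DZ), c² = 2r_DZ − r_MZ, e² = 1 − r_MZ (truncated to the
simplex and renormalised) is provided both as a fast method and as the ML
starting point; pair correlations are computed by double entry so the
result is invariant to within-pair member ordering. Covariate
pre-adjustment before the decomposition is left to the caller
(residualise, then decompose); the trait standardisation means only
variance *fractions* are estimated.

The discordant-MZ design compares exposed and unexposed co-twins within
MZ pairs discordant for current smoking: genetics and shared environment
cancel within pair, so the paired t-test (two-sided, n_pairs − 1 df)
isolates the unique-environment effect. Zero-variance differences are
reported as degenerate with NA statistics rather than as spurious
certainty. In the power-contrast check the within-pair difference SD is
set to 0.067, backed out from the modelled study's printed paired test
(a 0.054 difference at p = 8.29e-4 on 22 df implies t ≈ 3.84 and hence
SD ≈ 0.054·√23/3.84); at that noise level a 0.054 shift is detected in
most 23-pair replicates while a 0.0083 shift rarely is — the framework's
expected behaviour at these sample sizes, not a defect.

# Meta-analysis

Classical fixed-effect inverse variance: w_i = 1/se_i², combined estimate
Σw_i b_i/Σw_i, se (Σw_i)^−1/2, two-sided normal p on z = combined/se
(per-cohort tables sometimes label this column as a t statistic; the
normal reference is the standard fixed-effect convention and the
difference is negligible at these df). Q = Σw_i(b_i − combined)² on k−1
df; I² = max(0, (Q − df)/Q)·100, truncated at zero and defined as 0 when
Q = 0; both undefined for a single study, which passes through unchanged.
No Hartung–Knapp or continuity adjustments — strictly the named
estimator. Recomputing the four-cohort combination for the hypomethylated
site gives a combined SE of 0.003, matching the tabulated value; a prose
mention of "0.03" elsewhere in the source material is a typographical
slip and is not propagated. Note that combined estimates recomputed from
2-significant-figure inputs can differ from published roundings by one
unit in the last digit (0.0437 rounds to 0.044 against a printed 0.043);
the acceptance checks therefore use absolute tolerances of ~1.5 units in
the last printed digit.

# The synthetic X-methylome generator

Each simulated site draws a per-person latent liability z ~ N(0,1) with
ACE covariance (genetic component correlation 1 within MZ, 0.5 within DZ;
shared environment common to co-twins), shifts the sex-specific baseline
on the logit scale by `latent_sd · z`, maps back through the inverse
logit, and adds measurement noise from a beta distribution with
concentration `dispersion` — values stay in (0,1) and the variance shrinks
near the poles, mimicking the heteroscedasticity that motivates the M
transform. The ACE partition is exact on the latent scale and approximate
on beta; tests that quantify ACE recovery therefore either simulate pairs
directly on the latent scale or use high-concentration sites where the
attenuation is negligible. Smoking effects are added on the beta scale
(the scale on which array effect sizes are reported) after the latent
draw, then clipped to (1e-6, 1−1e-6). Chip/batch artifacts are additive
normal offsets on the M scale (intensity artifacts are approximately
multiplicative, hence additive in logit space) with SD 0.15 by default.
Cell composition enters by overwriting designated marker sites with
R w + noise, w drawn from a Dirichlet whose default concentration gives
granulocyte-dominated blood (mean proportions ≈ 0.60/0.08/0.05/0.05/
0.15/0.08).

Site classes: male-unmethylated (0.05) and male-methylated (0.90) poles,
female-hemimethylated-XCI (males at a pole, females at 0.5), multimodal
(two-component male mixture) and escape. No quantitative model of female
escape sites was available to emulate, so the escape class simply places
both sexes at the same pole and is documented as an extrapolation.

Default study conditions mirror the discovery design: 139 male twins, 34%
current smokers, all in same-sex pairs at a 3:1 MZ:DZ ratio, chips of 12.
The panel noise defaults (`dispersion` 300, `latent_sd` 0.15) are
calibrated so the current-smoking contrast at that design has a beta-scale
sampling SE near 0.009 — the precision the modelled study reports for its
top site — which fixes the "designed power" at which recovery is
evaluated. What the generator does **not** emulate: probe
cross-hybridisation, raw two-channel intensity artifacts, genomic
autocorrelation along the chromosome, smoking–sex interaction, and any
realistic female escape-site distribution. Green tests on this substrate
show the statistical machinery is correct and calibrated under the stated
generative model; they cannot certify performance on artefacts the
generator does not produce.

# Numerical and policy choices collected

* Dip bisection: 46 halvings of [0, 0.25] (resolution < 1e-12);
  feasibility tolerance 1e-12; ties collapsed to single jumps.
* Empirical p floor: always 1/(n_sim+1), always flagged as a bound.
* M-transform clip: 1e-6. Beta offset α: 100.
* QC precedence: missing > SNP > mapping; one reason per exclusion.
* BH-FDR via the standard step-up with cumulative-minimum monotonicity;
  q-values are order-invariant.
* ACE optimisation: Nelder–Mead on softmax coordinates, 4 starts,
  tie-break by loglik then smaller a²; sub-1e-6 components snapped to 0.
* Deconvolution: exhaustive active-set over ≤ 63 supports; exact.
* Pipeline determinism: every stochastic step derives from the config
  seed; rerunning a config byte-reproduces all output tables, and the run
  report records the seed and a hash of the configuration (excluding the
  output path).

# Problem sizes in the shipped checks

The test-suite and acceptance-script simulations use: 200 tiny samples
(n ≤ 8) for the LP oracle; uniform-null calibration with a 1e4-entry table
at n = 100 and 1e4 fresh replicates; 100 + 100 sites at 120 + 120
samples for the stratification contrast; 1000-site scans at n = 139–150
with 25–50 replicate cohorts for calibration and recovery; 500 + 500 twin
pairs (10–20 replicates) for ACE recovery; 23 discordant pairs × 400
replicates for the power contrast. These sizes were chosen as the
smallest that make the Monte-Carlo error comfortably smaller than each
tolerance being checked. No empirical number appears in this vignette or
the README that the tests or `scripts/acceptance.R` do not themselves
recompute.

# Limitations

* Mixed-model p-values use residual df, not Satterthwaite; at n ≈ 139
  with few random-effect levels this is mildly conservative.
* The nearest-n null-table substitution is an approximation for probes
  with unusual missingness; `null_n` makes it auditable.
* ACE estimates from beta-scale data are attenuated toward e² by
  measurement noise (quantified above); interpret fractions accordingly.
* Formal smoking × sex interaction testing is out of scope; the package
  supports sex-stratified scans and side-by-side comparison only.
* The framework's cohort-bound findings (specific significant CpGs,
  inflation factors, per-site variance fractions) depend on restricted
  human data; the shipped checks validate the machinery on synthetic
  data with known truth, not those specific values.
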