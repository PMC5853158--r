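---
title: "Two-sample Mendelian randomisation of atopy-related traits on glioma risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomisation of atopy-related traits on glioma risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the design

Observational studies have repeatedly reported that people with allergic
(atopic) conditions — eczema/atopic dermatitis, asthma and hay fever, raised
serum IgE — develop glioma less often. Those studies are vulnerable to recall
bias (often via proxy respondents), selection of controls, and reverse
causation: an immunosuppressive brain tumour can itself lower the expression
of atopy years before diagnosis. Mendelian randomisation (MR) side-steps
these problems by using germline variants as instrumental variables: alleles
are fixed at conception, so a variant robustly associated with an atopic
trait cannot be influenced by a later tumour, and its association with glioma
risk measures the downstream effect of the trait it instruments — provided
the variant affects glioma *only* through that trait (no horizontal
pleiotropy).

`atopymr` implements the two-sample flavour of this design, in which the
variant–exposure and variant–glioma associations come from non-overlapping
GWAS samples and only per-SNP summary statistics are needed. The package
covers the full path: parsing and harmonising summary statistics, five causal
estimators, pleiotropy/heterogeneity diagnostics, a generative simulation of
the binary-exposure/binary-outcome setting, and a priori power.

## Instruments and their representation

The instrument sets for the four traits (atopic dermatitis, 18 SNPs; asthma
and hay fever, 9; serum IgE level, 5; self-reported allergy, 14) ship as
plain-text TSV fixtures together with each SNP's association with all glioma
(12,488 cases / 18,169 controls). The sets were LD-pruned at r² ≥ 0.001 at
source, so instruments are treated as independent; `ld_prune()` reproduces
that rule for user-supplied sets with an LD matrix (greedy, keeping the
largest exposure |z| per correlated cluster — deterministic with |z|, then SE,
then rsID tie-breaks).

Effects are printed as ORs with 95% CIs, so the fixtures store exactly that
and `parse_or_ci()` recovers `beta = ln OR` and
`se = ln(CI_hi/CI_lo) / (2 × 1.959964)` on every load — the exact normal
quantile rather than 1.96, so that stored CIs round-trip as closely as the
printed rounding permits. This rounding matters: ORs printed at two decimals
carry up to ~6% relative error into small log-effects, which is why
quantities that are quadratic in small deviations (Cochran's Q in particular)
can differ visibly from values computed on unrounded data, while the causal
estimates themselves move by at most a few hundredths.

Harmonisation (`harmonise()`) aligns the glioma effect to the exposure's
effect allele, flipping signs where needed and attempting strand
complementation before declaring alleles incompatible. Palindromic (A/T,
C/G) SNPs cannot be strand-resolved from labels; the default policy resolves
them by comparing effect-allele frequencies and rejects SNPs whose
frequencies sit within 0.08 of 0.5 on both sides. The packaged analysis
instead uses `palindromic_action = "trust"`: both sides of each fixture come
from a single publication table printed on one strand, so label alignment is
already correct (without this, the G/C SNP rs6602364 at frequency 0.508 would
be discarded and the 18/17-SNP analyses would not be reproducible).

```{r}
library(atopymr)
sets <- load_atopy_instruments("atopic_dermatitis")
h <- harmonise(sets$exposure, sets$outcome, palindromic_action = "trust")
```

## The estimators

All estimators work on the harmonised pairs \((X_k, Y_k)\) with outcome SEs
\(\sigma_{Y_k}\) (and exposure SEs \(\sigma_{X_k}\) where stated). The raw
causal estimate is the glioma log OR per unit increase in the exposure's log
odds (per SD for IgE).

**Wald ratio & IVW.** Each SNP's ratio is \(\theta_k = Y_k / X_k\) with
first-order SE \(\sigma_{Y_k}/|X_k|\). The inverse-variance-weighted
estimate pools them as
\(\hat\beta = \sum_k X_k Y_k \sigma_{Y_k}^{-2} \big/ \sum_k X_k^2 \sigma_{Y_k}^{-2}\),
\(se(\hat\beta) = (\sum_k X_k^2 \sigma_{Y_k}^{-2})^{-1/2}\) — identically a
weighted regression of \(Y\) on \(X\) through the origin and a fixed-effect
meta-analysis of the \(\theta_k\); the test suite checks both identities to
\(10^{-10}\).

**Maximum likelihood.** \((X_k, Y_k)\) is modelled as bivariate normal with
mean \((\xi_k, \beta \xi_k)\), the reported SEs as SDs, and error correlation
\(\rho\) (0 by default: the two GWAS do not overlap). Profiling the nuisance
means analytically leaves a one-dimensional criterion
\(\tfrac12\sum_k (Y_k - \beta X_k)^2 / (\sigma_{Y_k}^2 - 2\rho\beta\sigma_{X_k}\sigma_{Y_k} + \beta^2\sigma_{X_k}^2)\),
minimised by golden-section search from the IVW solution (tolerance 1e-10);
this form is numerically stable even as \(\sigma_{X} \to 0\), where the MLE
provably collapses onto IVW. The SE comes from the observed information: the
analytic \((\beta, \xi)\) Hessian at the optimum, inverted by Schur
complement (the \(\xi\) block is diagonal). `rho_sensitivity()` sweeps
\(\rho\) over a grid to show how conclusions depend on the independence
assumption.

**Weighted median.** The 50th percentile of the ordered \(\theta_k\) under
normalised weights \(X_k^2/\sigma_{Y_k}^2\), interpolated between the
bracketing order statistics; consistent when at least half the weight comes
from valid instruments.

**Mode-based estimate.** The argmax of a weighted normal-kernel density of
the \(\theta_k\), bandwidth `phi` × the modified Silverman rule
\(0.9\,\min(sd, mad)\,K^{-1/5}\), evaluated on a fixed 2048-point grid
spanning the ratios ±4 bandwidths (deterministic; if all ratios coincide the
common value is returned). `phi = 1` by default and exposed because the
source analyses do not state it; consistent when the largest cluster of
instruments is valid.

**Bootstrap SEs.** The median and mode have no convenient analytic SE; both
use a parametric bootstrap that redraws \((X_k, Y_k)\) from normals at the
observed values/SEs and recomputes the estimator — 10,000 replicates, seed 1
by default, and the RNG state of the session is restored afterwards. Point
estimates never depend on the seed.

**MR-Egger.** After orienting every instrument to a positive exposure
effect, a weighted regression of \(Y\) on \(X\) with a free intercept
(weights \(\sigma_{Y}^{-2}\)). The slope is the pleiotropy-adjusted causal
estimate; the intercept estimates average directional pleiotropy per
instrument and is the package's formal pleiotropy test. SEs come from the
weighted regression (residual dispersion included); p-values use the
t distribution on K−2 df by default, with `p_dist = "normal"` available.

**Per-doubling conversion.** For binary exposures the raw slope is
multiplied by \(\ln 2\) before exponentiating, giving the glioma OR per
doubling in odds of the exposure; SEs and CI bounds scale identically. IgE
(per SD) is exponentiated unscaled, and the Egger intercept is never
converted.

```{r}
screen <- heidi_outlier(h, p_threshold = 0.01)
h17 <- h[!h$snp_id %in% screen$flagged, ]
per_doubling(mr_ivw(h17))
```

## Pleiotropy and heterogeneity diagnostics

`cochran_q()` computes \(Q = \sum_k w_k (\theta_k - \theta_{IVW})^2\) with
first-order weights (matching the forest-plot meta-analysis convention), its
chi-square p-value on K−1 df and \(I^2 = \max(0, (Q - df)/Q)\).
`heidi_outlier()` implements the heterogeneity-in-dependent-instruments
screen: the instrument with the strongest exposure association is the
reference (assumed valid), each other SNP's ratio deviation
\(d_k = \theta_k - \theta_{top}\) is tested on a 1-df chi-square with
delta-method variance \(var(\theta_k) + var(\theta_{top})\), and SNPs with
p < 0.01 are flagged. Here the *second-order* ratio variance (including
exposure-side uncertainty) is used, because outlier detection is sensitive to
understating the variance of weak instruments, while Q keeps first-order SEs
for comparability with the forest plot. Single-pass by default;
`iterate = TRUE` removes the worst outlier and re-screens until clean. On the
atopic-dermatitis set the screen flags rs909341 — a SNP in strong LD with a
known glioma risk locus at 20q13.33 — whose exclusion collapses \(I^2\) from
the ~90% regime to single digits; all downstream estimates for that trait use
the remaining 17 SNPs.

The pipeline's significance ledger mirrors the source analysis: p < 0.05 is
"potential", p < 0.05/4 (0.0125, Bonferroni for four traits) is
"significant", and 0.00625 is provided for subtype scans.

## The simulation harness

Ratio estimators are exact for continuous traits but only approximate when
both exposure and outcome are binary; the simulation module measures how much
that matters. For each individual, genotypes at `N` independent bi-allelic
variants are drawn Binomial(2, p) with p ~ Uniform(0.1, 0.9) (HWE, no LD);
exposure odds are \(x_j = x_0 \prod_i w_i^{g_{ij}}\) with per-allele ORs
\(w_i\) drawn from a pool (default: the printed atopic-dermatitis instrument
ORs, so simulated instrument strengths match the real ones); outcome odds are
\(y_j = y_0 \cdot 2^{\log_2 x_j \log_2 v}\), so \(v\) is exactly the outcome
OR per doubling of exposure odds and the true per-doubling log OR is
\(\ln v\); statuses are Bernoulli draws from odds/(1+odds). Baselines
\(x_0 = 0.0005\), \(y_0 = 0.01\) give trait- and glioma-like prevalences. The
cohort is split into two random halves; each half yields one case-control
GWAS (all cases and all controls by default), fitted per variant by additive
logistic regression, with perfect-separation fits reported as non-estimable
and excluded downstream.

Two scenarios matter: the null `v = 1.00` and causal `v = 1.33`. The
desk-scale profile — 100,000 individuals and 20 replicates — keeps the full
loop (simulate → two GWAS → harmonise → five estimators) at a few minutes on
one CPU and is what the tests and `analysis/04_simulation.R` run;
`paper_scale = TRUE` switches to 1,000,000 individuals and 100 replicates.
At desk scale the causal scenario leaves only tens of outcome cases per half
(the coupling \(y \propto x^{\log_2 v}\) with \(x \ll 1\) lowers outcome
prevalence), so the noisier estimators — MR-Egger above all — recover the
correct *sign* in most but not all replicates even though their means are
close to truth. What the harness does *not* emulate: LD between variants,
pleiotropic (invalid) instruments, covariates in the GWAS regressions, or
overlap between the two samples — so passing simulations demonstrate
estimator behaviour under clean assumptions, not robustness to their
violation.

```{r}
res <- run_scenarios(sim_scenario(v = 1.33, seed = 1), n_boot = 200)
res$summary
```

## Power and instrument strength

`approx_power()` uses the standard normal-approximation for summary-data MR
with a case-control outcome: with total outcome sample n, case fraction c and
instrument r²,
power = \(\Phi(\Delta - z_{1-\alpha/2}) + \Phi(-\Delta - z_{1-\alpha/2})\)
with \(\Delta = \sqrt{n r^2 c(1-c)}\,|\ln OR|\). Both rejection tails are
kept so that power tends to α (not α/2) for null designs and is symmetric in
OR ↔ 1/OR. Because the external heritability estimates behind the published
power figures are not reprinted anywhere usable, the module takes r² as an
input; `snp_r_squared()` provides the HWE approximation 2p(1−p)β² per SNP as
a stand-in, which is an *upper-bound proxy* on the liability/log-odds scale
for binary traits. `f_statistic()` gives the first-stage
F = (n−k−1)/k · r²/(1−r²).

## Numerical and design choices, in one place

- CI→SE conversion uses the exact 0.975 normal quantile (1.959964).
- Wald-ratio SEs are first-order by default (the weighting the IVW formula
  implies); `second_order = TRUE` adds exposure-side uncertainty and is what
  HEIDI uses internally.
- MLE: analytic profile + golden-section search started at IVW; observed
  (not expected) information for the SE; non-convergence at the search
  boundary raises an error with diagnostics rather than returning silently.
- WME/MBE: parametric bootstrap, 10,000 replicates, seed 1; the MBE density
  grid is fixed at 2048 points so point estimates are deterministic.
- Degenerate inputs: identical ratios give Q = 0 / I² = 0 / p = 1 and an MBE
  equal to the common ratio; a zero exposure effect is an error for ratio
  methods; `i_squared` is floored at 0.
- Simulation seeds derive per replicate as `seed + rep` (cohort) and
  `seed + rep + 5e5` (case/control sampling), all well below 2³¹.
- The analysis keeps every printed decimal as-is; no value from the source
  tables is "corrected", including one rsID printed with two different
  positions in different trait blocks (joins are by rsID, positions are
  never used).

## Limitations

Reproduction is bounded by the printed precision of the input tables:
estimates land within a few hundredths of the published ORs, but
Cochran's Q / I² — quadratic in small deviations — can differ by tens of
percentage points from values computed on unrounded GWAS output, and
published MLE standard errors follow a convention this package deliberately
does not reproduce (its observed-information SEs are the defensible ones;
see the estimator section). The per-doubling OR is not comparable to
observational ORs for ever-versus-never exposure. No multivariable MR,
individual-level 2SLS, or non-linear exposure–outcome modelling is provided,
and GBM/non-GBM subtype scans are out of scope because per-SNP subtype
statistics are not packaged.
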