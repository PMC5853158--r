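#' A priori power of a two-sample MR study with a binary outcome
#'
#' Normal-approximation power for detecting a causal odds ratio with an
#' instrument explaining a given share of exposure variance, following the
#' standard sample-size formula for summary-data MR with a case-control
#' outcome:
#' \deqn{power = \Phi(\Delta - z_{1-\alpha/2}) + \Phi(-\Delta - z_{1-\alpha/2}),}
#' \deqn{\Delta = \sqrt{n\, r^2\, c(1-c)}\;|\ln OR|}
#' with `n` the total outcome sample size and `c` the case fraction. Both
#' rejection tails are kept, so power tends to `alpha` (not `alpha/2`) as
#' `r_squared` tends to 0 or the OR to 1, and the function is symmetric in
#' `target_or` versus `1/target_or`.
#'
#' @param n_cases,n_controls Outcome GWAS counts.
#' @param r_squared Proportion of exposure variance explained by the
#'   instrument set, in \[0, 1).
#' @param target_or Hypothesised causal OR (> 0).
#' @param alpha Two-sided significance level, default 0.05.
#' @return Power in \[0, 1\]. Vectorised over `target_or` and `r_squared`.
#' @export
approx_power <- function(n_cases, n_controls, r_squared, target_or, alpha = 0.05) {
  stopifnot(n_cases > 0, n_controls > 0, all(target_or > 0),
            alpha > 0, alpha < 1)
  if (any(r_squared < 0 | r_squared >= 1)) {
    stop("r_squared must lie in [0, 1)")
  }
  n <- n_cases + n_controls
  ratio <- n_cases / n
  z <- stats::qnorm(1 - alpha / 2)
  delta <- sqrt(n * r_squared * ratio * (1 - ratio)) * abs(log(target_or))
  stats::pnorm(delta - z) + stats::pnorm(-delta - z)
}

#' First-stage F statistic of an instrument set
#'
#' Instrument-strength measure for `k` instruments explaining `r_squared` of
#' the exposure variance in a sample of `n_sample`:
#' \deqn{F = \frac{n - k - 1}{k}\cdot\frac{r^2}{1 - r^2}.}
#' Values above ~10 conventionally indicate that weak-instrument bias is
#' unlikely.
#'
#' @param r_squared Variance explained, in \[0, 1).
#' @param n_sample Exposure GWAS sample size.
#' @param k_instruments Number of instruments.
#' @return The F statistic (0 iff `r_squared` is 0).
#' @export
f_statistic <- function(r_squared, n_sample, k_instruments) {
  stopifnot(k_instruments >= 1)
  if (n_sample <= k_instruments + 1) stop("n_sample must exceed k_instruments + 1")
  if (any(r_squared < 0 | r_squared >= 1)) stop("r_squared must lie in [0, 1)")
  (n_sample - k_instruments - 1) / k_instruments * r_squared / (1 - r_squared)
}

#' Per-SNP variance explained from effect size and allele frequency
#'
#' Under Hardy-Weinberg equilibrium a variant with effect-allele frequency `p`
#' and per-allele effect `beta` (per SD of a standardised trait) explains
#' `2 p (1-p) beta^2` of the trait variance; summing over independent
#' instruments approximates the instrument-set r-squared.
#'
#' @param beta Per-allele effect(s).
#' @param eaf Effect-allele frequency(ies) in (0, 1).
#' @return Per-SNP variance explained.
#' @export
snp_r_squared <- function(beta, eaf) {
  stopifnot(all(eaf > 0 & eaf < 1))
  2 * eaf * (1 - eaf) * beta^2
}

#' Power over a grid of hypothesised odds ratios
#'
#' @inheritParams approx_power
#' @param or_grid Vector of ORs to evaluate.
#' @return Tibble with columns `target_or`, `power`.
#' @export
power_grid <- function(n_cases, n_controls, r_squared,
                       or_grid = seq(0.5, 1.5, by = 0.05), alpha = 0.05) {
  tibble::tibble(
    target_or = or_grid,
    power = approx_power(n_cases, n_controls, r_squared, or_grid, alpha)
  )
}
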