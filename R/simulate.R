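#' Define a binary-exposure / binary-outcome simulation scenario
#'
#' The generative model mimics two case-control GWAS drawn from one population.
#' For individual `j` with genotypes `g_ij` at `N` independent bi-allelic
#' variants (Binomial(2, p_i), allele frequencies uniform on
#' `allele_freq_range`, Hardy-Weinberg equilibrium):
#' \deqn{x_j = x_0 \prod_i w_i^{g_{ij}}}
#' \deqn{y_j = y_0 \cdot 2^{\log_2 x_j \cdot \log_2 v}}
#' \deqn{a_j \sim Binomial(1, x_j/(1+x_j)),\quad
#'       b_j \sim Binomial(1, y_j/(1+y_j))}
#' where `x_j`, `y_j` are the exposure and outcome disease odds, `w_i` the
#' per-allele exposure OR of variant `i` (sampled from `or_pool`), and `v` the
#' causal OR for the outcome per doubling in odds of the exposure (`v = 1`:
#' no causal effect). Baseline odds `x0 = 0.0005` and `y0 = 0.01` give
#' exposure and outcome prevalences comparable to the atopy-related traits and
#' glioma.
#'
#' @param n_variants Number of instrument variants `N`.
#' @param or_pool Pool of per-allele exposure ORs from which each `w_i` is
#'   sampled with replacement; defaults to the packaged atopic-dermatitis
#'   instrument ORs so simulated instrument strengths match the real ones.
#' @param allele_freq_range Interval for the allele frequencies, default
#'   `c(0.1, 0.9)`.
#' @param x0,y0 Baseline exposure / outcome odds.
#' @param v Causal OR per doubling of exposure odds (1 = null).
#' @param n_individuals Cohort size, split at random into two halves (one per
#'   GWAS). Default 100,000 — the desk-scale profile; `paper_scale = TRUE`
#'   below gives the full-scale preset.
#' @param n_cases_exp,n_controls_exp,n_cases_out,n_controls_out Case/control
#'   counts sampled (without replacement) for each GWAS; `NULL` means all
#'   available in the half.
#' @param n_reps Replicates for [run_scenarios()], default 20 (desk scale).
#' @param seed Base seed.
#' @param paper_scale If `TRUE`, use the full-scale profile: 1,000,000
#'   individuals and 100 replicates.
#'
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_variants = 18,
                         or_pool = NULL,
                         allele_freq_range = c(0.1, 0.9),
                         x0 = 0.0005, y0 = 0.01, v = 1,
                         n_individuals = 100000,
                         n_cases_exp = NULL, n_controls_exp = NULL,
                         n_cases_out = NULL, n_controls_out = NULL,
                         n_reps = 20, seed = 1,
                         paper_scale = FALSE) {
  if (is.null(or_pool)) or_pool <- atopy_or_pool("atopic_dermatitis")
  if (paper_scale) {
    n_individuals <- 1000000
    n_reps <- 100
  }
  stopifnot(n_variants >= 1, all(or_pool > 0), x0 > 0, y0 > 0, v > 0,
            length(allele_freq_range) == 2L,
            allele_freq_range[1] > 0, allele_freq_range[2] < 1,
            allele_freq_range[1] < allele_freq_range[2],
            n_individuals >= 4, n_reps >= 1)
  for (nm in c("n_cases_exp", "n_controls_exp", "n_cases_out", "n_controls_out")) {
    val <- get(nm)
    if (!is.null(val) && (val < 1 || val > n_individuals)) {
      stop(nm, " out of range")
    }
  }
  structure(list(n_variants = n_variants, or_pool = or_pool,
                 allele_freq_range = allele_freq_range,
                 x0 = x0, y0 = y0, v = v,
                 n_individuals = n_individuals,
                 n_cases_exp = n_cases_exp, n_controls_exp = n_controls_exp,
                 n_cases_out = n_cases_out, n_controls_out = n_controls_out,
                 n_reps = n_reps, seed = seed),
            class = "sim_scenario")
}

#' Simulate one cohort under the multiplicative-odds disease model
#'
#' Draws genotypes, exposure and outcome odds and disease statuses for every
#' individual, and assigns each to one of two disjoint halves (an exact random
#' half-partition) to reflect the two-sample setting. Bit-reproducible for a
#' fixed seed.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Seed; defaults to the scenario's.
#' @return A list of class `sim_cohort`: genotype matrix `g` (individuals x
#'   variants), allele frequencies `p`, per-variant ORs `w`, odds `x`, `y`,
#'   statuses `a`, `b`, and `half` (1 or 2).
#' @export
simulate_cohort <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  n <- scenario$n_individuals
  nv <- scenario$n_variants
  p <- stats::runif(nv, scenario$allele_freq_range[1], scenario$allele_freq_range[2])
  # index-based draw: sample(x, ...) on a length-1 pool would misread x as 1:x
  w <- scenario$or_pool[sample.int(length(scenario$or_pool), nv, replace = TRUE)]
  g <- vapply(seq_len(nv), function(i) stats::rbinom(n, 2L, p[i]),
              integer(n))
  x <- scenario$x0 * exp(as.vector(g %*% log(w)))
  y <- scenario$y0 * 2^(log2(x) * log2(scenario$v))
  a <- stats::rbinom(n, 1L, x / (1 + x))
  b <- stats::rbinom(n, 1L, y / (1 + y))
  half <- rep(2L, n)
  half[sample.int(n, floor(n / 2))] <- 1L
  structure(list(g = g, p = p, w = w, x = x, y = y, a = a, b = b, half = half),
            class = "sim_cohort")
}

# additive logistic regression of a binary status on allele count, one variant
# at a time; flags non-estimable fits (perfect separation, monomorphic)
logistic_scan <- function(g, status) {
  nv <- ncol(g)
  beta <- se <- rep(NA_real_, nv)
  ok <- logical(nv)
  for (i in seq_len(nv)) {
    gi <- g[, i]
    if (stats::var(gi) == 0) next
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, gi), status, family = stats::binomial())
    )
    if (!fit$converged || fit$rank < 2L) next
    r <- seq_len(fit$rank)
    covm <- chol2inv(fit$qr$qr[r, r, drop = FALSE])
    b <- fit$coefficients[2L]
    s <- sqrt(covm[2L, 2L])
    if (!is.finite(b) || !is.finite(s) || s > 10 || abs(b) > 10) next
    beta[i] <- b; se[i] <- s; ok[i] <- TRUE
  }
  list(beta = beta, se = se, estimable = ok)
}

#' Run the two case-control GWAS on a simulated cohort
#'
#' Half 1 provides the exposure GWAS (status `a`), half 2 the outcome GWAS
#' (status `b`). Within each half the requested numbers of cases and controls
#' are sampled without replacement (all available when `NULL`) and per-variant
#' association statistics computed under an additive logistic regression
#' model. Variants with perfect separation or no variation are reported as
#' non-estimable and carry `NA` effects.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param scenario The generating [sim_scenario()].
#' @param seed Seed for the case/control sampling.
#' @return A list with `exposure` and `outcome` instrument sets (synthetic
#'   rsIDs `snp1..snpN`, aligned effect alleles) plus an `estimable` logical
#'   matrix attribute-free companion column in each set.
#' @export
two_sample_gwas <- function(cohort, scenario, seed = scenario$seed) {
  stopifnot(inherits(cohort, "sim_cohort"))
  set.seed(seed)
  gwas_half <- function(half_id, status, n_cases, n_controls, label) {
    idx <- which(cohort$half == half_id)
    cases <- idx[status[idx] == 1L]
    controls <- idx[status[idx] == 0L]
    if (!is.null(n_cases)) {
      if (length(cases) < n_cases) {
        stop("insufficient cases in half ", half_id, " (", length(cases),
             " < ", n_cases, "): scenario prevalence too low for the design")
      }
      cases <- sample(cases, n_cases)
    }
    if (!is.null(n_controls)) {
      if (length(controls) < n_controls) {
        stop("insufficient controls in half ", half_id)
      }
      controls <- sample(controls, n_controls)
    }
    rows <- c(cases, controls)
    scan <- logistic_scan(cohort$g[rows, , drop = FALSE], status[rows])
    nv <- scenario$n_variants
    d <- tibble::tibble(
      snp_id = paste0("snp", seq_len(nv)),
      effect_allele = "A", other_allele = "G",
      eaf = colMeans(cohort$g[rows, , drop = FALSE]) / 2,
      beta = scan$beta, se = scan$se, estimable = scan$estimable,
      n_cases = length(cases), n_controls = length(controls)
    )
    d
  }
  exposure <- gwas_half(1L, cohort$a, scenario$n_cases_exp,
                        scenario$n_controls_exp, "exposure")
  outcome <- gwas_half(2L, cohort$b, scenario$n_cases_out,
                       scenario$n_controls_out, "outcome")
  list(exposure = exposure, outcome = outcome)
}

sim_harmonised <- function(gwas) {
  ok <- gwas$exposure$estimable & gwas$outcome$estimable &
    gwas$exposure$beta != 0
  structure(
    tibble::tibble(snp_id = gwas$exposure$snp_id[ok],
                   x = gwas$exposure$beta[ok],
                   sigma_x = gwas$exposure$se[ok],
                   y = gwas$outcome$beta[ok],
                   sigma_y = gwas$outcome$se[ok],
                   flipped = FALSE, palindromic = FALSE),
    class = c("harmonised_instruments", "tbl_df", "tbl", "data.frame"),
    exposure_type = "binary")
}

#' Run the simulation study over replicates
#'
#' Full loop per replicate: simulate a cohort, run the two GWAS, harmonise,
#' estimate with each requested MR method, and convert per doubling. The true
#' per-doubling causal log OR under the generative model is `ln v`.
#'
#' @param scenario A [sim_scenario()] (its `n_reps` and `seed` are used unless
#'   overridden).
#' @param methods Subset of `c("ivw", "mle", "wme", "mbe", "egger")`.
#' @param reps,seed Overrides for the scenario's replicate count and seed.
#' @param n_boot Bootstrap replicates for the WME/MBE standard errors within
#'   each replicate (kept modest by default; only coverage summaries use
#'   them).
#' @return A list of class `sim_result`: `per_rep` (one row per replicate and
#'   method: per-doubling `beta`, `se`, `n_snps`), `summary` (per-method mean
#'   estimate, Monte-Carlo SE, bias, empirical 95% coverage of `ln v`,
#'   proportion of positive estimates), and the scenario.
#' @export
run_scenarios <- function(scenario, methods = c("ivw", "mle", "wme", "mbe", "egger"),
                          reps = scenario$n_reps, seed = scenario$seed,
                          n_boot = 200) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    rep_seed <- seed + r
    cohort <- simulate_cohort(scenario, seed = rep_seed)
    gwas <- two_sample_gwas(cohort, scenario, seed = rep_seed + 500000L)
    h <- sim_harmonised(gwas)
    ests <- lapply(methods, function(m) {
      est <- switch(m,
        ivw = mr_ivw(h),
        mle = mr_mle(h),
        wme = mr_weighted_median(h, n_boot = n_boot, seed = rep_seed),
        mbe = mr_mode(h, n_boot = n_boot, seed = rep_seed),
        egger = mr_egger(h)[1, ]  # slope only
      )
      tibble::tibble(rep = r, method = m,
                     beta = est$beta * log(2), se = est$se * log(2),
                     n_snps = est$n_snps)
    })
    rows[[r]] <- dplyr::bind_rows(ests)
  }
  per_rep <- dplyr::bind_rows(rows)
  truth <- log(scenario$v)
  summary <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$method),
    mean_beta = mean(.data$beta),
    mc_se = stats::sd(.data$beta) / sqrt(dplyr::n()),
    bias = mean(.data$beta) - truth,
    coverage = mean(abs(.data$beta - truth) <= stats::qnorm(0.975) * .data$se),
    prop_positive = mean(.data$beta > 0),
    mean_or = mean(exp(.data$beta)),
    .groups = "drop"
  )
  structure(list(per_rep = per_rep, summary = summary, scenario = scenario,
                 truth = truth, seed = seed),
            class = "sim_result")
}
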