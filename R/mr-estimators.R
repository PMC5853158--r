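new_mr_estimate <- function(method, beta, se, p_value, n_snps,
                            ci_quantile = stats::qnorm(0.975),
                            exposure_type = "binary") {
  out <- tibble::tibble(
    method = method,
    n_snps = as.integer(n_snps),
    beta = beta,
    se = se,
    ci_lower = beta - ci_quantile * se,
    ci_upper = beta + ci_quantile * se,
    p_value = p_value
  )
  structure(out, class = c("mr_estimate", class(out)),
            exposure_type = exposure_type)
}

#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio for one instrument is the outcome effect divided by the
#' exposure effect, `theta = y / x`; its default standard error is the
#' first-order delta-method value `sigma_y / |x|`, which ignores exposure-side
#' uncertainty and matches the weighting implied by the inverse-variance
#' pooling formula. The second-order form adds the exposure-side term
#' `y^2 sigma_x^2 / x^4`.
#'
#' @param instruments A `harmonised_instruments` tibble (see [harmonise()]).
#' @param second_order Include exposure-side uncertainty in the SE? Default
#'   `FALSE`.
#' @return Tibble with columns `snp_id`, `theta`, `se_theta`.
#' @export
wald_ratio <- function(instruments, second_order = FALSE) {
  if (any(instruments$x == 0)) stop("zero exposure effect: Wald ratio undefined")
  theta <- instruments$y / instruments$x
  v <- instruments$sigma_y^2 / instruments$x^2
  if (second_order) {
    v <- v + instruments$y^2 * instruments$sigma_x^2 / instruments$x^4
  }
  tibble::tibble(snp_id = instruments$snp_id, theta = theta, se_theta = sqrt(v))
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools all instruments into a single causal estimate of the outcome log odds
#' per unit increase in the exposure (log odds for binary exposures, SD for
#' continuous ones):
#' \deqn{\hat\beta = \frac{\sum_k X_k Y_k \sigma_{Y_k}^{-2}}
#'                        {\sum_k X_k^2 \sigma_{Y_k}^{-2}},\qquad
#'       se(\hat\beta) = \sqrt{\frac{1}{\sum_k X_k^2 \sigma_{Y_k}^{-2}}}}
#' which is identical to a weighted least-squares regression of \eqn{Y} on
#' \eqn{X} through the origin with weights \eqn{\sigma_Y^{-2}}, and to a
#' fixed-effect meta-analysis of the per-SNP Wald ratios with first-order SEs.
#'
#' @inheritParams wald_ratio
#' @return A one-row `mr_estimate` tibble (`method = "ivw"`).
#' @export
mr_ivw <- function(instruments) {
  check_min_instruments(instruments, 2L)
  if (any(instruments$x == 0)) stop("zero exposure effect among instruments")
  w <- instruments$sigma_y^-2
  denom <- sum(instruments$x^2 * w)
  beta <- sum(instruments$x * instruments$y * w) / denom
  se <- sqrt(1 / denom)
  new_mr_estimate("ivw", beta, se, two_sided_p(beta / se), nrow(instruments),
                  exposure_type = attr(instruments, "exposure_type") %||% "binary")
}

#' Maximum-likelihood causal estimate under a bivariate-normal model
#'
#' Models each instrument's observed pair \eqn{(X_k, Y_k)} as bivariate normal
#' with mean \eqn{(\xi_k, \beta\xi_k)}, marginal SDs equal to the reported
#' standard errors and error correlation `rho` (0 for non-overlapping samples).
#' The per-SNP nuisance means \eqn{\xi_k} are profiled out analytically and the
#' causal slope is found by one-dimensional optimisation of the profile
#' likelihood; the standard error comes from the observed information (the
#' full \eqn{(\beta,\xi)} Hessian of the negative log-likelihood at the
#' optimum, inverted by Schur complement).
#'
#' @inheritParams wald_ratio
#' @param rho Correlation between the errors of the exposure and outcome
#'   associations, in (-1, 1); default 0.
#' @return A one-row `mr_estimate` tibble (`method = "mle"`).
#' @export
mr_mle <- function(instruments, rho = 0) {
  check_min_instruments(instruments, 2L)
  stopifnot(length(rho) == 1L, rho > -1, rho < 1)
  x <- instruments$x; y <- instruments$y
  sx <- instruments$sigma_x; sy <- instruments$sigma_y
  cc <- 1 / (1 - rho^2)

  # profiling the nuisance means xi_k analytically leaves the Mahalanobis
  # distance of (x, y) from the line (xi, b xi): numerically stable even for
  # vanishing exposure uncertainty
  profile_nll <- function(b) {
    sum((y - b * x)^2 / (sy^2 - 2 * rho * b * sx * sy + b^2 * sx^2)) / 2
  }
  b0 <- mr_ivw(instruments)$beta
  half_width <- max(10, 200 * sqrt(1 / sum(x^2 / sy^2)))
  opt <- stats::optimize(profile_nll, c(b0 - half_width, b0 + half_width),
                         tol = 1e-10)
  beta <- opt$minimum
  if (min(abs(beta - (b0 + c(-1, 1) * half_width))) < 1e-6) {
    stop("MLE did not converge in the interior of the search interval ",
         sprintf("[%.3g, %.3g]; objective %.6g", b0 - half_width,
                 b0 + half_width, opt$objective))
  }

  # observed information: H = c * [[sum(xi^2/sy^2), B'], [B, diag(A)]]
  a <- 1 / sx^2 - 2 * rho * beta / (sx * sy) + beta^2 / sy^2
  xi <- (x / sx^2 - rho * (y + beta * x) / (sx * sy) + beta * y / sy^2) / a
  b_cross <- rho * (x - 2 * xi) / (sx * sy) - (y - 2 * beta * xi) / sy^2
  info <- cc * (sum(xi^2 / sy^2) - sum(b_cross^2 / a))
  if (info <= 0) stop("observed information not positive definite at the MLE")
  se <- sqrt(1 / info)
  new_mr_estimate("mle", beta, se, two_sided_p(beta / se), nrow(instruments),
                  exposure_type = attr(instruments, "exposure_type") %||% "binary")
}

#' Sensitivity of the MLE to the error correlation assumption
#'
#' Re-fits [mr_mle()] over a grid of error correlations, relaxing the default
#' assumption that the exposure and outcome summary statistics come from
#' non-overlapping samples.
#'
#' @inheritParams mr_mle
#' @param rho_grid Numeric vector of correlations in (-1, 1).
#' @return Tibble ordered by `rho` with columns `rho`, `beta_hat`, `se`,
#'   `p_value`.
#' @export
rho_sensitivity <- function(instruments, rho_grid = seq(-0.2, 0.2, by = 0.01)) {
  if (!length(rho_grid)) stop("rho_grid must be non-empty")
  rho_grid <- sort(rho_grid)
  rows <- lapply(rho_grid, function(r) {
    est <- mr_mle(instruments, rho = r)
    tibble::tibble(rho = r, beta_hat = est$beta, se = est$se,
                   p_value = est$p_value)
  })
  dplyr::bind_rows(rows)
}

# interpolated weighted 50th percentile of ordered ratios
weighted_percentile <- function(theta, weights, prob = 0.5) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  stats::approx(cum, theta, xout = prob, rule = 2)$y
}

#' Weighted-median causal estimate
#'
#' The estimate is the inverse-variance-weighted median of the per-SNP Wald
#' ratios: ratios are ordered, their normalised weights cumulated, and the 50th
#' weight percentile found by linear interpolation. It is consistent when at
#' least half the weight comes from valid instruments. The standard error is a
#' parametric bootstrap: `(X_k, Y_k)` pairs are resampled from normal
#' distributions centred on the observed values with the reported SEs and the
#' estimator recomputed.
#'
#' @inheritParams wald_ratio
#' @param n_boot Bootstrap replicates for the SE, default 10000.
#' @param seed Seed for the bootstrap, default 1.
#' @return A one-row `mr_estimate` tibble (`method = "wme"`). The point
#'   estimate is deterministic; `se` and `p_value` are bootstrap-based.
#' @export
mr_weighted_median <- function(instruments, n_boot = 10000, seed = 1) {
  check_min_instruments(instruments, 3L)
  point <- function(x, y, sy) {
    weighted_percentile(y / x, x^2 / sy^2)
  }
  beta <- point(instruments$x, instruments$y, instruments$sigma_y)
  se <- bootstrap_se(instruments, point, n_boot, seed)
  new_mr_estimate("wme", beta, se, two_sided_p(beta / se), nrow(instruments),
                  exposure_type = attr(instruments, "exposure_type") %||% "binary")
}

mbe_bandwidth <- function(theta) {
  # modified Silverman rule-of-thumb on the ratio estimates
  0.9 * min(stats::sd(theta), stats::mad(theta)) / length(theta)^(1 / 5)
}

mbe_point <- function(theta, se_theta, phi, grid_n = 2048) {
  h <- phi * mbe_bandwidth(theta)
  if (!is.finite(h) || h <= 0) return(theta[1])  # all ratios identical
  w <- se_theta^-2
  w <- w / sum(w)
  grid <- seq(min(theta) - 4 * h, max(theta) + 4 * h, length.out = grid_n)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, theta, h)), 0)
  grid[which.max(dens)]
}

#' Mode-based causal estimate
#'
#' The estimate is the mode (argmax) of an inverse-variance-weighted
#' normal-kernel density of the per-SNP Wald ratios, with bandwidth equal to
#' `phi` times a modified Silverman rule-of-thumb
#' `0.9 min(sd, mad) K^(-1/5)`. It is consistent when the largest group of
#' instruments sharing the same causal ratio is valid. SE by parametric
#' bootstrap, as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier, default 1.
#' @return A one-row `mr_estimate` tibble (`method = "mbe"`).
#' @export
mr_mode <- function(instruments, phi = 1, n_boot = 10000, seed = 1) {
  check_min_instruments(instruments, 3L)
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0) {
    stop("phi must be a positive scalar")
  }
  point <- function(x, y, sy) mbe_point(y / x, sy / abs(x), phi)
  beta <- point(instruments$x, instruments$y, instruments$sigma_y)
  se <- bootstrap_se(instruments, point, n_boot, seed)
  new_mr_estimate("mbe", beta, se, two_sided_p(beta / se), nrow(instruments),
                  exposure_type = attr(instruments, "exposure_type") %||% "binary")
}

bootstrap_se <- function(instruments, point_fun, n_boot, seed) {
  if (n_boot < 2) return(NA_real_)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k <- nrow(instruments)
  est <- vapply(seq_len(n_boot), function(i) {
    xs <- stats::rnorm(k, instruments$x, instruments$sigma_x)
    ys <- stats::rnorm(k, instruments$y, instruments$sigma_y)
    ok <- xs != 0
    point_fun(xs[ok], ys[ok], instruments$sigma_y[ok])
  }, 0)
  stats::sd(est)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with a free intercept and weights `sigma_y^-2`, after orienting every
#' instrument so its exposure effect is positive. The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional (unbalanced horizontal) pleiotropy per instrument, zero under
#' the InSIDE assumption when pleiotropy is balanced. Standard errors come
#' from the weighted regression; p-values use the t distribution with K-2
#' degrees of freedom by default (regression convention) or the normal when
#' `p_dist = "normal"`.
#'
#' @inheritParams wald_ratio
#' @param p_dist `"t"` (default) or `"normal"` reference distribution for
#'   p-values and CIs.
#' @return A two-row `mr_estimate` tibble: methods `egger_slope` and
#'   `egger_intercept`.
#' @export
mr_egger <- function(instruments, p_dist = c("t", "normal")) {
  p_dist <- match.arg(p_dist)
  check_min_instruments(instruments, 3L)
  s <- sign(instruments$x)
  x <- instruments$x * s
  y <- instruments$y * s
  if (stats::var(x) == 0) stop("no variation in exposure effects after orientation")
  fit <- stats::lm(y ~ x, weights = instruments$sigma_y^-2)
  co <- summary(fit)$coefficients
  k <- nrow(instruments)
  if (p_dist == "t") {
    p <- 2 * stats::pt(-abs(co[, "Estimate"] / co[, "Std. Error"]), df = k - 2)
    q <- stats::qt(0.975, df = k - 2)
  } else {
    p <- 2 * stats::pnorm(-abs(co[, "Estimate"] / co[, "Std. Error"]))
    q <- stats::qnorm(0.975)
  }
  etype <- attr(instruments, "exposure_type") %||% "binary"
  dplyr::bind_rows(
    new_mr_estimate("egger_slope", co["x", 1], co["x", 2], p["x"], k,
                    ci_quantile = q, exposure_type = etype),
    new_mr_estimate("egger_intercept", co["(Intercept)", 1],
                    co["(Intercept)", 2], p["(Intercept)"], k,
                    ci_quantile = q, exposure_type = etype)
  )
}

#' Convert a causal estimate to the per-doubling odds-ratio scale
#'
#' For a binary exposure the raw estimate is the outcome log OR per unit
#' increase in the log odds of the exposure; multiplying by ln 2 re-expresses
#' it per doubling in odds of the exposure, which is then exponentiated to an
#' OR. Standard errors and CI bounds scale by the same factor. Continuous
#' exposures (IgE, per SD) are exponentiated without rescaling, and the
#' `egger_intercept` row is never converted (it is a log-odds per instrument,
#' not a causal slope).
#'
#' @param estimate An `mr_estimate` tibble (one or more rows).
#' @param exposure_type Override for the exposure type recorded on the
#'   estimate.
#' @return The estimate with added columns `or`, `or_ci_lower`, `or_ci_upper`
#'   (per doubling for binary exposures).
#' @export
per_doubling <- function(estimate, exposure_type = NULL) {
  etype <- exposure_type %||% attr(estimate, "exposure_type") %||% "binary"
  fac <- ifelse(estimate$method == "egger_intercept", NA_real_,
                if (etype == "binary") log(2) else 1)
  estimate$or <- exp(estimate$beta * fac)
  estimate$or_ci_lower <- exp(estimate$ci_lower * fac)
  estimate$or_ci_upper <- exp(estimate$ci_upper * fac)
  estimate
}

check_min_instruments <- function(instruments, k) {
  if (is.null(nrow(instruments)) || nrow(instruments) < k) {
    stop("at least ", k, " instruments required")
  }
  invisible(instruments)
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Significance tiers used for reporting
#'
#' Mirrors the analysis' multiple-testing ledger: 0.05 nominal evidence for a
#' potential association, 0.0125 Bonferroni-corrected for four traits
#' (significant), and 0.00625 for subtype scans over two outcomes.
#'
#' @param p P-value(s).
#' @param thresholds Named vector of tier cutpoints.
#' @return Character vector: `"none"`, `"potential"` or `"significant"`.
#' @export
significance_tier <- function(p, thresholds = c(potential = 0.05, significant = 0.0125)) {
  ifelse(p < thresholds[["significant"]], "significant",
         ifelse(p < thresholds[["potential"]], "potential", "none"))
}
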