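#' Run the full two-sample MR analysis over one or more traits
#'
#' Orchestrates, per trait: fixture (or user TSV) loading, harmonisation,
#' HEIDI-outlier screening (flagged SNPs are excluded before estimation), the
#' five causal estimators plus the MR-Egger intercept, heterogeneity
#' diagnostics before and after exclusions, per-doubling OR conversion for
#' binary exposures, and significance tiering. Deterministic given the
#' configuration and seed.
#'
#' @param traits Character vector of trait names; each must either be a
#'   packaged trait (see [atopy_traits()]) or have
#'   `<trait>_exposure.tsv` / `<trait>_glioma.tsv` files in `data_dir`.
#' @param data_dir Directory with fixture TSVs (default: packaged data).
#' @param palindromic_action Passed to [harmonise()]; the default `"trust"`
#'   assumes both sides of each fixture are printed on the same strand (they
#'   come from a single publication table), so palindromic SNPs are aligned by
#'   their allele labels rather than dropped.
#' @param heidi Run the HEIDI-outlier screen and exclude flagged SNPs?
#'   Default `TRUE`.
#' @param heidi_threshold Flagging threshold, default 0.01.
#' @param n_boot Bootstrap replicates for WME/MBE standard errors.
#' @param seed Seed for the bootstrap.
#' @param phi MBE bandwidth multiplier.
#' @param tiers Significance tiers passed to [significance_tier()].
#'
#' @return A list of class `mr_report`: `estimates` (one row per trait and
#'   method with log-scale and OR-scale results), `heterogeneity` (per trait,
#'   before and after exclusions), `heidi` (named list of [heidi_outlier()]
#'   reports), `instruments` (named list of harmonised sets after exclusion),
#'   and `config`.
#' @export
mr_pipeline <- function(traits = atopy_traits(), data_dir = NULL,
                        palindromic_action = "trust",
                        heidi = TRUE, heidi_threshold = 0.01,
                        n_boot = 10000, seed = 1, phi = 1,
                        tiers = c(potential = 0.05, significant = 0.0125)) {
  estimates <- list()
  het <- list()
  heidi_reports <- list()
  kept <- list()
  for (trait in traits) {
    sets <- load_atopy_instruments_or_dir(trait, data_dir)
    h <- harmonise(sets$exposure, sets$outcome,
                   palindromic_action = palindromic_action)
    het_all <- cochran_q(wald_ratio(h))
    excluded <- character(0)
    if (heidi && nrow(h) >= 3) {
      rep_h <- heidi_outlier(h, p_threshold = heidi_threshold)
      heidi_reports[[trait]] <- rep_h
      excluded <- rep_h$flagged
      h <- h[!h$snp_id %in% excluded, ]
    }
    het_kept <- if (nrow(h) >= 2) cochran_q(wald_ratio(h)) else
      tibble::tibble(q = NA_real_, df = NA_integer_, p_het = NA_real_,
                     i_squared = NA_real_)
    ests <- dplyr::bind_rows(
      mr_ivw(h),
      mr_mle(h),
      if (nrow(h) >= 3) mr_weighted_median(h, n_boot = n_boot, seed = seed),
      if (nrow(h) >= 3) mr_mode(h, phi = phi, n_boot = n_boot, seed = seed),
      if (nrow(h) >= 3) mr_egger(h)
    )
    attr(ests, "exposure_type") <- attr(h, "exposure_type")
    ests <- per_doubling(ests)
    ests$trait <- trait
    ests$exposure_type <- attr(h, "exposure_type")
    ests$tier <- significance_tier(ests$p_value, tiers)
    ests$excluded_snps <- paste(excluded, collapse = ",")
    estimates[[trait]] <- ests
    het[[trait]] <- dplyr::bind_rows(
      cbind(tibble::tibble(trait = trait, stage = "all_instruments"), het_all),
      cbind(tibble::tibble(trait = trait, stage = "after_exclusions"), het_kept)
    )
    kept[[trait]] <- h
  }
  structure(list(
    estimates = dplyr::bind_rows(estimates),
    heterogeneity = dplyr::bind_rows(het),
    heidi = heidi_reports,
    instruments = kept,
    config = list(traits = traits, palindromic_action = palindromic_action,
                  heidi = heidi,
                  heidi_threshold = heidi_threshold, n_boot = n_boot,
                  seed = seed, phi = phi, tiers = tiers)
  ), class = "mr_report")
}

load_atopy_instruments_or_dir <- function(trait, data_dir) {
  if (is.null(data_dir) && trait %in% atopy_traits()) {
    return(load_atopy_instruments(trait))
  }
  if (is.null(data_dir)) stop("unknown trait: ", trait)
  load_atopy_instruments(trait, dir = data_dir)
}

#' @export
print.mr_report <- function(x, digits = 3, ...) {
  cat("Two-sample MR report:", paste(x$config$traits, collapse = ", "), "\n\n")
  est <- x$estimates
  est$or_fmt <- sprintf("%.2f (%.2f-%.2f)", est$or, est$or_ci_lower, est$or_ci_upper)
  est$or_fmt[est$method == "egger_intercept"] <-
    sprintf("%.3f (%.3f-%.3f)",
            est$beta[est$method == "egger_intercept"],
            est$ci_lower[est$method == "egger_intercept"],
            est$ci_upper[est$method == "egger_intercept"])
  print(as.data.frame(est[, c("trait", "method", "n_snps", "or_fmt", "p_value", "tier")]),
        digits = digits, row.names = FALSE)
  cat("\nHeterogeneity (Cochran's Q on Wald ratios):\n")
  hh <- as.data.frame(x$heterogeneity)
  hh$i_squared_pct <- round(100 * hh$i_squared)
  print(hh, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to TSV and JSON
#'
#' Writes `estimates.tsv`, `heterogeneity.tsv`, `heidi_<trait>.tsv` and a
#' combined `report.json` under `dir`. Regenerating from the same
#' configuration is byte-identical.
#'
#' @param report An [mr_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(d, name) {
    utils::write.table(d, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(report$estimates, "estimates.tsv")
  write_tsv(report$heterogeneity, "heterogeneity.tsv")
  for (trait in names(report$heidi)) {
    write_tsv(report$heidi[[trait]]$table, sprintf("heidi_%s.tsv", trait))
  }
  json <- list(estimates = report$estimates,
               heterogeneity = report$heterogeneity,
               heidi_flagged = lapply(report$heidi, `[[`, "flagged"),
               config = report$config)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Forest plot of per-SNP Wald odds ratios with the pooled IVW estimate
#'
#' Per-SNP ORs and 95% CIs are ordered by effect magnitude, with the pooled
#' inverse-variance-weighted estimate appended as a diamond. For binary
#' exposures pass per-doubling-scale values consistently for ratios and pooled
#' estimate.
#'
#' @param ratios A [wald_ratio()] tibble.
#' @param pooled A one-row `mr_estimate` (usually [mr_ivw()]).
#' @param scale Multiplier applied to log-scale estimates before
#'   exponentiating (use `log(2)` for per-doubling display), default 1.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_forest <- function(ratios, pooled, scale = 1, title = NULL) {
  if (!nrow(ratios)) stop("no ratios to plot")
  z <- stats::qnorm(0.975)
  d <- tibble::tibble(
    label = ratios$snp_id,
    or = exp(ratios$theta * scale),
    lo = exp((ratios$theta - z * ratios$se_theta) * scale),
    hi = exp((ratios$theta + z * ratios$se_theta) * scale),
    pooled = FALSE
  )
  d <- d[order(d$or), ]
  d <- rbind(d, tibble::tibble(label = "Pooled (IVW)",
                               or = exp(pooled$beta * scale),
                               lo = exp(pooled$ci_lower * scale),
                               hi = exp(pooled$ci_upper * scale),
                               pooled = TRUE))
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled, size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18), guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4), guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, title = title) +
    ggplot2::theme_bw()
}

#' Scatter plot of outcome against exposure effects with IVW and Egger fits
#'
#' One point per instrument (oriented to positive exposure effect), the
#' origin-constrained IVW line and the MR-Egger line with its free intercept;
#' a visible gap between the two lines at zero exposure effect indicates
#' directional pleiotropy.
#'
#' @param instruments A `harmonised_instruments` tibble.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(instruments, title = NULL) {
  s <- sign(instruments$x)
  d <- tibble::tibble(x = instruments$x * s, y = instruments$y * s,
                      sx = instruments$sigma_x, sy = instruments$sigma_y)
  ivw <- mr_ivw(instruments)
  egger <- mr_egger(instruments)
  z <- stats::qnorm(0.975)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - z * .data$sy,
                                        ymax = .data$y + z * .data$sy),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$x - z * .data$sx,
                                         xmax = .data$x + z * .data$sx),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = ivw$beta, intercept = 0,
                         colour = "#1b6ca8") +
    ggplot2::geom_abline(slope = egger$beta[1], intercept = egger$beta[2],
                         colour = "#c0392b", linetype = "longdash") +
    ggplot2::labs(x = "Effect on exposure (log OR or per-SD)",
                  y = "Effect on glioma (log OR)", title = title) +
    ggplot2::theme_bw()
}
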