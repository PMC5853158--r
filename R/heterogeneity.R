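#' Cochran's Q heterogeneity test across per-SNP Wald ratios
#'
#' Computes \eqn{Q = \sum_k w_k (\theta_k - \theta_{IVW})^2} with
#' \eqn{w_k = se(\theta_k)^{-2}} and \eqn{\theta_{IVW}} the inverse-variance
#' weighted mean of the ratios, referred to a chi-square distribution with
#' K-1 degrees of freedom, together with
#' \eqn{I^2 = \max(0, (Q - df)/Q)}, the proportion of variability across
#' instruments attributable to heterogeneity rather than sampling error.
#' Excess heterogeneity across instruments for the same exposure suggests
#' pleiotropic pathways.
#'
#' @param ratios Tibble of Wald ratios as returned by [wald_ratio()]
#'   (columns `theta`, `se_theta`; first-order SEs by convention, matching the
#'   forest-plot meta-analysis).
#' @return A one-row tibble: `q`, `df`, `p_het`, `i_squared` (proportion in
#'   \[0, 1\]; multiply by 100 for the conventional percentage).
#' @export
cochran_q <- function(ratios) {
  if (nrow(ratios) < 2) stop("at least 2 ratios required")
  w <- ratios$se_theta^-2
  pooled <- sum(w * ratios$theta) / sum(w)
  q <- sum(w * (ratios$theta - pooled)^2)
  df <- nrow(ratios) - 1L
  tibble::tibble(
    q = q,
    df = df,
    p_het = stats::pchisq(q, df, lower.tail = FALSE),
    i_squared = max(0, (q - df) / q)
  )
}

#' HEIDI-outlier screen for pleiotropic instruments
#'
#' Heterogeneity-in-dependent-instruments outlier test: the instrument with
#' the strongest exposure association (largest |x|/sigma_x; ties broken by
#' smaller sigma_x, then rsID) is taken as the reference, assumed valid. For
#' every other SNP the deviation of its Wald ratio from the reference ratio,
#' \eqn{d_k = \theta_k - \theta_{top}}, is tested against zero with the
#' delta-method variance \eqn{var(\theta_k) + var(\theta_{top})} (second-order,
#' including exposure-side uncertainty) on a 1-df chi-square. SNPs with
#' p below the threshold are flagged as violating the exclusion-restriction
#' assumption and should be removed before estimation.
#'
#' @inheritParams wald_ratio
#' @param p_threshold Flagging threshold, default 0.01 (the advocated value).
#' @param iterate If `TRUE`, remove the most significant flagged SNP and
#'   re-test until none remains (the reference is re-chosen each pass);
#'   default single pass.
#' @return A list of class `heidi_report`: `top_snp`, `table` (per-SNP `d`,
#'   `se_d`, `p_heidi`; `NA` for the reference), `flagged` (character vector,
#'   possibly empty), `p_threshold`.
#' @export
heidi_outlier <- function(instruments, p_threshold = 0.01, iterate = FALSE) {
  check_min_instruments(instruments, 3L)

  screen <- function(h) {
    zx <- abs(h$x) / h$sigma_x
    ord <- order(-zx, h$sigma_x, h$snp_id)
    top <- ord[1]
    theta <- h$y / h$x
    v <- h$sigma_y^2 / h$x^2 + h$y^2 * h$sigma_x^2 / h$x^4
    d <- theta - theta[top]
    vd <- v + v[top]
    p <- stats::pchisq(d^2 / vd, df = 1, lower.tail = FALSE)
    p[top] <- NA_real_
    tibble::tibble(snp_id = h$snp_id, d = d, se_d = sqrt(vd), p_heidi = p,
                   reference = seq_len(nrow(h)) == top)
  }

  h <- instruments
  flagged <- character(0)
  repeat {
    tab <- screen(h)
    hits <- tab$snp_id[!is.na(tab$p_heidi) & tab$p_heidi < p_threshold]
    if (!iterate || !length(hits)) break
    worst <- tab$snp_id[which.min(tab$p_heidi)]
    flagged <- c(flagged, worst)
    h <- h[h$snp_id != worst, ]
    if (nrow(h) < 3) break
  }
  if (!iterate) flagged <- tab$snp_id[!is.na(tab$p_heidi) & tab$p_heidi < p_threshold]

  structure(list(top_snp = tab$snp_id[tab$reference][1],
                 table = tab,
                 flagged = flagged,
                 p_threshold = p_threshold),
            class = "heidi_report")
}

#' @export
print.heidi_report <- function(x, ...) {
  cat("HEIDI-outlier screen (reference instrument:", x$top_snp, ")\n")
  cat("threshold p <", x$p_threshold, "\n")
  if (length(x$flagged)) {
    cat("flagged:", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("no instrument flagged\n")
  }
  invisible(x)
}
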