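strand_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) a1 == strand_complement(a2)

#' Harmonise exposure and outcome summary statistics to a common effect allele
#'
#' Aligns per-SNP outcome effects to the exposure effect allele: if the outcome
#' effect was reported for the exposure's other allele (directly or after
#' strand complementation), its sign is flipped. Palindromic SNPs (A/T, C/G),
#' for which allele labels cannot distinguish strands, are resolved by
#' comparing effect-allele frequencies; when either frequency is missing or
#' both lie within `freq_tolerance` of 0.5 the SNP is flagged as unresolvable
#' and dropped (with a warning).
#'
#' Harmonisation is idempotent: applying it to an already-aligned pair returns
#' the data unchanged with `flipped = FALSE`.
#'
#' @param exposure,outcome Instrument sets (see [instrument_set()]) sharing
#'   `snp_id` values; rows are matched by `snp_id`.
#' @param freq_tolerance Half-width of the allele-frequency ambiguity zone
#'   around 0.5 used for palindromic SNPs, default 0.08 (reject when both
#'   frequencies fall in \[0.42, 0.58\]).
#' @param palindromic_action `"resolve"` (default): resolve palindromic SNPs
#'   by allele frequency and drop unresolvable ones; `"trust"`: assume both
#'   datasets report alleles on the same strand and align palindromic SNPs by
#'   their labels (appropriate when both tables come from one publication, as
#'   the packaged fixtures do); `"drop"`: remove all palindromic SNPs.
#'
#' @return A tibble of class `harmonised_instruments` with columns `snp_id`,
#'   `x`, `sigma_x` (exposure effect and SE), `y`, `sigma_y` (outcome effect
#'   and SE), `flipped`, `palindromic`. Attributes carry the trait name and
#'   exposure type; dropped SNPs are recorded in attribute `rejected`.
#' @export
harmonise <- function(exposure, outcome, freq_tolerance = 0.08,
                      palindromic_action = c("resolve", "trust", "drop")) {
  palindromic_action <- match.arg(palindromic_action)
  common <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(common)) stop("no shared snp_id between exposure and outcome")
  e <- exposure[match(common, exposure$snp_id), ]
  o <- outcome[match(common, outcome$snp_id), ]
  e_eaf <- if ("eaf" %in% names(e)) e$eaf else rep(NA_real_, nrow(e))
  o_eaf <- if ("eaf" %in% names(o)) o$eaf else rep(NA_real_, nrow(o))

  n <- length(common)
  flipped <- logical(n)
  palindromic <- logical(n)
  keep <- rep(TRUE, n)
  y <- o$beta

  for (k in seq_len(n)) {
    ea <- e$effect_allele[k]; oa <- e$other_allele[k]
    oe <- o$effect_allele[k]; oo <- o$other_allele[k]
    if (is_palindromic(ea, oa)) {
      palindromic[k] <- TRUE
      if (!setequal(c(oe, oo), c(ea, oa))) {
        stop("incompatible alleles for palindromic SNP ", common[k])
      }
      if (palindromic_action == "drop") {
        keep[k] <- FALSE
        next
      }
      if (palindromic_action == "trust") {
        if (oe == oa) {
          y[k] <- -y[k]
          flipped[k] <- TRUE
        }
        next
      }
      ambiguous <- is.na(e_eaf[k]) || is.na(o_eaf[k]) ||
        (abs(e_eaf[k] - 0.5) <= freq_tolerance && abs(o_eaf[k] - 0.5) <= freq_tolerance)
      if (ambiguous) {
        keep[k] <- FALSE
        next
      }
      # frequency of the allele the outcome effect is attached to, versus the
      # exposure effect allele: same side of 0.5 means same allele
      f_out <- if (oe == ea) o_eaf[k] else 1 - o_eaf[k]
      if (abs(e_eaf[k] - f_out) > abs(e_eaf[k] - (1 - f_out))) {
        y[k] <- -y[k]
        flipped[k] <- TRUE
      }
    } else {
      aligned <- if (setequal(c(oe, oo), c(ea, oa))) {
        c(oe, oo)
      } else if (setequal(strand_complement(c(oe, oo)), c(ea, oa))) {
        strand_complement(c(oe, oo))
      } else {
        stop("incompatible allele sets for SNP ", common[k],
             " (", ea, "/", oa, " vs ", oe, "/", oo, ")")
      }
      if (aligned[1] == oa) {
        y[k] <- -y[k]
        flipped[k] <- TRUE
      }
    }
  }

  out <- tibble::tibble(
    snp_id = common,
    x = e$beta, sigma_x = e$se,
    y = y, sigma_y = o$se,
    flipped = flipped, palindromic = palindromic
  )[keep, ]
  if (any(!keep)) {
    warning("dropped palindromic SNP(s): ",
            paste(common[!keep], collapse = ", "))
  }
  structure(out,
            class = c("harmonised_instruments", class(out)),
            trait_name = attr(exposure, "trait_name"),
            exposure_type = attr(exposure, "exposure_type") %||% "binary",
            rejected = common[!keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prune correlated instruments to an approximately independent set
#'
#' Greedy pruning at an LD threshold: variants are visited in decreasing order
#' of exposure association strength (|beta|/se); each retained variant removes
#' all others correlated with it at `r2 >= threshold`. Within each correlated
#' cluster only the most strongly associated SNP survives, and no retained pair
#' exceeds the threshold. The result does not depend on the input row order.
#'
#' @param set An [instrument_set()].
#' @param r2 Symmetric matrix of pairwise LD r² with unit diagonal, with
#'   dimnames covering the set's `snp_id`s.
#' @param threshold Pruning threshold, default 0.001 (only effectively
#'   independent variants are kept).
#'
#' @return The pruned instrument set.
#' @export
ld_prune <- function(set, r2, threshold = 0.001) {
  ids <- set$snp_id
  if (is.null(rownames(r2)) || is.null(colnames(r2)) ||
      !all(ids %in% rownames(r2)) || !all(ids %in% colnames(r2))) {
    stop("r2 matrix must be named and cover every snp_id")
  }
  r2 <- r2[ids, ids, drop = FALSE]
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("r2 matrix must be symmetric")
  if (any(is.na(r2))) stop("r2 matrix has missing entries")
  z <- abs(set$beta) / set$se
  # deterministic order: strength desc, then snp_id for ties
  ord <- order(-z, ids)
  keep <- logical(length(ids))
  removed <- logical(length(ids))
  for (k in ord) {
    if (removed[k]) next
    keep[k] <- TRUE
    removed <- removed | (r2[, k] >= threshold)
  }
  pruned <- set[keep, ]
  structure(pruned, class = class(set),
            trait_name = attr(set, "trait_name"),
            exposure_type = attr(set, "exposure_type"),
            provenance = attr(set, "provenance"))
}

#' Read a square LD r-squared matrix from TSV
#'
#' Expects a header row of rsIDs and a leading rsID column.
#' @param path File path.
#' @return Numeric matrix with rsID dimnames.
#' @export
read_ld_matrix <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", row.names = 1,
                         check.names = FALSE)
  as.matrix(d)
}
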