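#' Convert an odds ratio with confidence interval to log scale
#'
#' Recovers the log odds ratio and its standard error from a point estimate
#' and a symmetric (on the log scale) confidence interval, the form in which
#' GWAS catalogues and published tables usually report per-allele effects.
#'
#' @param or_point Odds ratio point estimate (> 0). Vectorised.
#' @param ci_lower,ci_upper Confidence interval bounds (> 0), with
#'   `ci_lower <= or_point <= ci_upper`.
#' @param level Confidence level of the interval, default 0.95.
#'
#' @return A list with components `beta` (log OR) and `se` (standard error of
#'   `beta`, computed as the log CI width divided by twice the exact normal
#'   quantile, 1.959964 at the 0.95 level).
#'
#' @examples
#' parse_or_ci(1.24, 1.16, 1.32)
#' @export
parse_or_ci <- function(or_point, ci_lower, ci_upper, level = 0.95) {
  stopifnot(is.numeric(or_point), is.numeric(ci_lower), is.numeric(ci_upper),
            length(level) == 1L, level > 0, level < 1)
  if (any(or_point <= 0 | ci_lower <= 0 | ci_upper <= 0)) {
    stop("odds ratios and confidence bounds must be positive")
  }
  if (any(ci_lower > or_point | or_point > ci_upper)) {
    stop("point estimate must lie inside its confidence interval")
  }
  if (any(ci_lower == ci_upper)) {
    stop("degenerate confidence interval (zero width)")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(beta = log(or_point), se = (log(ci_upper) - log(ci_lower)) / (2 * z))
}

#' Construct an instrument set from a table of variant associations
#'
#' An instrument set is a tibble of per-SNP summary associations for one trait,
#' one row per variant, carrying `trait_name`, `exposure_type` and `provenance`
#' as attributes. Effect sizes are stored as `beta` (log OR for binary traits,
#' per-SD effect for continuous ones) with standard error `se`.
#'
#' @param data Data frame with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`; optionally `region`, `position`, `eaf`, `p_value`.
#' @param trait_name Trait label.
#' @param exposure_type `"binary"` or `"continuous"`.
#' @param provenance Free-text source label.
#'
#' @return A tibble of class `instrument_set`.
#' @export
instrument_set <- function(data, trait_name, exposure_type = c("binary", "continuous"),
                           provenance = "") {
  exposure_type <- match.arg(exposure_type)
  data <- tibble::as_tibble(data)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(data$snp_id)) stop("duplicated snp_id in instrument set")
  bases <- c("A", "C", "G", "T")
  if (!all(data$effect_allele %in% bases) || !all(data$other_allele %in% bases)) {
    stop("alleles must be one of A/C/G/T")
  }
  if (any(data$effect_allele == data$other_allele)) {
    stop("effect_allele must differ from other_allele")
  }
  if (any(!is.finite(data$se) | data$se <= 0)) stop("se must be positive")
  if ("eaf" %in% names(data) &&
      any(!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1))) {
    stop("eaf must lie in (0, 1)")
  }
  if (!"p_value" %in% names(data)) {
    data$p_value <- 2 * stats::pnorm(-abs(data$beta / data$se))
  }
  structure(data,
            class = c("instrument_set", class(data)),
            trait_name = trait_name,
            exposure_type = exposure_type,
            provenance = provenance)
}

#' Read per-SNP summary associations from a TSV file
#'
#' Accepts either `or`/`ci_lower`/`ci_upper` columns (converted on load through
#' [parse_or_ci()], so the conversion code is exercised on every read) or
#' pre-computed `beta`/`se` columns. Lines starting with `#` are comments.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams instrument_set
#' @return A tibble of class `instrument_set`.
#' @export
read_associations <- function(path, trait_name = basename(path),
                              exposure_type = "binary", provenance = path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (all(c("or", "ci_lower", "ci_upper") %in% names(d))) {
    conv <- parse_or_ci(d$or, d$ci_lower, d$ci_upper)
    d$beta <- conv$beta
    d$se <- conv$se
  } else if (!all(c("beta", "se") %in% names(d))) {
    stop("file must provide either or/ci_lower/ci_upper or beta/se columns: ", path)
  }
  instrument_set(d, trait_name = trait_name, exposure_type = exposure_type,
                 provenance = provenance)
}

#' Names of the packaged atopy-related trait instrument sets
#' @return Character vector of trait identifiers.
#' @export
atopy_traits <- function() {
  c("atopic_dermatitis", "asthma_hayfever", "ige", "self_reported_allergy")
}

#' Exposure type of a packaged trait
#' @param trait_name One of [atopy_traits()].
#' @return `"binary"` or `"continuous"` (IgE level is a per-SD continuous trait).
#' @export
atopy_exposure_type <- function(trait_name) {
  trait_name <- match.arg(trait_name, atopy_traits())
  if (trait_name == "ige") "continuous" else "binary"
}

#' Load a packaged atopy-trait instrument set and its glioma associations
#'
#' The package ships, as plain-text fixtures, the per-SNP associations of the
#' LD-pruned instruments for four atopy-related traits together with their
#' associations with all glioma (12,488 cases / 18,169 controls). Betas and
#' standard errors are recomputed from the stored OR/CI columns on every load.
#'
#' @param trait_name One of `"atopic_dermatitis"` (18 SNPs),
#'   `"asthma_hayfever"` (9), `"ige"` (5) or `"self_reported_allergy"` (14).
#' @param dir Directory holding the fixture TSVs; defaults to the package's
#'   `extdata` directory.
#'
#' @return A list with `exposure` and `outcome` instrument sets.
#' @export
load_atopy_instruments <- function(trait_name, dir = NULL) {
  trait_name <- match.arg(trait_name, atopy_traits())
  if (is.null(dir)) dir <- system.file("extdata", package = "atopymr")
  etype <- atopy_exposure_type(trait_name)
  read_one <- function(side) {
    path <- file.path(dir, sprintf("%s_%s.tsv", trait_name, side))
    if (!file.exists(path)) stop("fixture not found: ", path)
    read_associations(path,
                      trait_name = if (side == "glioma") "glioma" else trait_name,
                      exposure_type = if (side == "glioma") "binary" else etype,
                      provenance = path)
  }
  list(exposure = read_one("exposure"), outcome = read_one("glioma"))
}

#' Pool of per-allele exposure odds ratios used by the simulation defaults
#'
#' Returns the printed per-allele exposure ORs of the packaged instrument sets;
#' the simulation samples its per-variant effect sizes `w` from this pool so
#' that simulated instrument strengths match the real ones.
#'
#' @param trait_name A packaged trait, or `"all"` to pool every binary trait.
#' @return Numeric vector of ORs (> 1).
#' @export
atopy_or_pool <- function(trait_name = "atopic_dermatitis") {
  traits <- if (identical(trait_name, "all")) {
    setdiff(atopy_traits(), "ige")
  } else {
    match.arg(trait_name, atopy_traits())
  }
  unlist(lapply(traits, function(tr) {
    exp(load_atopy_instruments(tr)$exposure$beta)
  }), use.names = FALSE)
}
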