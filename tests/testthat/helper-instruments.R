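# build a harmonised instrument tibble directly (synthetic data helpers)
make_harmonised <- function(x, y, sigma_x, sigma_y,
                            snp_id = paste0("rs", seq_along(x)),
                            exposure_type = "binary") {
  structure(
    tibble::tibble(snp_id = snp_id, x = x, sigma_x = sigma_x,
                   y = y, sigma_y = sigma_y,
                   flipped = FALSE, palindromic = FALSE),
    class = c("harmonised_instruments", "tbl_df", "tbl", "data.frame"),
    exposure_type = exposure_type
  )
}

# harmonised fixture for a packaged trait, optionally excluding SNPs
fixture_harmonised <- function(trait, exclude = character(0)) {
  sets <- load_atopy_instruments(trait)
  h <- harmonise(sets$exposure, sets$outcome, palindromic_action = "trust")
  h[!h$snp_id %in% exclude, ]
}

# random instruments around a true causal slope, independent normal noise
random_instruments <- function(k, beta, sigma_x = 0.02, sigma_y = 0.05,
                               x_range = c(0.1, 0.5)) {
  x_true <- stats::runif(k, x_range[1], x_range[2])
  make_harmonised(
    x = x_true + stats::rnorm(k, 0, sigma_x),
    y = beta * x_true + stats::rnorm(k, 0, sigma_y),
    sigma_x = rep(sigma_x, k),
    sigma_y = rep(sigma_y, k)
  )
}

make_assoc_set <- function(df, trait = "toy", exposure_type = "binary") {
  instrument_set(df, trait_name = trait, exposure_type = exposure_type)
}
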