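#!/usr/bin/env Rscript
# End-to-end synthetic study: emulate a 13-case micro-PIV flow sweep of a
# shear-thinning solution (truth n = 0.883, K = 1, slip ~ 1/3 of the mean
# velocity, 2% relative noise averaged over 60 replicates), run the full
# inference (cosh fit -> normalization -> power-law profile fit ->
# differential viscometry -> overall power law), then predict each case with
# the slit forward model and compare against the synthetic measurements with
# a 99% confidence band.

suppressPackageStartupMessages(library(microvisc))

seed <- 7
out_dir <- "results/02_synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- pipeline_config(
  fluid = power_law_fluid(K = 1.0, n = 0.883),
  noise = noise_model(sigma_rel = 0.02, n_rep = 60, seed = seed),
  n_cases = 13, shear_range = c(8, 132), slip_fraction = 0.33,
  forward_model = "slit", seed = seed, out_dir = out_dir)
report <- run_pipeline(cfg)

write_profiles(report$profiles, file.path(out_dir, "profiles.csv"))

cat(sprintf("Recovered overall index n = %.4f (truth 0.883)\n",
            report$model$n))
cat(sprintf("Per-case index range: %.3f - %.3f\n",
            min(report$summary$n), max(report$summary$n)))
cat(sprintf("99%% CI coverage of the forward predictions: %.2f - %.2f\n",
            min(report$summary$ci_coverage),
            max(report$summary$ci_coverage)))
cat(sprintf("Line mean/max velocity ratio: %.3f - %.3f (blunter than the\n",
            min(report$summary$mean_over_max),
            max(report$summary$mean_over_max)))
cat("  Newtonian 0.687, the shear-thinning + slip signature)\n")
cat("wrote", out_dir, "\n")
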