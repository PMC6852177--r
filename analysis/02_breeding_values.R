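#!/usr/bin/env Rscript
# Stage 2: per-ring joint-site REML and family breeding values.
#
# Fits Y = mu + site + block(site) + family + site:family + e at every
# cambial age with site-specific residual variances and stacks the family
# BLUPs into EBV trajectories.

suppressMessages(library(ringwas))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

rings <- read_rings("results/data/rings.tsv")
ebvs <- ebv_trajectories(rings, traits = "WD")
write_tsv(ebvs, "results/ebv.tsv", seed = seed)

for (rg in c(1, 7, 14)) {
  fit <- fit_ring_model(rings, "WD", rg)
  vc <- fit$varcomp
  cat(sprintf(
    "ring %2d: sigma_f2 = %.1f, sigma_sf2 = %.1f, sigma_e2 = %s, h2_fam = %.2f\n",
    rg, vc$sigma_f2, vc$sigma_sf2,
    paste(sprintf("%.1f", vc$sigma_e2), collapse = "/"),
    vc$sigma_f2 / (vc$sigma_f2 + vc$sigma_sf2 + mean(vc$sigma_e2))))
}
cat(sprintf("EBV table: %d families x %d rings\n",
            length(unique(ebvs$family)), length(unique(ebvs$ring))))
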