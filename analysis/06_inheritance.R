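#!/usr/bin/env Rscript
# Stage 6: mode of inheritance of the called QTLs.
#
# Genotype-class means of the matching latent trait give 2a = |G_BB - G_bb|
# and d = G_Bb - (G_BB + G_bb)/2; |d/a| <= 0.5 is additive, up to 1.25
# partial-to-full dominance, beyond that over/underdominance.

suppressMessages(library(ringwas))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

geno <- read_vcf("results/data/genotypes.vcf")
latent <- read.delim("results/latent.tsv", comment.char = "#")
qtls <- read.delim("results/qtls.tsv", comment.char = "#")
if (!nrow(qtls)) {
  cat("no QTLs to classify\n")
  quit(status = 0)
}

lat_col <- c(intercept = "beta0", slope = "beta1",
             beta2 = "beta2", beta3 = "beta3")
recs <- do.call(rbind, lapply(seq_len(nrow(qtls)), function(i) {
  ph <- data.frame(individual = latent$individual,
                   WD = latent[[lat_col[[qtls$Latent_trait[i]]]]])
  inheritance_records(data.frame(snp_id = qtls$SNP[i], trait = "WD"),
                      geno, ph)
}))
recs$latent_trait <- qtls$Latent_trait
write_inheritance_table(recs, "results/inheritance.tsv", seed = seed)

for (i in seq_len(nrow(recs)))
  with(recs[i, ], cat(sprintf(
    "%s (%s): 2a = %.3f, d = %.3f, d/a = %.2f -> %s\n",
    snp_id, latent_trait, two_a, d, d_over_a, class)))
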