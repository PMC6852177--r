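test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_rings = 0), "n_rings")
  expect_error(sim_config(n_individuals = 100, n_families = 80), "n_families")
})

test_that("genotype simulation is deterministic and respects the missing rate", {
  cfg <- sim_config(n_individuals = 60, n_contigs = 10, snps_per_contig = 5,
                    missing_rate = 0, seed = 11)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_false(anyNA(g1$dosage))
  expect_true(all(g1$dosage %in% 0:2))

  cfgm <- sim_config(n_individuals = 200, n_contigs = 20, snps_per_contig = 5,
                     missing_rate = 0.1, seed = 12)
  gm <- simulate_genotypes(cfgm)
  expect_gt(mean(is.na(gm$dosage)), 0.07)
  expect_lt(mean(is.na(gm$dosage)), 0.13)

  expect_warning(simulate_genotypes(
    sim_config(n_individuals = 10, n_contigs = 3, snps_per_contig = 1,
               seed = 1)), "LD")
})

test_that("genotypes obey Hardy-Weinberg within a single subpopulation", {
  cfg <- sim_config(n_individuals = 500, n_contigs = 25, snps_per_contig = 8,
                    admixture_k = 1, missing_rate = 0, seed = 13)
  g <- simulate_genotypes(cfg)
  pv <- apply(g$dosage, 2, function(x) {
    p <- mean(x) / 2
    e <- c((1 - p)^2, 2 * p * (1 - p), p^2) * length(x)
    o <- tabulate(x + 1, 3)
    suppressWarnings(chisq.test(o, p = e / sum(e))$p.value)
  })
  expect_gte(mean(pv > 0.01), 0.95)
})

test_that("within-contig LD decays monotonically with physical distance", {
  edges <- c(0, 1000, 3000, 6000, 10000)
  means <- matrix(NA_real_, 20, length(edges) - 1)
  for (s in 1:20) {
    cfg <- sim_config(n_individuals = 120, n_contigs = 12,
                      snps_per_contig = 8, missing_rate = 0, seed = 6000 + s)
    ld <- pairwise_geno_r2(simulate_genotypes(cfg))
    bins <- cut(ld$distance, edges)
    means[s, ] <- tapply(ld$r2, bins, mean)
  }
  avg <- colMeans(means, na.rm = TRUE)
  # strict decay at short range; beyond the decay scale the bins sit on the
  # 1/n sampling floor, so allow noise of that order
  expect_true(all(diff(avg) <= 1 / (4 * 120)))
  expect_gt(avg[1], 3 * avg[length(avg)])
})

test_that("population structure is recoverable for K = 2 and absent for K = 1", {
  nsig1 <- 0L
  for (s in 1:30) {
    cfg <- sim_config(n_individuals = 100, n_contigs = 50,
                      snps_per_contig = 5, admixture_k = 1,
                      missing_rate = 0, seed = 7000 + s)
    pc <- pca_covariates(simulate_genotypes(cfg), n_pcs = 2)
    nsig1 <- nsig1 + (pc$n_significant > 0L)
  }
  expect_lte(nsig1 / 30, 0.05)

  cfg2 <- sim_config(n_individuals = 200, n_contigs = 60,
                     snps_per_contig = 10, admixture_k = 2,
                     admixture_alpha = 0.3, missing_rate = 0, seed = 77)
  pc2 <- pca_covariates(simulate_genotypes(cfg2))
  expect_gte(pc2$n_significant, 1L)
})

test_that("zero-variance phenotypes reproduce the archetype spline exactly", {
  cfg <- sim_config(n_individuals = 10, n_contigs = 3, snps_per_contig = 4,
                    missing_rate = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  tr <- truth_set(qtls = list(), variances = zero_variances(), seed = 21)
  ph <- simulate_phenotypes(g, tr, cfg)
  arch <- default_archetypes()
  expected <- spline_eval(unlist(arch[1, c("beta0", "beta1", "beta2", "beta3")]),
                          arch$K1, arch$K2, seq_len(cfg$n_rings))
  for (id in unique(ph$individual)[1:5]) {
    tr_i <- ph[ph$individual == id, ]
    expect_equal(tr_i$WD[order(tr_i$ring)], unname(expected), tolerance = 1e-12)
  }
})

test_that("an additive QTL separates homozygote latent means by 2a", {
  cfg <- sim_config(n_individuals = 2000, n_contigs = 10, snps_per_contig = 5,
                    missing_rate = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  snp <- g$info$snp_id[which.max(g$info$maf)]
  a <- 4
  tr <- truth_set(qtl_spec(snp, "intercept", "WD", additive_effect = a,
                           dominance_effect = 0), seed = 31)
  ph <- simulate_phenotypes(g, tr, cfg)
  lat <- attr(ph, "truth_realized")$latent$WD
  gdos <- g$dosage[rownames(lat), snp]
  gap <- mean(lat[gdos == 2, "beta0"]) - mean(lat[gdos == 0, "beta0"])
  se <- sqrt(var(lat[, "beta0"]) * (1 / sum(gdos == 2) + 1 / sum(gdos == 0)))
  expect_lt(abs(gap - 2 * a), 4 * se)
})

test_that("realized PVE tracks the target within tolerance", {
  rel_err <- vapply(1:12, function(s) {
    cfg <- sim_config(n_individuals = 2000, n_contigs = 10,
                      snps_per_contig = 5, missing_rate = 0, seed = 800 + s)
    g <- simulate_genotypes(cfg)
    snp <- g$info$snp_id[which.max(g$info$maf)]
    tr <- truth_set(qtl_spec(snp, "slope", "WD", target_pve = 0.05),
                    seed = 800 + s)
    ph <- simulate_phenotypes(g, tr, cfg)
    pve <- attr(ph, "truth_realized")$qtls$WD[[snp]]$realized_pve
    abs(pve - 0.05) / 0.05
  }, numeric(1))
  expect_lt(mean(rel_err), 0.10)
  expect_true(all(rel_err < 0.20))
})

test_that("phenotype simulation validates its inputs", {
  cfg <- sim_config(n_individuals = 20, n_contigs = 2, snps_per_contig = 3,
                    seed = 1)
  g <- simulate_genotypes(cfg)
  tr <- truth_set(qtl_spec("MA_99_12345", "intercept", "WD"), seed = 1)
  expect_error(simulate_phenotypes(g, tr, cfg), "MA_99_12345")
  expect_error(qtl_spec("x", "intercept", "WD", target_pve = 0.9),
               "target_pve")
})
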