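test_that("MAF/missingness filter keeps the boundary and preserves order", {
  n <- 50
  d <- cbind(rep(0, n),                          # MAF 0.00 (monomorphic)
             c(rep(1, 4), rep(0, n - 4)),        # MAF 0.04
             c(rep(1, 5), rep(0, n - 5)),        # MAF 0.05 (boundary, kept)
             c(rep(1, 30), rep(0, n - 30)),      # MAF 0.30
             rep(c(0, 2), length.out = n))       # MAF 0.50 exactly
  colnames(d) <- sprintf("MA_1_%d", 1:5)
  g <- genotype_matrix(d)
  kept <- filter_snps(g)
  expect_identical(kept$info$snp_id, sprintf("MA_1_%d", 3:5))
  # idempotent
  expect_identical(filter_snps(kept)$info$snp_id, kept$info$snp_id)
})

test_that("missingness above 20% removes a common SNP, 20% exactly is kept", {
  n <- 100
  x21 <- rbinom(n, 2, 0.3); x21[1:21] <- NA
  x20 <- rbinom(n, 2, 0.3); x20[1:20] <- NA
  ok <- rbinom(n, 2, 0.3)
  ok[1] <- 1L  # guard against a monomorphic draw
  d <- cbind(x21, x20, ok)
  colnames(d) <- sprintf("MA_1_%d", 1:3)
  kept <- filter_snps(genotype_matrix(d))
  expect_false("MA_1_1" %in% kept$info$snp_id)
  expect_true("MA_1_2" %in% kept$info$snp_id)
  expect_error(filter_snps(genotype_matrix(cbind(MA_1_9 = rep(0L, 10)))),
               "removed")
})

test_that("mean imputation fills missing with column means and is idempotent", {
  d <- cbind(c(0, 2, NA, 0, 2), c(1, 1, 1, NA, 1))
  colnames(d) <- c("MA_1_1", "MA_1_2")
  g <- impute_mean(genotype_matrix(d))
  expect_equal(g$dosage[3, 1], 1.0)
  expect_equal(g$dosage[4, 2], 1.0)
  expect_equal(colMeans(g$dosage), colMeans(d, na.rm = TRUE),
               ignore_attr = TRUE)
  g0 <- toy_genotypes(20, c(0.3, 0.4), seed = 2)
  expect_identical(impute_mean(g0), g0)
})

test_that("PCA scores are orthogonal and invariant to individual reordering", {
  g <- toy_genotypes(80, runif(100, 0.1, 0.5), seed = 3)
  pc <- pca_covariates(g)
  cp <- crossprod(pc$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_true(all(diff(pc$varfrac) <= 1e-12))
  expect_true(all(pc$varfrac >= 0 & pc$varfrac <= 1))
  perm <- sample(80)
  g2 <- genotype_matrix(g$dosage[perm, ])
  pc2 <- pca_covariates(g2)
  relerr <- abs(abs(pc2$scores[match(rownames(g$dosage),
                                     rownames(g2$dosage)), 1]) -
                abs(pc$scores[, 1]))
  expect_lt(max(relerr), 1e-8)
  expect_error(pca_covariates(genotype_matrix(matrix(1, 10, 4))), "variance")
})

test_that("unstructured genotypes show no Tracy-Widom significant axes", {
  nsig <- vapply(1:20, function(s) {
    g <- toy_genotypes(100, runif(250, 0.1, 0.5), seed = 9000 + s)
    pca_covariates(g, n_pcs = 2)$n_significant
  }, integer(1))
  expect_gte(mean(nsig == 0L), 0.95)
})

test_that("pairwise r2 matches a hand computation and direct cor", {
  d <- cbind(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2), c(2, 1, 0, 1, 0, 2))
  colnames(d) <- c("MA_1_100", "MA_1_300", "MA_1_900")
  g <- genotype_matrix(d)
  ld <- pairwise_geno_r2(g)
  expect_equal(nrow(ld), 3)
  dup <- ld[ld$snp_a == "MA_1_100" & ld$snp_b == "MA_1_300", ]
  expect_equal(dup$r2, 1)
  expect_equal(dup$distance, 200)
  pair <- ld[ld$snp_a == "MA_1_100" & ld$snp_b == "MA_1_900", ]
  expect_equal(pair$r2, cor(d[, 1], d[, 3])^2)
})

test_that("r2 is invariant to allele relabeling and respects contigs", {
  g <- toy_genotypes(50, c(0.2, 0.3, 0.4), seed = 5)
  ld1 <- pairwise_geno_r2(g, same_contig_only = FALSE)
  flip <- g$dosage
  flip[, 2] <- 2 - flip[, 2]
  ld2 <- pairwise_geno_r2(genotype_matrix(flip), same_contig_only = FALSE)
  expect_equal(ld1$r2, ld2$r2, tolerance = 1e-12)
  expect_equal(nrow(ld1), 3)
  # the three SNPs sit on different contigs, so within-contig pairs are empty
  expect_equal(nrow(pairwise_geno_r2(g, same_contig_only = TRUE)), 0)
})

test_that("independent SNPs have mean r2 near 1/n", {
  n <- 500
  g <- toy_genotypes(n, rep(0.4, 60), seed = 6)
  ld <- pairwise_geno_r2(g, same_contig_only = FALSE)
  m <- mean(ld$r2)
  se <- sd(ld$r2) / sqrt(nrow(ld))
  expect_lt(abs(m - 1 / n), 3 * se + 2e-4)
})

test_that("Hill-Weir fit recovers rho and its algebraic C->0 limit holds", {
  set.seed(9)
  d <- sample(1:5000, 400, replace = TRUE)
  r2 <- hill_weir_expectation(0.01 * d, 500) + rnorm(400, 0, 0.02)
  fit <- fit_hill_weir(data.frame(distance = d, r2 = r2), 500)
  expect_lt(abs(fit$rho - 0.01) / 0.01, 0.10)
  for (n in c(50, 500, 5000))
    expect_equal(hill_weir_expectation(0, n),
                 (10 / 22) * (1 + 36 / (22 * n)), tolerance = 1e-12)
  # fitted curve is monotone decreasing
  dd <- seq(0, 10000, by = 100)
  expect_true(all(diff(fit$curve(dd)) <= 0))
  expect_error(fit_hill_weir(data.frame(distance = rep(100, 20),
                                        r2 = runif(20)), 500),
               "single distance")
  expect_error(fit_hill_weir(data.frame(distance = 1:5, r2 = runif(5)), 500),
               "10")
})

test_that("distance_at_r2 matches a dense-grid oracle and handles sentinels", {
  set.seed(10)
  d <- sample(1:4000, 300, replace = TRUE)
  r2 <- hill_weir_expectation(0.02 * d, 400) + rnorm(300, 0, 0.01)
  fit <- fit_hill_weir(data.frame(distance = d, r2 = r2), 400)
  x <- distance_at_r2(fit, 0.1)
  grid <- seq(0, 20000, by = 0.5)
  oracle <- grid[which(fit$curve(grid) <= 0.1)[1]]
  expect_lt(abs(x - oracle), 1)
  # monotone in target
  expect_gt(distance_at_r2(fit, 0.05), distance_at_r2(fit, 0.2))
  # asymptote 1/n above target -> infinite distance
  fit_small_n <- fit_hill_weir(data.frame(distance = d, r2 = r2), 5)
  expect_identical(distance_at_r2(fit_small_n, 0.1), Inf)
  # target above the distance-zero value -> 0
  expect_identical(distance_at_r2(fit, 0.99), 0)
})
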