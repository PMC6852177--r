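orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, scale = FALSE)
  qr.Q(qr(X)) * sqrt(n)  # centered columns with unit 1/n-norm
}

test_that("orthonormal design reproduces the soft-threshold closed form", {
  n <- 64
  X <- orthonormal_design(n, 8)
  y <- rnorm(n)
  lam <- 0.05
  f <- fit_lasso(X, y, lambda = lam, tol = 1e-13)
  rho <- crossprod(X, y - mean(y)) / n
  s <- sqrt(colMeans(scale(X, scale = FALSE)^2))
  oracle <- sign(rho) * pmax(abs(rho) - lam, 0)
  expect_lt(max(abs(f$beta * s - oracle)), 1e-10)
})

test_that("lambda at or above lambda_max empties the model; lambda 0 is OLS", {
  n <- 60
  X <- orthonormal_design(n, 6, seed = 2)
  y <- rnorm(n)
  rho <- crossprod(X, y - mean(y)) / n
  f <- fit_lasso(X, y, lambda = max(abs(rho)) + 1e-10)
  expect_true(all(f$beta == 0))
  f0 <- fit_lasso(X[, 1:4], y, lambda = 0, tol = 1e-13)
  ols <- lm.fit(cbind(1, X[, 1:4]), y)$coefficients
  expect_lt(max(abs(f0$beta - ols[-1])), 1e-8)
  expect_lt(abs(f0$intercept - ols[1]), 1e-8)
})

test_that("solutions and objective match glmnet with unpenalized covariates", {
  skip_if_not_installed("glmnet")
  set.seed(2)
  n <- 120; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  cv <- matrix(rnorm(n * 2), n, 2)
  y <- X[, 1] * 0.5 + cv[, 1] * 0.3 + rnorm(n)
  lam <- 0.08
  f <- fit_lasso(X, y, covariates = cv, lambda = lam, tol = 1e-13)
  Zs <- scale(X) * sqrt(n / (n - 1))
  # glmnet rescales penalty factors to sum to nvars; undo that in lambda
  gn <- glmnet::glmnet(cbind(cv, Zs), y, lambda = lam * p / (p + 2),
                       standardize = FALSE, thresh = 1e-16,
                       penalty.factor = c(0, 0, rep(1, p)))
  bg <- as.numeric(coef(gn))[-1]
  s <- apply(X, 2, function(c) sqrt(mean((c - mean(c))^2)))
  expect_lt(max(abs(c(f$covariate_effects, f$beta * s) - bg)), 1e-7)
})

test_that("non-finite inputs are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_lasso(X, c(rnorm(9), NA), lambda = 0.1), "non-finite")
  X[1, 1] <- Inf
  expect_error(fit_lasso(X, rnorm(10), lambda = 0.1), "non-finite")
})

test_that("first_q selects the dominant signal and respects q bounds", {
  set.seed(3)
  n <- 100; p <- 50
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  colnames(X) <- paste0("s", 1:p)
  y <- X[, 7] * 1.5 + rnorm(n, 0, 0.5)
  prep <- ringwas:::prep_lasso(X, y)
  sel <- ringwas:::lasso_support(prep, first_q(1))
  expect_identical(sel$support, 7L)
  expect_error(select_lambda(X, y, rule = first_q(p + 1)), "exceeds")
  # a full-support request walks the path down until every column is active
  Xf <- matrix(rnorm(200 * 5), 200, 5)
  yf <- rnorm(200)
  pf <- ringwas:::prep_lasso(Xf, yf)
  self <- ringwas:::lasso_support(pf, first_q(5))
  expect_identical(sort(self$support), 1:5)
  expect_lt(self$lambda, 0.5 * pf$lambda_max)
})

test_that("cross-validated lambda is deterministic given its seed", {
  set.seed(4)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- X[, 3] + rnorm(80)
  l1 <- select_lambda(X, y, rule = cv_k(5, seed = 9))
  l2 <- select_lambda(X, y, rule = cv_k(5, seed = 9))
  expect_identical(l1, l2)
  expect_gt(l1, 0)
})

test_that("the false-positive threshold follows its closed form", {
  grid <- expand.grid(q = c(1, 5, 10, 50, 84), EV = c(0.5, 1, 2),
                      p = c(1000, 178101))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], if (p >= q)
      expect_equal(ssp_threshold(q, EV, p),
                   min(1, 0.5 + q^2 / (2 * EV * p))))
  }
  expect_equal(ssp_threshold(10, 1, 1000), 0.55)
  expect_equal(ssp_threshold(1, 1, 1), 1.0)
  expect_error(ssp_threshold(0, 1, 10))
  expect_error(ssp_threshold(5, 1, 3))
})

test_that("stability selection is reproducible and frequency-consistent", {
  set.seed(5)
  n <- 60; p <- 80
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  colnames(X) <- paste0("s", 1:p)
  y <- X[, 11] + rnorm(n, 0, 0.7)
  cfg <- stability_config(n_subsamples = 30, q = 3, seed = 17)
  s1 <- stability_selection(X, y, cfg = cfg)
  s2 <- stability_selection(X, y, cfg = cfg)
  expect_identical(s1$freq, s2$freq)
  expect_true(all(s1$freq >= 0 & s1$freq <= 1))
  # the path grid may overshoot q by a few columns at the entry point
  expect_true(all(s1$support_sizes >= 3))
  expect_lte(max(s1$support_sizes), 8)
  one <- stability_selection(X, y,
                             cfg = stability_config(n_subsamples = 1, q = 3,
                                                    seed = 1))
  expect_true(all(one$freq %in% c(0, 1)))
  expect_error(stability_selection(X, rep(1, n), cfg = cfg), "degenerate")
  expect_error(stability_selection(X[1:10, ], y[1:10], cfg = cfg), "20")
})

test_that("a strongly planted QTL reaches a high selection frequency", {
  set.seed(6)
  n <- 200; p <- 300
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  colnames(X) <- paste0("s", 1:p)
  gx <- X[, 42]
  a <- sqrt(0.10 / (0.90 * var(gx)))   # 10% PVE
  y <- a * gx + rnorm(n)
  ss <- stability_selection(X, y, cfg = stability_config(n_subsamples = 100,
                                                         seed = 2))
  expect_gt(ss$freq[42], 0.9)
  called <- call_qtls(ss, trait = "WD", latent_trait = "intercept")
  expect_true("s42" %in% called$snp_id)
  expect_true(all(diff(called$frequency) <= 0))
})

test_that("pure-noise responses stay below the false-positive budget", {
  set.seed(7)
  n <- 200; p <- 500
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  colnames(X) <- paste0("s", 1:p)
  calls <- vapply(1:10, function(s) {
    y <- rnorm(n)
    ss <- stability_selection(X, y,
                              cfg = stability_config(n_subsamples = 50,
                                                     seed = 1000 + s))
    sum(ss$freq >= ss$threshold)
  }, numeric(1))
  expect_lt(mean(calls), 1)
})

test_that("QTL calling includes the boundary and orders deterministically", {
  ssp <- structure(list(freq = c(a = 0.700, b = 0.520, c = 0.519,
                                 d = 0.700),
                        threshold = 0.52, q = 2, EV = 1, p = 4,
                        support_sizes = integer(0), n_subsamples = 100,
                        n_skipped = 0L), class = "ssp_table")
  got <- call_qtls(ssp, trait = "WD", latent_trait = "slope")
  expect_identical(got$snp_id, c("a", "d", "b"))
  ssp$freq[] <- 0.1
  expect_equal(nrow(call_qtls(ssp)), 0)
})

test_that("adaptive-LASSO PVE recovers a planted 5% QTL", {
  ests <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 2000
    gx <- rbinom(n, 2, 0.4)
    X <- cbind(snpA = gx, snpB = rbinom(n, 2, 0.3))
    a <- sqrt(0.05 / (0.95 * var(gx)))
    y <- a * gx + rnorm(n)
    adaptive_lasso_pve(X, y, selected = "snpA", seed = s)$pve
  }, numeric(1))
  expect_lt(abs(mean(ests) - 5), 1.5)
  expect_true(all(ests >= 0))
})

test_that("PVE vanishes for an unrelated SNP and splits between equal QTLs", {
  set.seed(11)
  n <- 1500
  X <- cbind(s1 = rbinom(n, 2, 0.4), s2 = rbinom(n, 2, 0.4))
  y <- rnorm(n)
  p0 <- adaptive_lasso_pve(X, y, selected = c("s1"), seed = 1)
  expect_lt(p0$pve, 0.5)
  y2 <- 0.3 * X[, 1] + 0.3 * X[, 2] + rnorm(n)
  p2 <- adaptive_lasso_pve(X, y2, selected = c("s1", "s2"), seed = 1)
  expect_lt(abs(p2$pve[1] - p2$pve[2]), 0.5 * max(p2$pve))
  expect_error(adaptive_lasso_pve(X, y, selected = character(0)), "one")
})

test_that("calling is invariant to column order and affine response scaling", {
  set.seed(12)
  n <- 120; p <- 60
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  colnames(X) <- paste0("s", 1:p)
  y <- X[, 5] * 0.8 + rnorm(n, 0, 0.6)
  cfg <- stability_config(n_subsamples = 40, q = 3, seed = 3)
  s1 <- stability_selection(X, y, cfg = cfg)
  perm <- sample(p)
  s2 <- stability_selection(X[, perm], y, cfg = cfg)
  expect_equal(s2$freq[colnames(X)], s1$freq, tolerance = 1e-12)
  s3 <- stability_selection(X, 100 + 7 * y, cfg = cfg)
  expect_identical(names(which(s1$freq >= s1$threshold)),
                   names(which(s3$freq >= s3$threshold)))
})

test_that("the full pipeline finds a strong planted QTL and is deterministic", {
  cfg <- sim_config(n_individuals = 150, n_contigs = 40, snps_per_contig = 5,
                    missing_rate = 0.02, seed = 21)
  g <- simulate_genotypes(cfg)
  snp <- g$info$snp_id[which.max(g$info$maf)]
  tr <- truth_set(qtl_spec(snp, "intercept", "WD", target_pve = 0.25),
                  seed = 21)
  ph <- simulate_phenotypes(g, tr, cfg)
  scfg <- stability_config(n_subsamples = 60, seed = 21)
  r1 <- run_pipeline(g, ph, cfg = scfg)
  expect_true(snp %in% r1$qtls$snp_id[r1$qtls$latent_trait == "intercept"])
  expect_true(all(r1$qtls$pve >= 0 & r1$qtls$pve <= 100))
  r2 <- run_pipeline(g, ph, cfg = scfg)
  expect_identical(r1$qtls, r2$qtls)
})
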