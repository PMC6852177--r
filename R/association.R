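# Multilocus LASSO association for one latent trait:
#   min_{a0, a} 1/(2n) sum_i (y_i - a0 - sum_j x_ij a_j)^2 + lambda sum_j |a_j|
# with PC covariates always unpenalized, stability selection over
# half-subsamples, the expected-false-positive threshold
#   pi_thr = 1/2 + q^2 / (2 E[V] p),
# and adaptive-LASSO refitting of the selected SNPs for per-QTL PVE.

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
}

# Center y and covariates, center X and scale penalized columns to unit
# 1/n-norm. Constant columns keep scale 1 and a zero column (never selected).
prep_lasso <- function(X, y, covariates = NULL) {
  X <- as.matrix(X)
  check_finite(X, "X"); check_finite(y, "y")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  s <- sqrt(colMeans(Xc^2))
  szero <- s <= 0
  s[szero] <- 1
  Xs <- sweep(Xc, 2, s, "/")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    check_finite(covariates, "covariates")
    stopifnot(nrow(covariates) == n)
    cm <- colMeans(covariates)
    Cc <- sweep(covariates, 2, cm)
    if (qr(Cc)$rank < ncol(Cc) && ncol(Cc) > 0)
      stopf("covariate matrix is rank deficient")
    Z <- cbind(Cc, Xs)
    pf <- c(rep(0, ncol(Cc)), rep(1, p))
  } else {
    cm <- numeric(0); Cc <- NULL
    Z <- Xs
    pf <- rep(1, p)
  }
  ym <- mean(y)
  # lambda_max: smallest lambda with an empty penalized support, computed on
  # the residual after the unpenalized covariates
  r0 <- y - ym
  if (!is.null(Cc) && ncol(Cc) > 0) r0 <- lm.fit(Cc, r0)$residuals
  lambda_max <- max(abs(crossprod(Xs, r0)) / n, 1e-12)
  list(Z = Z, yc = y - ym, pf = pf, n = n, p = p,
       n_cov = length(cm), xm = xm, s = s, cm = cm, ym = ym,
       lambda_max = lambda_max, snp_names = colnames(X))
}

unscale_beta <- function(prep, b) {
  ncov <- prep$n_cov
  bx <- b[(ncov + 1):length(b)] / prep$s
  bc <- if (ncov) b[seq_len(ncov)] else numeric(0)
  a0 <- prep$ym - sum(prep$xm * bx) - if (ncov) sum(prep$cm * bc) else 0
  list(intercept = a0, beta = setNames(bx, prep$snp_names),
       covariate_effects = bc)
}

#' Solve the multilocus LASSO at a given penalty
#'
#' Coordinate descent on the standardized design; covariates (e.g. the first
#' five PCs) are never penalized. SNP effects are reported back on the
#' dosage (0/1/2) scale.
#'
#' @param X Complete dosage matrix, individuals x SNPs.
#' @param y Latent-trait response vector.
#' @param covariates Optional unpenalized covariate matrix.
#' @param lambda Penalty (>= 0).
#' @param tol Coordinate-descent convergence tolerance.
#' @return List: `intercept`, `beta` (named SNP effects, dosage scale),
#'   `covariate_effects`, `lambda`, `objective` (standardized-scale value of
#'   the penalized objective).
#' @export
fit_lasso <- function(X, y, covariates = NULL, lambda, tol = 1e-11) {
  stopifnot(lambda >= 0)
  prep <- prep_lasso(X, y, covariates)
  # short warm-started path down to the requested lambda
  lams <- if (lambda >= prep$lambda_max) lambda else
    unique(c(exp(seq(log(prep$lambda_max), log(max(lambda, 1e-12)),
                     length.out = 15L)), lambda))
  fit <- lasso_cd_path(prep$Z, prep$yc, prep$pf, lams, tol = tol)
  b <- fit$beta[, fit$n_lambda]
  res <- prep$yc - as.numeric(prep$Z %*% b)
  obj <- sum(res^2) / (2 * prep$n) + lambda * sum(prep$pf * abs(b))
  out <- unscale_beta(prep, b)
  out$lambda <- lambda
  out$objective <- obj
  out
}

#' Penalty-selection rules for the LASSO path
#'
#' `first_q(q)` takes the first (largest) lambda on the path whose penalized
#' support reaches `q` SNPs, so the per-subsample selection count entering
#' the stability threshold is known exactly. `cv_k(k, seed)` is k-fold
#' cross-validation, minimizing mean squared prediction error.
#'
#' @param q Target support size.
#' @param k Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return A `lambda_rule` object.
#' @export
first_q <- function(q) {
  stopifnot(q >= 1)
  structure(list(type = "first_q", q = as.integer(q)), class = "lambda_rule")
}

#' @rdname first_q
#' @export
cv_k <- function(k = 10, seed = 1) {
  structure(list(type = "cv", k = as.integer(k), seed = as.integer(seed)),
            class = "lambda_rule")
}

lambda_path <- function(lambda_max, n_points = 100L, ratio = 1e-3) {
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = n_points))
}

# Support of the penalized coefficients at the rule's lambda, on prepared data.
lasso_support <- function(prep, rule, tol = 1e-9) {
  p <- prep$p
  if (rule$type == "first_q") {
    q <- rule$q
    if (q > p) stopf("first_q: q = %d exceeds the number of SNPs (%d)", q, p)
    lams <- lambda_path(prep$lambda_max)
    fit <- lasso_cd_path(prep$Z, prep$yc, prep$pf, lams, tol = tol,
                         stop_at_support = q)
    if (fit$support[fit$n_lambda] < q) {
      # support never reached q on the default path: extend it
      lams <- lambda_path(prep$lambda_max, 60L, 1e-6)
      fit <- lasso_cd_path(prep$Z, prep$yc, prep$pf, lams, tol = tol,
                           stop_at_support = q)
    }
    j <- fit$n_lambda
    b <- fit$beta[, j]
    list(lambda = lams[j], support = which(prep$pf > 0 & b != 0) - prep$n_cov,
         beta = b)
  } else {
    lam <- cv_lambda(prep, rule, tol = tol)
    fit <- lasso_cd_path(prep$Z, prep$yc, prep$pf, lam, tol = tol)
    b <- fit$beta[, 1]
    list(lambda = lam, support = which(prep$pf > 0 & b != 0) - prep$n_cov,
         beta = b)
  }
}

cv_lambda <- function(prep, rule, n_points = 60L, tol = 1e-7) {
  n <- prep$n
  lams <- lambda_path(prep$lambda_max, n_points)
  old <- .Random.seed_save()
  set.seed(child_seed(rule$seed, "cvfolds"))
  folds <- sample(rep_len(seq_len(rule$k), n))
  .Random.seed_restore(old)
  err <- matrix(NA_real_, rule$k, length(lams))
  for (f in seq_len(rule$k)) {
    tr <- folds != f
    fit <- lasso_cd_path(prep$Z[tr, , drop = FALSE], prep$yc[tr], prep$pf,
                         lams, tol = tol)
    pred <- prep$Z[!tr, , drop = FALSE] %*% fit$beta
    err[f, ] <- colMeans((prep$yc[!tr] - pred)^2)
  }
  lams[which.min(colMeans(err))]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Choose the LASSO penalty for a data set
#'
#' @param X Dosage matrix.
#' @param y Response.
#' @param covariates Optional unpenalized covariates.
#' @param rule A [first_q()] or [cv_k()] rule.
#' @return The selected lambda.
#' @export
select_lambda <- function(X, y, covariates = NULL, rule) {
  stopifnot(inherits(rule, "lambda_rule"))
  prep <- prep_lasso(X, y, covariates)
  lasso_support(prep, rule)$lambda
}

#' Stability-selection threshold controlling expected false positives
#'
#' `min(1, 1/2 + q^2 / (2 E[V] p))`: with per-subsample selection count `q`
#' out of `p` markers, selection frequencies at or above this cutoff keep
#' the expected number of falsely selected markers below `EV`. At the
#' study scale (p = 178101, q = 84, EV = 1) the cutoff is 0.52.
#'
#' @param q Number of markers selected per subsample (>= 1).
#' @param EV Bound on the expected number of false positives (> 0).
#' @param p Total number of markers (>= q).
#' @return Threshold in (0.5, 1\].
#' @export
ssp_threshold <- function(q, EV = 1, p) {
  stopifnot(q >= 1, EV > 0, p >= q)
  min(1, 0.5 + q^2 / (2 * EV * p))
}

# Study-style default: q chosen so the Eq.-5 cutoff is ~0.52 at any p
default_q <- function(p) max(1L, ceiling(sqrt(0.04 * p)))

#' Stability-selection configuration
#'
#' @param n_subsamples Number of half-subsamples (study: 1000).
#' @param subsample_fraction Fraction of individuals per subsample (0.5).
#' @param EV Expected-false-positive bound (default 1).
#' @param q Per-subsample selection count; default `ceiling(sqrt(0.04 p))`,
#'   which reproduces the 0.52 cutoff of the study design at any panel size
#'   (resolved against `p` when the selection is run).
#' @param threshold SSP cutoff; default from [ssp_threshold()].
#' @param seed Seed controlling the subsampling stream.
#' @return A `stability_config` list.
#' @export
stability_config <- function(n_subsamples = 1000, subsample_fraction = 0.5,
                             EV = 1, q = NULL, threshold = NULL, seed = 1) {
  stopifnot(n_subsamples >= 1, subsample_fraction > 0,
            subsample_fraction < 1, EV > 0)
  if (!is.null(q)) stopifnot(q >= 1)
  if (!is.null(threshold)) stopifnot(threshold > 0.5, threshold <= 1)
  structure(list(n_subsamples = as.integer(n_subsamples),
                 subsample_fraction = subsample_fraction, EV = EV,
                 q = q, threshold = threshold, seed = as.integer(seed)),
            class = "stability_config")
}

#' Selection frequencies over repeated half-subsample LASSO fits
#'
#' For each of `n_subsamples` seeded subsamples of
#' `floor(n * subsample_fraction)` individuals drawn without replacement,
#' the LASSO is fitted (penalty per `lambda_rule` within the subsample) and
#' the nonzero SNP support recorded; the selection frequency of each SNP is
#' its stability selection probability (SSP). Degenerate subsamples
#' (constant response) are skipped and logged; more than 10% skips is an
#' error.
#'
#' @param X Complete dosage matrix (individuals x SNPs).
#' @param y Latent-trait response.
#' @param covariates Optional unpenalized covariates (e.g. PC scores).
#' @param cfg A [stability_config()].
#' @param lambda_rule A [first_q()] or [cv_k()] rule; default
#'   `first_q(cfg$q)`.
#' @return An `ssp_table`: `freq` (named SSP per SNP), `q`, `threshold`,
#'   `support_sizes`, `n_subsamples`, `n_skipped`.
#' @export
stability_selection <- function(X, y, covariates = NULL,
                                cfg = stability_config(),
                                lambda_rule = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 20L) stopf("stability selection needs at least 20 individuals")
  q <- cfg$q %||% default_q(p)
  lambda_rule <- lambda_rule %||% first_q(q)
  threshold <- cfg$threshold %||% ssp_threshold(q, cfg$EV, p)
  m <- floor(n * cfg$subsample_fraction)
  set.seed(child_seed(cfg$seed, "stability"))
  counts <- numeric(p)
  sizes <- integer(cfg$n_subsamples)
  skipped <- 0L
  for (b in seq_len(cfg$n_subsamples)) {
    idx <- sample.int(n, m)
    ys <- y[idx]
    if (var(ys) == 0 || !all(is.finite(ys))) {
      skipped <- skipped + 1L
      next
    }
    prep <- prep_lasso(X[idx, , drop = FALSE], ys,
                       if (!is.null(covariates))
                         covariates[idx, , drop = FALSE] else NULL)
    sel <- lasso_support(prep, lambda_rule)
    counts[sel$support] <- counts[sel$support] + 1
    sizes[b] <- length(sel$support)
  }
  if (skipped > 0L)
    message(sprintf("stability_selection: skipped %d degenerate subsample(s)",
                    skipped))
  if (skipped > 0.1 * cfg$n_subsamples)
    stopf("more than 10%% of subsamples were degenerate")
  freq <- setNames(counts / cfg$n_subsamples,
                   colnames(X) %||% paste0("snp", seq_len(p)))
  structure(list(freq = freq, q = q, EV = cfg$EV, p = p,
                 threshold = threshold, support_sizes = sizes,
                 n_subsamples = cfg$n_subsamples, n_skipped = skipped),
            class = "ssp_table")
}

#' Call QTLs from stability selection probabilities
#'
#' SNPs whose SSP is at least the threshold ("at least", boundary included),
#' sorted by frequency descending then SNP id; the empty set is a valid
#' result.
#'
#' @param ssp An `ssp_table` from [stability_selection()].
#' @param trait,latent_trait Labels carried into the records.
#' @param threshold Override the table's threshold.
#' @return data.frame: snp_id, trait, latent_trait, frequency.
#' @export
call_qtls <- function(ssp, trait = NA_character_,
                      latent_trait = NA_character_, threshold = NULL) {
  stopifnot(inherits(ssp, "ssp_table"))
  thr <- threshold %||% ssp$threshold
  hit <- ssp$freq[ssp$freq >= thr]
  ord <- order(-hit, names(hit))
  data.frame(snp_id = names(hit)[ord],
             trait = rep(trait, length(hit)),
             latent_trait = rep(latent_trait, length(hit)),
             frequency = unname(hit[ord]), stringsAsFactors = FALSE)
}

#' Per-QTL percentage of phenotypic variance via the adaptive LASSO
#'
#' Two-stage fit on the selected SNPs: initial OLS (ridge fallback when the
#' design is rank deficient or a coefficient is exactly zero) gives weights
#' `w_j = 1/|alpha_j|`; the adaptive LASSO re-fit uses those weights as
#' penalty factors with lambda chosen by k-fold cross-validation. The PVE of
#' SNP j is `100 * Var(x_j alpha_j) / Var(y)`.
#'
#' @param X Complete dosage matrix.
#' @param y Response.
#' @param covariates Optional unpenalized covariates.
#' @param selected Character ids (or column indices) of the selected SNPs.
#' @param seed Seed for the CV folds.
#' @param k CV folds (default 5).
#' @return data.frame: snp_id, effect (dosage scale), pve (percent).
#' @export
adaptive_lasso_pve <- function(X, y, covariates = NULL, selected,
                               seed = 1, k = 5) {
  X <- as.matrix(X)
  if (length(selected) < 1L) stopf("need at least one selected SNP")
  sel_idx <- if (is.character(selected)) match(selected, colnames(X))
             else as.integer(selected)
  if (anyNA(sel_idx)) stopf("selected SNP(s) not found in X")
  Xs <- X[, sel_idx, drop = FALSE]
  ids <- colnames(X)[sel_idx] %||% paste0("snp", sel_idx)
  n <- nrow(Xs)
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  Z <- cbind(1, covariates, Xs)
  init <- NULL
  if (n > ncol(Z)) {
    ols <- lm.fit(Z, y)
    if (ols$rank == ncol(Z)) init <- ols$coefficients
  }
  ridge_init <- function() {
    Zc <- scale(cbind(covariates, Xs), scale = FALSE)
    C <- crossprod(Zc) / n
    lam <- 1e-2 * mean(diag(C))
    as.numeric(solve(C + lam * diag(ncol(Zc)),
                     crossprod(Zc, y - mean(y)) / n))
  }
  if (is.null(init)) {
    a <- ridge_init()
    a_snp <- a[(ncov + 1):length(a)]
  } else {
    a_snp <- init[(1 + ncov + 1):length(init)]
  }
  if (any(a_snp == 0)) {
    message("adaptive_lasso_pve: zero initial weight; ridge fallback used")
    a_r <- ridge_init()
    a_snp[a_snp == 0] <- a_r[(ncov + 1):length(a_r)][a_snp == 0]
    a_snp[a_snp == 0] <- 1e-8
  }
  w <- 1 / abs(a_snp)
  prep <- prep_lasso(Xs, y, covariates)
  # the standardized coefficient is s_j * (dosage-scale effect), so dividing
  # the factor by s_j makes the penalty act on the dosage-scale effect
  pf <- w / prep$s
  pf <- pf / mean(pf)
  prep$pf[prep$n_cov + seq_along(pf)] <- pf
  snp_cols <- prep$n_cov + seq_along(pf)
  prep$lambda_max <- max(abs(crossprod(prep$Z[, snp_cols, drop = FALSE],
                                       prep$yc) / n) / pmax(pf, 1e-12),
                         1e-12)
  lam <- cv_lambda(prep, list(k = as.integer(k), seed = as.integer(seed)),
                   n_points = 50L, tol = 1e-9)
  fit <- lasso_cd_path(prep$Z, prep$yc, prep$pf, lam, tol = 1e-11)
  b <- unscale_beta(prep, fit$beta[, 1])
  pve <- 100 * apply(sweep(Xs, 2, b$beta, "*"), 2, var) / var(y)
  data.frame(snp_id = ids, effect = unname(b$beta), pve = unname(pve),
             stringsAsFactors = FALSE)
}
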