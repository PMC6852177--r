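# SNP QC, mean imputation, PCA covariates with Tracy-Widom significance,
# zygotic LD r2 and the Hill-Weir decay trendline.

#' Filter SNPs on minor-allele frequency and missingness
#'
#' Keeps SNPs with MAF >= `maf_min` (computed on non-missing calls; the
#' boundary is kept) and missing fraction <= `max_missing`; column order is
#' preserved and the operation is idempotent.
#'
#' @param g A `genotype_matrix`.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param max_missing Maximum missing fraction (default 0.20).
#' @return Filtered `genotype_matrix`.
#' @export
filter_snps <- function(g, maf_min = 0.05, max_missing = 0.20) {
  stopifnot(inherits(g, "genotype_matrix"))
  af <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  missf <- colMeans(is.na(g$dosage))
  keep <- !is.na(maf) & maf >= maf_min & missf <= max_missing
  if (!any(keep)) stopf("all SNPs removed by the MAF/missingness filter")
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  info = g$info[keep, , drop = FALSE])
}

#' Replace missing dosages by the per-SNP mean of observed dosages
#'
#' @param g A `genotype_matrix`.
#' @return `genotype_matrix` with a complete (possibly fractional) dosage
#'   matrix; input without missing calls is returned unchanged.
#' @export
impute_mean <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!anyNA(g$dosage)) return(g)
  d <- g$dosage
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  out <- g
  out$dosage <- d
  out$info$missing <- 0
  out
}

# Tracy-Widom (TW1) critical points (Patterson 2006 tabulation).
tw_critical <- c("0.05" = 0.9793, "0.01" = 2.0234, "0.001" = 3.2724)

#' Tracy-Widom statistics for a set of eigenvalues
#'
#' Patterson-style normalization: for the k-th test the eigenvalues from k
#' onward estimate an effective marker count, the leading one is rescaled
#' and centred with the Tracy-Widom mean/scale, and compared with the TW1
#' critical point.
#'
#' @param eigenvalues Positive eigenvalues, decreasing.
#' @param level Significance level: 0.05, 0.01 or 0.001.
#' @return data.frame with the TW statistic and significance per eigenvalue.
#' @export
tracy_widom <- function(eigenvalues, level = 0.01) {
  crit <- tw_critical[as.character(level)]
  if (is.na(crit)) stopf("level must be one of 0.05, 0.01, 0.001")
  l <- eigenvalues[eigenvalues > max(eigenvalues) * 1e-9]
  m_all <- length(l)
  tw <- rep(NA_real_, m_all)
  for (k in seq_len(m_all)) {
    lk <- l[k:m_all]
    m <- length(lk)
    if (m < 3L) break
    s1 <- sum(lk); s2 <- sum(lk^2)
    neff <- ((m + 1) * s1^2) / ((m - 1) * s2 - s1^2)
    if (!is.finite(neff) || neff <= 1) next
    ell <- m * lk[1] / s1
    a <- sqrt(neff - 1); b <- sqrt(m)
    mu <- (a + b)^2 / neff
    sig <- ((a + b) / neff) * (1 / a + 1 / b)^(1 / 3)
    tw[k] <- (ell - mu) / sig
  }
  data.frame(index = seq_len(m_all), eigenvalue = l, tw = tw,
             significant = !is.na(tw) & tw > crit)
}

#' Principal-component covariates with Tracy-Widom significance
#'
#' PCA of the column-standardized dosage matrix. The number of significant
#' axes counts leading eigenvalues whose Tracy-Widom statistic exceeds the
#' critical point, stopping at the first non-significant one.
#'
#' @param g A complete (imputed) `genotype_matrix`.
#' @param n_pcs Number of PC score columns to return (default 5).
#' @param level Tracy-Widom significance level (default 0.01).
#' @return List: `scores` (individuals x n_pcs), `varfrac`, `eigenvalues`,
#'   `tw` (per-eigenvalue table), `n_significant`.
#' @export
pca_covariates <- function(g, n_pcs = 5, level = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (anyNA(d)) stopf("impute missing dosages before PCA (see impute_mean)")
  if (nrow(d) < n_pcs + 1) stopf("need at least n_pcs + 1 individuals")
  sds <- apply(d, 2, sd)
  keep <- sds > 0
  if (!any(keep)) stopf("zero-variance dosage matrix")
  z <- scale(d[, keep, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  varfrac <- ev / sum(ev)
  twt <- tracy_widom(ev, level = level)
  nsig <- 0L
  for (i in seq_len(nrow(twt))) {
    if (isTRUE(twt$significant[i])) nsig <- nsig + 1L else break
  }
  scores <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  rownames(scores) <- rownames(d)
  list(scores = scores, varfrac = varfrac, eigenvalues = ev, tw = twt,
       n_significant = nsig)
}

#' Pairwise zygotic LD (squared genotype correlation)
#'
#' r2 is the squared Pearson correlation of dosage vectors over individuals
#' non-missing at both SNPs; distance is the absolute difference of 1-based
#' positions. Pairs with fewer than 2 complete observations are skipped.
#'
#' @param g A `genotype_matrix`.
#' @param same_contig_only Restrict to within-contig pairs (default TRUE).
#' @param min_r2 Drop records below this r2 (default 0, keep all).
#' @return data.frame: snp_a, snp_b, contig, distance, r2.
#' @export
pairwise_geno_r2 <- function(g, same_contig_only = TRUE, min_r2 = 0) {
  stopifnot(inherits(g, "genotype_matrix"))
  info <- g$info
  groups <- if (same_contig_only) split(seq_len(nrow(info)), info$contig)
            else list(all = seq_len(nrow(info)))
  out <- list()
  skipped <- 0L
  for (gr in names(groups)) {
    idx <- groups[[gr]]
    if (length(idx) < 2L) next
    sub <- g$dosage[, idx, drop = FALSE]
    cc <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
    nobs <- crossprod(!is.na(sub))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    a <- pr[, 1]; b <- pr[, 2]
    ok <- nobs[pr] >= 2L & is.finite(cc[pr])
    skipped <- skipped + sum(!ok)
    a <- a[ok]; b <- b[ok]
    if (!length(a)) next
    out[[gr]] <- data.frame(
      snp_a = info$snp_id[idx[a]], snp_b = info$snp_id[idx[b]],
      contig = info$contig[idx[a]],
      distance = abs(info$pos[idx[a]] - info$pos[idx[b]]),
      r2 = cc[cbind(a, b)]^2, stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    message(sprintf("pairwise_geno_r2: skipped %d pair(s) with <2 complete observations or zero variance",
                    skipped))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_a = character(), snp_b = character(),
                      contig = character(), distance = numeric(),
                      r2 = numeric())
  rownames(res) <- NULL
  res[res$r2 >= min_r2, , drop = FALSE]
}

#' Hill-Weir expectation of r2 at recombination scale C
#'
#' `E[r2] = ((10+C)/((2+C)(11+C))) * (1 + ((3+C)(12+12C+C^2)) /
#' (n(2+C)(11+C)))` with `C = rho * distance`; the `n`-dependent factor is
#' the finite-sample inflation with asymptote 1/n.
#'
#' @param C Non-negative recombination parameter (rho times distance in bp).
#' @param n Sample size.
#' @return Expected r2.
#' @export
hill_weir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir LD-decay trendline
#'
#' Nonlinear least squares of per-pair r2 records on the Hill-Weir
#' expectation with `C = rho * distance`, using a bounded
#' Levenberg-Marquardt fit (`minpack.lm`) with multiple starting values.
#'
#' @param records LD records from [pairwise_geno_r2()] (needs `distance`,
#'   `r2`; at least 10 records spanning at least 2 distinct distances).
#' @param n Sample size (individuals) behind the r2 values.
#' @return A `hill_weir_fit`: `rho`, `n`, and `curve(distance)` giving the
#'   fitted expectation.
#' @export
fit_hill_weir <- function(records, n) {
  stopifnot(all(c("distance", "r2") %in% names(records)))
  if (nrow(records) < 10L) stopf("need at least 10 LD records")
  if (length(unique(records$distance)) < 2L)
    stopf("LD records span a single distance; decay cannot be fitted")
  d <- records$distance
  r2 <- records$r2
  starts <- 10^seq(-6, 0, by = 1)
  best <- NULL
  best_rss <- Inf
  errs <- character()
  for (s in starts) {
    fit <- try(minpack.lm::nlsLM(
      r2 ~ hill_weir_expectation(rho * d, n),
      start = list(rho = s), lower = c(rho = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (inherits(fit, "try-error")) {
      errs <- c(errs, as.character(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- fit
    }
  }
  if (is.null(best))
    stopf("Hill-Weir fit failed to converge from all starts: %s",
          paste(unique(errs), collapse = "; "))
  rho <- unname(coef(best)["rho"])
  structure(list(rho = rho, n = n, rss = best_rss,
                 curve = function(distance)
                   hill_weir_expectation(rho * distance, n)),
            class = "hill_weir_fit")
}

#' Distance at which the fitted LD curve drops to a target r2
#'
#' Smallest distance where the fitted Hill-Weir expectation is <= `target`;
#' `Inf` when the curve's asymptote (1/n) stays above the target, 0 when
#' even unlinked-distance-zero LD is already below it.
#'
#' @param fit A `hill_weir_fit`.
#' @param target Target r2 (default 0.1).
#' @return Distance in bp (possibly `Inf` or 0).
#' @export
distance_at_r2 <- function(fit, target = 0.1) {
  stopifnot(inherits(fit, "hill_weir_fit"))
  at0 <- fit$curve(0)
  if (at0 <= target) return(0)
  if (fit$rho <= 0) return(Inf)
  asym <- 1 / fit$n
  if (asym >= target) return(Inf)
  hi <- 1
  while (fit$curve(hi) > target && hi < 1e12) hi <- hi * 10
  if (fit$curve(hi) > target) return(Inf)
  uniroot(function(x) fit$curve(x) - target, c(0, hi),
          tol = 1e-9 * max(1, hi))$root
}
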