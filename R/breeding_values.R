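# Joint-site mixed model per annual ring:
#   Y_ijkl = mu + S_i + B_j(i) + F_k + SF_ik + e_ijkl
# with F ~ N(0, sigma_f^2), SF ~ N(0, sigma_sf^2) and site-specific residual
# variances. REML via the sparse mixed-model equations; EBVs are the BLUPs
# of the family effects.

#' REML fit of a general two-random-term model with grouped residuals
#'
#' Internal engine behind [fit_ring_model()]. Maximizes the REML
#' log-likelihood over log-variances with `nlminb`, using Henderson's
#' mixed-model equations in sparse form.
#'
#' @param y Response vector.
#' @param X Fixed-effect design (full column rank).
#' @param Zlist Named list of random-effect indicator matrices.
#' @param resid_group Factor of residual-variance groups (e.g. site).
#' @return List with variance components, fixed solutions, BLUPs,
#'   REML log-likelihood and AIC.
#' @keywords internal
reml_mme <- function(y, X, Zlist, resid_group) {
  n <- length(y)
  p <- ncol(X)
  resid_group <- droplevels(as.factor(resid_group))
  glev <- levels(resid_group)
  nr <- length(Zlist)
  qs <- vapply(Zlist, ncol, 1L)
  W <- Matrix::Matrix(X, sparse = TRUE)
  for (Z in Zlist) W <- cbind(W, Z)
  A <- list(); b <- list(); yy <- numeric(length(glev)); ng <- integer(length(glev))
  for (gi in seq_along(glev)) {
    rows <- which(resid_group == glev[gi])
    Wg <- W[rows, , drop = FALSE]
    A[[gi]] <- Matrix::forceSymmetric(Matrix::crossprod(Wg))
    b[[gi]] <- as.numeric(Matrix::crossprod(Wg, y[rows]))
    yy[gi] <- sum(y[rows]^2)
    ng[gi] <- length(rows)
  }
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  ranidx <- split(p + seq_len(sum(qs)), rep(seq_len(nr), qs))

  neg2ll <- function(theta) {
    sig_r <- exp(theta[seq_len(nr)])
    sig_e <- exp(theta[nr + seq_along(glev)])
    dvals <- c(rep(0, p), rep(1 / sig_r, qs))
    M <- A[[1]] / sig_e[1]
    rhs <- b[[1]] / sig_e[1]
    if (length(glev) > 1L)
      for (gi in 2:length(glev)) {
        M <- M + A[[gi]] / sig_e[gi]
        rhs <- rhs + b[[gi]] / sig_e[gi]
      }
    M <- M + Matrix::Diagonal(x = dvals)
    ch <- try(Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE,
                               super = NA), silent = TRUE)
    if (inherits(ch, "try-error")) return(list(val = 1e10))
    ld <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    ypy <- sum(yy / sig_e) - sum(sol * rhs)
    val <- sum(ng * log(sig_e)) + sum(qs * log(sig_r)) + ld + ypy +
      (n - p) * log(2 * pi)
    list(val = val, sol = sol)
  }
  obj <- function(theta) neg2ll(theta)$val
  # method-of-moments starting values from the family-mean decomposition
  fam1 <- Zlist[[1]] %*% seq_len(qs[1])
  famf <- factor(as.integer(fam1))
  gm <- tapply(y, famf, mean)
  within <- y - gm[famf]
  s_e0 <- max(var(as.numeric(within)) * n / max(n - qs[1], 1), vy * 1e-4)
  nbar <- n / qs[1]
  s_f0 <- max(var(as.numeric(gm)) - s_e0 / nbar, vy * 1e-3)
  start <- log(c(s_f0, rep(max(s_f0 / 4, vy * 1e-3), nr - 1),
                 rep(s_e0, length(glev))))
  lo <- log(vy * 1e-8)
  hi <- log(vy * 1e4)
  opt <- nlminb(start, obj, lower = lo, upper = hi,
                control = list(iter.max = 300, eval.max = 600,
                               rel.tol = 1e-7))
  fin <- neg2ll(opt$par)
  sol <- fin$sol
  sig_r <- exp(opt$par[seq_len(nr)])
  sig_e <- exp(opt$par[nr + seq_along(glev)])
  # variances pinned at the floor are reported as zero
  floor_tol <- vy * 1e-7
  sig_r[sig_r < floor_tol] <- 0
  blups <- lapply(seq_len(nr), function(r)
    setNames(sol[ranidx[[r]]], colnames(Zlist[[r]])))
  k <- nr + length(glev)
  list(sigma2_random = setNames(sig_r, names(Zlist)),
       sigma2_resid = setNames(sig_e, glev),
       fixed = setNames(sol[seq_len(p)], colnames(X)),
       blups = setNames(blups, names(Zlist)),
       loglik = -fin$val / 2, aic = fin$val + 2 * k,
       convergence = opt$convergence)
}

ring_design <- function(d, include_sf = TRUE) {
  d$site <- as.factor(d$site)
  d$block <- as.factor(d$block)
  d$family <- as.factor(d$family)
  if (nlevels(d$family) < 2L) stopf("need at least 2 families")
  if (max(table(d$family)) < 2L)
    stopf("need at least one family with 2 or more observations")
  X <- if (nlevels(d$block) > 1L) {
    stats::model.matrix(~block, d)  # blocks are coded within site, so this
  } else {                          # spans site + block-within-site
    matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stopf("singular fixed-effect design: term(s) %s are confounded",
          paste(bad, collapse = ", "))
  }
  Zf <- Matrix::sparse.model.matrix(~0 + family, d)
  colnames(Zf) <- levels(d$family)
  Zlist <- list(family = Zf)
  if (include_sf && nlevels(d$site) > 1L) {
    sf <- droplevels(interaction(d$site, d$family, sep = ":"))
    Zsf <- Matrix::sparse.model.matrix(~0 + sf)
    colnames(Zsf) <- levels(sf)
    Zlist$site_family <- Zsf
  }
  list(d = d, X = X, Zlist = Zlist)
}

#' Fit the joint-site mixed model for one trait at one ring
#'
#' Estimates variance components by REML and returns the family BLUPs
#' (estimated breeding values, EBVs). Site and block-within-site enter as
#' fixed effects, family and site-by-family as random, and each site has its
#' own residual variance. With a single site the site-by-family term and the
#' second residual variance drop automatically.
#'
#' @param rings Long-format ring table (see [simulate_phenotypes()] or
#'   [read_rings()]).
#' @param trait Name of the trait column to analyse.
#' @param ring Ring (cambial age) to analyse.
#' @param include_sf Include the site-by-family interaction.
#' @return List with `varcomp` (sigma_f2, sigma_sf2, per-site residuals),
#'   `ebv` (data.frame family/ring/trait/ebv), `loglik`, `aic`.
#' @export
fit_ring_model <- function(rings, trait, ring, include_sf = TRUE) {
  check_ring_table(rings, trait)
  d <- rings[rings$ring == ring & !is.na(rings[[trait]]), , drop = FALSE]
  if (!nrow(d)) stopf("no observations for trait '%s' at ring %s", trait, ring)
  des <- ring_design(d, include_sf = include_sf)
  fit <- reml_mme(des$d[[trait]], des$X, des$Zlist, des$d$site)
  ebv <- data.frame(family = names(fit$blups$family),
                    ring = ring, trait = trait,
                    ebv = as.numeric(fit$blups$family),
                    stringsAsFactors = FALSE)
  list(varcomp = list(sigma_f2 = unname(fit$sigma2_random["family"]),
                      sigma_sf2 = if ("site_family" %in%
                                      names(fit$sigma2_random))
                        unname(fit$sigma2_random["site_family"]) else NA_real_,
                      sigma_e2 = fit$sigma2_resid),
       ebv = ebv, fixed = fit$fixed, loglik = fit$loglik, aic = fit$aic,
       convergence = fit$convergence)
}

check_ring_table <- function(rings, trait = NULL) {
  need <- c("individual", "site", "block", "family", "ring")
  miss <- setdiff(need, names(rings))
  if (length(miss))
    stopf("ring table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!is.null(trait) && !trait %in% names(rings))
    stopf("trait column '%s' not found in ring table", trait)
  invisible(TRUE)
}

#' EBV trajectories across all rings
#'
#' Applies [fit_ring_model()] to every ring of every requested trait and
#' stacks the family BLUPs into per-family EBV trajectories. When
#' `model_selection = "aic"` the model with and without the site-by-family
#' term are compared per ring and the lower-AIC fit kept.
#'
#' @param rings Long-format ring table.
#' @param traits Trait columns to analyse (default: all non-design columns).
#' @param model_selection `"none"` (full model) or `"aic"`.
#' @return data.frame with columns family, ring, trait, ebv.
#' @export
ebv_trajectories <- function(rings, traits = NULL,
                             model_selection = c("none", "aic")) {
  model_selection <- match.arg(model_selection)
  check_ring_table(rings)
  traits <- traits %||%
    setdiff(names(rings), c("individual", "site", "block", "family", "ring"))
  ringv <- sort(unique(rings$ring))
  if (length(ringv) < 3L)
    stopf("fewer than 3 rings available; spline fitting needs more ages")
  out <- vector("list", length(traits) * length(ringv))
  i <- 0L
  for (tr in traits) {
    for (rg in ringv) {
      fit <- fit_ring_model(rings, tr, rg, include_sf = TRUE)
      if (model_selection == "aic") {
        alt <- fit_ring_model(rings, tr, rg, include_sf = FALSE)
        if (alt$aic < fit$aic) fit <- alt
      }
      i <- i + 1L
      out[[i]] <- fit$ebv
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
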