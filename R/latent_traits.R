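# Two-knot linear spline summarizing an EBV trajectory:
#   y(t) = beta0 + beta1*t + beta2*(t-K1)+ + beta3*(t-K2)+ + eps
# The four least-squares estimates are the latent traits used as GWAS
# responses; beta2/beta3 are slope changes at the knots, not segment slopes.

#' Fit the two-knot linear spline to one trajectory
#'
#' Ordinary least squares on the truncated-line basis
#' \[1, t, (t-K1)+, (t-K2)+\].
#'
#' @param t Vector of ages (ring indices).
#' @param y Trajectory values.
#' @param K1,K2 Knot positions, strictly inside the age range with at least
#'   one point beyond each knot.
#' @return A `spline_fit` list: beta0..beta3, K1, K2, rss, sigma2 (residual
#'   variance, rss / (n - 4)), fitted values.
#' @export
fit_linear_spline <- function(t, y, K1, K2) {
  stopifnot(length(t) == length(y))
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(unique(t)) < 5L)
    stopf("need at least 5 distinct time points, got %d", length(unique(t)))
  if (!(K1 < K2)) stopf("knots must satisfy K1 < K2")
  if (K1 <= min(t) || K2 >= max(t))
    stopf("knots must lie strictly inside the time range")
  if (!any(t > K1)) stopf("no time points beyond knot K1 = %s", K1)
  if (!any(t > K2)) stopf("no time points beyond knot K2 = %s", K2)
  X <- cbind(1, t, pmax(t - K1, 0), pmax(t - K2, 0))
  fit <- lm.fit(X, y)
  if (fit$rank < 4L) {
    # identify which truncated column is degenerate
    bad <- if (length(unique(pmax(t - K2, 0))) < 2L) "K2" else "K1"
    stopf("rank-deficient spline design: no information past knot %s", bad)
  }
  beta <- unname(fit$coefficients)
  rss <- sum(fit$residuals^2)
  structure(list(beta0 = beta[1], beta1 = beta[2], beta2 = beta[3],
                 beta3 = beta[4], K1 = K1, K2 = K2, rss = rss,
                 sigma2 = if (length(y) > 4L) rss / (length(y) - 4L) else 0,
                 fitted = as.numeric(X %*% beta)),
            class = "spline_fit")
}

#' Choose global knots minimizing total residual sum of squares
#'
#' Evaluates every candidate knot pair on every trajectory and returns the
#' pair with the smallest summed RSS; ties break to the smaller K1 then the
#' smaller K2. Knots are global per trait so latent traits are comparable
#' across individuals.
#'
#' @param trajectories data.frame with columns `id`, `t`, `y` (one row per
#'   observation; several individuals stacked).
#' @param candidate_grid Two-column matrix/data.frame of (K1, K2) pairs; by
#'   default all integer pairs 3 <= K1 < K2 <= max(t) - 2.
#' @return Numeric `c(K1, K2)`.
#' @export
choose_knots <- function(trajectories, candidate_grid = NULL) {
  stopifnot(all(c("id", "t", "y") %in% names(trajectories)))
  tmax <- max(trajectories$t)
  if (is.null(candidate_grid)) {
    ks <- expand.grid(K1 = 3:(tmax - 2L), K2 = 3:(tmax - 2L))
    candidate_grid <- ks[ks$K1 < ks$K2, c("K1", "K2")]
  }
  candidate_grid <- as.matrix(candidate_grid)
  if (!nrow(candidate_grid)) stopf("empty candidate knot grid")
  # deterministic tie-break: scan in (K1, K2) ascending order, strict improvement
  ord <- order(candidate_grid[, 1], candidate_grid[, 2])
  candidate_grid <- candidate_grid[ord, , drop = FALSE]
  split_tr <- split(trajectories[c("t", "y")], trajectories$id)
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(candidate_grid))) {
    k <- candidate_grid[i, ]
    tot <- 0
    ok <- TRUE
    for (tr in split_tr) {
      f <- try(fit_linear_spline(tr$t, tr$y, k[1], k[2]), silent = TRUE)
      if (inherits(f, "try-error")) { ok <- FALSE; break }
      tot <- tot + f$rss
    }
    if (ok && tot < best_rss - 1e-12) {
      best_rss <- tot
      best <- k
    }
  }
  if (is.null(best)) stopf("no candidate knot pair admits a valid spline fit")
  unname(best)
}

#' Latent-trait matrix from EBV trajectories
#'
#' Fits the two-knot spline per family per trait and returns the four latent
#' traits. Individuals whose trajectory cannot support the fit (too few
#' rings, no points beyond a knot) are dropped with a message.
#'
#' @param ebvs data.frame with columns family, ring, trait, ebv
#'   (see [ebv_trajectories()]).
#' @param knots Either `c(K1, K2)` applied to every trait, or a data.frame
#'   with columns trait, K1, K2. Default `c(6, 10)`.
#' @return data.frame: individual, trait, beta0..beta3, K1, K2, sigma2;
#'   ordered by individual id within trait.
#' @export
latent_trait_matrix <- function(ebvs, knots = c(6, 10)) {
  stopifnot(all(c("family", "ring", "trait", "ebv") %in% names(ebvs)))
  out <- list()
  for (tr in unique(ebvs$trait)) {
    if (is.data.frame(knots)) {
      kk <- knots[knots$trait == tr, ]
      if (!nrow(kk)) stopf("no knots supplied for trait '%s'", tr)
      k1 <- kk$K1[1]; k2 <- kk$K2[1]
    } else {
      k1 <- knots[1]; k2 <- knots[2]
    }
    d <- ebvs[ebvs$trait == tr, ]
    ids <- sort(unique(d$family))
    dropped <- character()
    rows <- list()
    for (id in ids) {
      di <- d[d$family == id, ]
      f <- try(fit_linear_spline(di$ring, di$ebv, k1, k2), silent = TRUE)
      if (inherits(f, "try-error")) {
        dropped <- c(dropped, id)
        next
      }
      rows[[id]] <- data.frame(individual = id, trait = tr,
                               beta0 = f$beta0, beta1 = f$beta1,
                               beta2 = f$beta2, beta3 = f$beta3,
                               K1 = k1, K2 = k2, sigma2 = f$sigma2,
                               stringsAsFactors = FALSE)
    }
    if (length(dropped))
      message(sprintf("latent_trait_matrix: dropped %d individual(s) for trait %s: %s",
                      length(dropped), tr,
                      paste(utils::head(dropped, 5), collapse = ", ")))
    out[[tr]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
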