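#' Simulation configuration for a two-site half-sib progeny trial
#'
#' Defines the conditions of the emulated study design: genotyped mother
#' trees (one per half-sib family), two field sites with blocks, six progeny
#' per family per site, and 14 annual rings per tree. Genotypes are organised
#' in contigs with within-contig linkage disequilibrium decaying on a
#' physical-distance scale, and the population carries K-way admixed
#' structure.
#'
#' @param n_individuals Number of genotyped mother trees.
#' @param n_contigs Number of contigs in the SNP panel.
#' @param snps_per_contig SNPs per contig.
#' @param contig_length_bp Contig length in base pairs.
#' @param ld_decay_bp Distance scale (bp) of within-contig LD decay.
#' @param admixture_k Number of latent subpopulations.
#' @param admixture_alpha Dirichlet concentration for individual admixture
#'   proportions (small values give near-pure ancestries).
#' @param subpop_fst Balding-Nichols differentiation between subpopulations.
#' @param maf_range Interval in (0, 0.5] from which SNP minor-allele
#'   frequencies are drawn.
#' @param missing_rate Proportion of genotype calls set to missing,
#'   uniformly at random.
#' @param n_families Number of half-sib families; must equal
#'   `n_individuals` (one genotyped mother per family).
#' @param progeny_per_family_per_site Phenotyped progeny per family per site.
#' @param n_sites Number of field sites.
#' @param blocks_per_site Randomised blocks within each site.
#' @param n_rings Number of annual rings (cambial ages) measured per tree.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 517, n_contigs = 100,
                       snps_per_contig = 20, contig_length_bp = 10000,
                       ld_decay_bp = 1000, admixture_k = 2,
                       admixture_alpha = 0.5, subpop_fst = 0.05,
                       maf_range = c(0.05, 0.5), missing_rate = 0.02,
                       n_families = NULL,
                       progeny_per_family_per_site = 6, n_sites = 2,
                       blocks_per_site = 10, n_rings = 14, seed = 1) {
  n_families <- n_families %||% n_individuals
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_contigs = as.integer(n_contigs),
              snps_per_contig = as.integer(snps_per_contig),
              contig_length_bp = as.integer(contig_length_bp),
              ld_decay_bp = as.numeric(ld_decay_bp),
              admixture_k = as.integer(admixture_k),
              admixture_alpha = as.numeric(admixture_alpha),
              subpop_fst = as.numeric(subpop_fst),
              maf_range = as.numeric(maf_range),
              missing_rate = as.numeric(missing_rate),
              n_families = as.integer(n_families),
              progeny_per_family_per_site =
                as.integer(progeny_per_family_per_site),
              n_sites = as.integer(n_sites),
              blocks_per_site = as.integer(blocks_per_site),
              n_rings = as.integer(n_rings),
              seed = as.integer(seed))
  counts <- c("n_individuals", "n_contigs", "snps_per_contig",
              "contig_length_bp", "admixture_k", "n_families",
              "progeny_per_family_per_site", "n_sites", "blocks_per_site",
              "n_rings")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) stopf("'%s' must be >= 1", nm)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stopf("'missing_rate' must be in [0, 1)")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stopf("'maf_range' must be an interval within (0, 0.5]")
  if (cfg$n_families != cfg$n_individuals)
    stopf("'n_families' must equal 'n_individuals' (one mother per family)")
  if (cfg$snps_per_contig > cfg$contig_length_bp)
    stopf("more SNPs per contig than base pairs")
  if (cfg$ld_decay_bp <= 0) stopf("'ld_decay_bp' must be positive")
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

#' Simulate a mother-tree SNP panel with LD and admixed structure
#'
#' Haplotypes are drawn from a Gaussian AR(1) copula along each contig:
#' adjacent latent values correlate as `exp(-distance / ld_decay_bp)` and are
#' thresholded at subpopulation-specific allele frequencies
#' (Balding-Nichols differentiation at `subpop_fst`). Each individual's two
#' haplotypes per contig are independent given ancestry, so genotypes obey
#' Hardy-Weinberg within a subpopulation, and within-contig genotype
#' correlation decays monotonically with physical distance.
#'
#' @param config A [sim_config()].
#' @return A `genotype_matrix`: list with `dosage` (individuals x SNPs,
#'   values 0/1/2/NA), `info` (SNP metadata: id, contig, 1-based position,
#'   alleles, empirical MAF, missing fraction) and `admixture` (individual
#'   ancestry proportions).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$snps_per_contig < 2L)
    warning("snps_per_contig < 2: within-contig LD is undefined")
  set.seed(child_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  K <- config$admixture_k
  s <- config$snps_per_contig
  S <- s * config$n_contigs

  m <- config$maf_range[1] +
    (config$maf_range[2] - config$maf_range[1]) * rbeta(S, 1, 3)
  p_base <- ifelse(runif(S) < 0.5, m, 1 - m)
  Fst <- config$subpop_fst
  if (K > 1L && Fst > 0) {
    a1 <- p_base * (1 - Fst) / Fst
    a2 <- (1 - p_base) * (1 - Fst) / Fst
    pk <- vapply(seq_len(K), function(k) rbeta(S, a1, a2), numeric(S))
  } else {
    pk <- matrix(p_base, S, K)
  }
  Q <- rdirichlet_mat(n, rep(config$admixture_alpha, K))
  Qh <- Q[rep(seq_len(n), each = 2L), , drop = FALSE]
  cumQ <- Qh %*% upper.tri(diag(K), diag = TRUE)
  cumQ[, K] <- 1

  dosage <- matrix(NA_integer_, n, S)
  contig <- integer(S)
  pos <- integer(S)
  for (cg in seq_len(config$n_contigs)) {
    idx <- ((cg - 1L) * s + 1L):(cg * s)
    cpos <- sort(sample.int(config$contig_length_bp, s))
    contig[idx] <- cg
    pos[idx] <- cpos
    z <- rowSums(runif(2L * n) > cumQ) + 1L
    E <- matrix(rnorm(2L * n * s), 2L * n, s)
    H <- E
    if (s > 1L) {
      phi <- exp(-diff(cpos) / config$ld_decay_bp)
      for (j in 2L:s)
        H[, j] <- phi[j - 1L] * H[, j - 1L] +
          sqrt(1 - phi[j - 1L]^2) * E[, j]
    }
    thr <- qnorm(pk[idx, , drop = FALSE])  # s x K
    alle <- H < t(thr)[z, , drop = FALSE]
    odd <- seq(1L, 2L * n, by = 2L)
    dosage[, idx] <- alle[odd, , drop = FALSE] + alle[odd + 1L, , drop = FALSE]
  }
  if (config$missing_rate > 0) {
    miss <- runif(length(dosage)) < config$missing_rate
    dosage[miss] <- NA_integer_
  }
  ids <- sprintf("I%04d", seq_len(n))
  snp_id <- sprintf("MA_%d_%d", contig, pos)
  rownames(dosage) <- ids
  colnames(dosage) <- snp_id
  rownames(Q) <- ids
  g <- genotype_matrix(dosage,
                       info = data.frame(snp_id = snp_id,
                                         contig = paste0("MA_", contig),
                                         pos = pos, ref = "A", alt = "G",
                                         stringsAsFactors = FALSE))
  g$admixture <- Q
  g
}

#' Construct a genotype matrix container
#'
#' @param dosage Individuals x SNPs matrix of 0/1/2 dosages with NA missing.
#' @param info SNP metadata (snp_id, contig, pos, ref, alt); derived from
#'   column names of `dosage` when omitted (expects `MA_<contig>_<pos>` ids).
#' @return A `genotype_matrix` list; empirical MAF and missing fraction are
#'   (re)computed on construction.
#' @export
genotype_matrix <- function(dosage, info = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stopf("dosages must be 0, 1, 2 or NA")
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("MA_1_%d", seq_len(ncol(dosage)))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("I%04d", seq_len(nrow(dosage)))
  if (is.null(info)) {
    parts <- strsplit(colnames(dosage), "_", fixed = TRUE)
    ok <- all(vapply(parts, length, 1L) >= 3L)
    info <- data.frame(
      snp_id = colnames(dosage),
      contig = if (ok) vapply(parts, function(x)
        paste(x[-length(x)], collapse = "_"), "") else "MA_1",
      pos = if (ok) as.integer(vapply(parts, function(x)
        x[length(x)], "")) else seq_len(ncol(dosage)),
      ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  stopifnot(nrow(info) == ncol(dosage))
  af <- colMeans(dosage, na.rm = TRUE) / 2
  info$maf <- pmin(af, 1 - af)
  info$missing <- colMeans(is.na(dosage))
  structure(list(dosage = dosage, info = info), class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d contigs), %.1f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$info$contig)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Declare a simulated QTL acting on a latent trait
#'
#' @param snp_id SNP identifier present in the simulated panel.
#' @param latent_trait One of `"intercept"`, `"slope"`, `"beta2"`, `"beta3"`.
#' @param trait_name Phenotype the QTL acts on (must match an archetype).
#' @param additive_effect Per-allele additive effect on the latent trait; when
#'   `target_pve` is given this only sets the additive:dominance shape and is
#'   rescaled to hit the target.
#' @param dominance_effect Heterozygote deviation (added when dosage is 1).
#' @param target_pve Proportion of latent-trait variance the QTL should
#'   explain, in \[0, 0.5\]; effects are calibrated against the empirical
#'   dosage distribution of the panel.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(snp_id, latent_trait = c("intercept", "slope",
                                              "beta2", "beta3"),
                     trait_name = "WD", additive_effect = 1,
                     dominance_effect = 0, target_pve = NULL) {
  latent_trait <- match.arg(latent_trait)
  if (!is.null(target_pve) &&
      (target_pve < 0 || target_pve > 0.5))
    stopf("target_pve must lie in [0, 0.5]")
  structure(list(snp_id = snp_id, latent_trait = latent_trait,
                 trait_name = trait_name,
                 additive_effect = additive_effect,
                 dominance_effect = dominance_effect,
                 target_pve = target_pve), class = "qtl_spec")
}

#' Default trajectory archetype: ring wood density
#'
#' One trait ("WD", kg m^-3) whose mean trajectory over cambial ages 1-14
#' rises steeply in the juvenile phase, flattens at the first knot (age 6)
#' and steepens again at the second knot (age 10).
#' @return data.frame of per-trait spline parameters and knots.
#' @export
default_archetypes <- function() {
  data.frame(trait = "WD", beta0 = 400, beta1 = 12, beta2 = -8, beta3 = 6,
             K1 = 6, K2 = 10, stringsAsFactors = FALSE)
}

#' Default variance components of the simulated trial
#'
#' Family (mother) latent-trait standard deviations, site-by-family
#' interaction, site-specific ring residuals, block effects and additive
#' site offsets, in trait units (kg m^-3 for the density archetype).
#' @return Named list of variance parameters.
#' @export
default_variances <- function() {
  list(latent_sd = c(beta0 = 20, beta1 = 3, beta2 = 2, beta3 = 2),
       sigma_sf = 8, sigma_e = c(25, 30), sigma_block = 5,
       site_effect = c(0, 15))
}

#' All-zero variance components (deterministic trajectories)
#' @return Named list with every variance parameter at zero.
#' @export
zero_variances <- function() {
  list(latent_sd = c(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0),
       sigma_sf = 0, sigma_e = c(0, 0), sigma_block = 0,
       site_effect = c(0, 0))
}

#' Bundle planted QTLs, archetypes and variance components
#'
#' @param qtls List of [qtl_spec()] objects (possibly empty: global null).
#' @param archetypes Per-trait spline parameters, as [default_archetypes()].
#' @param variances Variance components, as [default_variances()].
#' @param seed Seed recorded for reproducibility.
#' @return A `truth_set` list.
#' @export
truth_set <- function(qtls = list(), archetypes = default_archetypes(),
                      variances = default_variances(), seed = 1) {
  if (inherits(qtls, "qtl_spec")) qtls <- list(qtls)
  stopifnot(all(vapply(qtls, inherits, TRUE, "qtl_spec")))
  if (!all(vapply(qtls, `[[`, "", "trait_name") %in% archetypes$trait))
    stopf("every QTL trait_name must match an archetype trait")
  structure(list(qtls = qtls, archetypes = archetypes,
                 variances = variances, seed = as.integer(seed)),
            class = "truth_set")
}

#' Evaluate the two-knot linear spline
#'
#' @param beta Numeric vector (beta0, beta1, beta2, beta3).
#' @param K1,K2 Knot positions (cambial age).
#' @param t Vector of ages.
#' @return Trajectory values at `t`.
#' @export
spline_eval <- function(beta, K1, K2, t) {
  beta[1] + beta[2] * t + beta[3] * pmax(t - K1, 0) + beta[4] * pmax(t - K2, 0)
}

latent_cols <- c(intercept = "beta0", slope = "beta1",
                 beta2 = "beta2", beta3 = "beta3")

#' Simulate longitudinal progeny phenotypes from planted latent-trait QTLs
#'
#' Each mother's latent spline parameters are the trait archetype plus
#' polygenic deviations plus the planted QTL terms (additive `a * dosage` and
#' dominance `d * 1[dosage = 1]`, evaluated on the mother's genotype). Progeny
#' ring values are the mother trajectory plus site, block-within-site and
#' site-by-family effects and independent per-ring residual noise with
#' site-specific variance.
#'
#' QTLs with a `target_pve` are calibrated against the empirical dosage
#' variance so the realized share of latent-trait variance matches the
#' target; realized effects and PVE are recorded in the `"truth_realized"`
#' attribute of the result.
#'
#' @param genotypes A `genotype_matrix` of the mothers.
#' @param truth A [truth_set()].
#' @param config The [sim_config()] used for the genotypes.
#' @return Long-format ring table: one row per progeny x ring with columns
#'   `individual`, `site`, `block`, `family`, `ring` and one column per trait.
#' @export
simulate_phenotypes <- function(genotypes, truth, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(truth, "truth_set"), inherits(config, "sim_config"))
  if (config$n_rings < 5L) stopf("n_rings must be >= 5 for spline fitting")
  for (q in truth$qtls)
    if (!q$snp_id %in% colnames(genotypes$dosage))
      stopf("QTL SNP '%s' is not in the genotype panel", q$snp_id)
  set.seed(child_seed(config$seed, "phenotypes"))
  n_fam <- config$n_families
  mothers <- rownames(genotypes$dosage)[seq_len(n_fam)]
  vv <- truth$variances
  sigma_e <- rep_len(vv$sigma_e, config$n_sites)
  site_effect <- rep_len(vv$site_effect, config$n_sites)

  # latent parameters per mother per trait
  realized <- list()
  latent <- list()
  for (ti in seq_len(nrow(truth$archetypes))) {
    arch <- truth$archetypes[ti, ]
    B <- cbind(beta0 = rnorm(n_fam, arch$beta0, vv$latent_sd["beta0"]),
               beta1 = rnorm(n_fam, arch$beta1, vv$latent_sd["beta1"]),
               beta2 = rnorm(n_fam, arch$beta2, vv$latent_sd["beta2"]),
               beta3 = rnorm(n_fam, arch$beta3, vv$latent_sd["beta3"]))
    rownames(B) <- mothers
    qtls <- Filter(function(q) q$trait_name == arch$trait, truth$qtls)
    qre <- list()
    if (length(qtls)) {
      by_par <- split(qtls, vapply(qtls, `[[`, "", "latent_trait"))
      for (par in names(by_par)) {
        col <- latent_cols[[par]]
        tot_target <- sum(vapply(by_par[[par]], function(q)
          q$target_pve %||% 0, 0))
        if (tot_target >= 1) stopf("target PVEs on '%s' sum to >= 1", par)
        sigL2 <- vv$latent_sd[[col]]^2 / (1 - tot_target)
        for (q in by_par[[par]]) {
          g <- genotypes$dosage[mothers, q$snp_id]
          g[is.na(g)] <- mean(g, na.rm = TRUE)
          e0 <- q$additive_effect * g +
            q$dominance_effect * as.numeric(g == 1)
          a <- q$additive_effect; d <- q$dominance_effect
          if (!is.null(q$target_pve)) {
            v0 <- var(e0)
            if (v0 <= 0)
              stopf("QTL SNP '%s' is monomorphic in the panel", q$snp_id)
            sc <- sqrt(q$target_pve * sigL2 / v0)
            e0 <- e0 * sc; a <- a * sc; d <- d * sc
          }
          B[, col] <- B[, col] + e0
          qre[[q$snp_id]] <- list(snp_id = q$snp_id, trait = arch$trait,
                                  latent_trait = par, additive = a,
                                  dominance = d)
        }
      }
    }
    # realized PVE against the final latent variance
    for (id in names(qre)) {
      q <- qre[[id]]
      col <- latent_cols[[q$latent_trait]]
      g <- genotypes$dosage[mothers, id]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      e <- q$additive * g + q$dominance * as.numeric(g == 1)
      qre[[id]]$realized_pve <- var(e) / var(B[, col])
    }
    latent[[arch$trait]] <- B
    realized[[arch$trait]] <- qre
  }

  # trial layout
  npf <- config$progeny_per_family_per_site
  n_prog <- n_fam * config$n_sites * npf
  fam_i <- rep(rep(seq_len(n_fam), each = npf), times = config$n_sites)
  site_i <- rep(seq_len(config$n_sites), each = n_fam * npf)
  block_i <- sample.int(config$blocks_per_site, n_prog, replace = TRUE)
  block_eff <- matrix(rnorm(config$n_sites * config$blocks_per_site,
                            0, vv$sigma_block),
                      config$n_sites, config$blocks_per_site)
  sf_eff <- matrix(rnorm(config$n_sites * n_fam, 0, vv$sigma_sf),
                   config$n_sites, n_fam)
  prog_id <- sprintf("%s_S%d_P%d", mothers[fam_i], site_i,
                     ave(fam_i, fam_i, site_i, FUN = seq_along))

  rings <- seq_len(config$n_rings)
  out <- data.frame(
    individual = rep(prog_id, each = config$n_rings),
    site = paste0("S", rep(site_i, each = config$n_rings)),
    block = sprintf("S%d_B%d", rep(site_i, each = config$n_rings),
                    rep(block_i, each = config$n_rings)),
    family = rep(mothers[fam_i], each = config$n_rings),
    ring = rep(rings, times = n_prog),
    stringsAsFactors = FALSE)
  for (ti in seq_len(nrow(truth$archetypes))) {
    arch <- truth$archetypes[ti, ]
    B <- latent[[arch$trait]]
    traj <- t(apply(B, 1, spline_eval, K1 = arch$K1, K2 = arch$K2,
                    t = rings))  # n_fam x n_rings
    base <- traj[fam_i, , drop = FALSE] +
      site_effect[site_i] +
      block_eff[cbind(site_i, block_i)] +
      sf_eff[cbind(site_i, fam_i)]
    noise <- matrix(rnorm(n_prog * config$n_rings, 0, sigma_e[site_i]),
                    n_prog, config$n_rings)
    out[[arch$trait]] <- as.vector(t(base + noise))
  }
  attr(out, "truth_realized") <- list(latent = latent, qtls = realized,
                                      archetypes = truth$archetypes)
  out
}
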