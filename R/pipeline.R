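# End-to-end orchestration: genotype QC -> per-ring EBVs -> latent traits ->
# stability-selection LASSO per latent trait -> adaptive-LASSO PVE ->
# inheritance classification.

#' Stability-selection association scan over the four latent traits
#'
#' Runs [stability_selection()] and [call_qtls()] per latent trait of one
#' phenotype, then [adaptive_lasso_pve()] on any called QTLs.
#'
#' @param latent Latent-trait table for one trait
#'   (see [latent_trait_matrix()]).
#' @param genotypes A complete (filtered, imputed) `genotype_matrix` whose
#'   rows cover the latent table's individuals.
#' @param covariates Optional covariate matrix (e.g. PC scores), rows
#'   aligned with the genotype matrix rownames.
#' @param cfg A [stability_config()].
#' @param latent_traits Which of intercept/slope/beta2/beta3 to scan.
#' @return List: `qtls` (records with effect and PVE), `ssp` (per latent
#'   trait `ssp_table`s).
#' @export
assoc_scan <- function(latent, genotypes, covariates = NULL,
                       cfg = stability_config(),
                       latent_traits = c("intercept", "slope",
                                         "beta2", "beta3")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  trait <- unique(latent$trait)
  stopifnot(length(trait) == 1L)
  ids <- intersect(latent$individual, rownames(genotypes$dosage))
  if (length(ids) < 20L) stopf("fewer than 20 genotyped individuals")
  latent <- latent[match(ids, latent$individual), ]
  X <- genotypes$dosage[ids, , drop = FALSE]
  if (anyNA(X)) stopf("impute missing dosages before association")
  covs <- if (!is.null(covariates)) covariates[ids, , drop = FALSE]
  ssp <- list()
  recs <- list()
  for (lt in latent_traits) {
    y <- latent[[latent_cols[[lt]]]]
    tab <- stability_selection(X, y, covs, cfg)
    ssp[[lt]] <- tab
    called <- call_qtls(tab, trait = trait, latent_trait = lt)
    if (nrow(called)) {
      pve <- adaptive_lasso_pve(X, y, covs, called$snp_id, seed = cfg$seed)
      called <- merge(called, pve, by = "snp_id", sort = FALSE)
    } else {
      called$effect <- numeric(0)
      called$pve <- numeric(0)
    }
    recs[[lt]] <- called
  }
  qtls <- do.call(rbind, recs)
  rownames(qtls) <- NULL
  list(qtls = qtls, ssp = ssp)
}

#' Run the full functional association pipeline
#'
#' Simulated or provided inputs are pushed through SNP QC, mean imputation,
#' PCA covariates, per-ring REML/BLUP breeding values, two-knot spline
#' latent traits, the stability-selection LASSO scan and inheritance
#' classification.
#'
#' @param genotypes A `genotype_matrix` (mother trees).
#' @param rings Long-format progeny ring table.
#' @param knots `c(K1, K2)` or `"search"` for an RSS grid search.
#' @param cfg A [stability_config()].
#' @param n_pcs Number of PC covariates (default 5).
#' @param maf_min,max_missing QC thresholds.
#' @param traits Trait columns to analyse (default: all).
#' @param model_selection Passed to [ebv_trajectories()].
#' @return List: `qtls`, `inheritance`, `latent`, `ebvs`, `pca`, `ssp`,
#'   `knots`, `genotypes` (post-QC).
#' @export
run_pipeline <- function(genotypes, rings, knots = c(6, 10),
                         cfg = stability_config(), n_pcs = 5,
                         maf_min = 0.05, max_missing = 0.20,
                         traits = NULL, model_selection = "none") {
  check_ring_table(rings)
  traits <- traits %||%
    setdiff(names(rings), c("individual", "site", "block", "family", "ring"))
  g <- filter_snps(genotypes, maf_min = maf_min, max_missing = max_missing)
  g <- impute_mean(g)
  pca <- pca_covariates(g, n_pcs = n_pcs)
  ebvs <- ebv_trajectories(rings, traits = traits,
                           model_selection = model_selection)
  qtls <- list()
  ssp <- list()
  latents <- list()
  knots_used <- list()
  for (tr in traits) {
    etr <- ebvs[ebvs$trait == tr, ]
    kk <- knots
    if (identical(knots, "search")) {
      traj <- data.frame(id = etr$family, t = etr$ring, y = etr$ebv)
      kk <- choose_knots(traj)
    }
    lat <- latent_trait_matrix(etr, knots = kk)
    scan <- assoc_scan(lat, g, covariates = pca$scores, cfg = cfg)
    latents[[tr]] <- lat
    qtls[[tr]] <- scan$qtls
    ssp[[tr]] <- scan$ssp
    knots_used[[tr]] <- kk
  }
  qtls <- do.call(rbind, qtls)
  rownames(qtls) <- NULL
  inh <- NULL
  if (nrow(qtls)) {
    # inheritance on the raw latent phenotype of the matching latent trait
    inh <- do.call(rbind, lapply(seq_len(nrow(qtls)), function(i) {
      lt <- qtls$latent_trait[i]
      lat <- latents[[qtls$trait[i]]]
      ph <- data.frame(individual = lat$individual,
                       val = lat[[latent_cols[[lt]]]])
      names(ph)[2] <- qtls$trait[i]
      rec <- try(inheritance_records(qtls[i, , drop = FALSE], genotypes, ph),
                 silent = TRUE)
      if (inherits(rec, "try-error")) NULL else cbind(
        rec, latent_trait = lt, stringsAsFactors = FALSE)
    }))
  }
  list(qtls = qtls, inheritance = inh, latent = latents, ebvs = ebvs,
       pca = pca, ssp = ssp, knots = knots_used, genotypes = g)
}
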