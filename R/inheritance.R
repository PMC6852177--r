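# Mode of inheritance from genotype-class means:
#   2a = |G_BB - G_bb|,  d = G_Bb - 0.5 (G_BB + G_bb)
# and the d/a ratio, with the classification bands
#   additive/codominant |d/a| <= 0.50, partial-to-full dominance
#   0.50 < |d/a| <= 1.25, over-/underdominance |d/a| > 1.25
# (boundaries closed into the lower class).

#' Trait means per genotype class
#'
#' @param dosages Vector of 0/1/2 dosages (NA allowed).
#' @param phenotype Trait values aligned with `dosages`.
#' @return List: G_bb (dosage 0), G_Bb (dosage 1), G_BB (dosage 2) and the
#'   class counts. Errors name any empty class.
#' @export
genotype_class_means <- function(dosages, phenotype) {
  stopifnot(length(dosages) == length(phenotype))
  ok <- !is.na(dosages) & !is.na(phenotype)
  dosages <- dosages[ok]; phenotype <- phenotype[ok]
  counts <- vapply(0:2, function(k) sum(dosages == k), 1L)
  names(counts) <- c("bb", "Bb", "BB")
  cls <- c("bb (dosage 0)", "Bb (dosage 1)", "BB (dosage 2)")
  for (k in 1:3)
    if (counts[k] == 0L) stopf("empty genotype class %s", cls[k])
  list(G_bb = mean(phenotype[dosages == 0]),
       G_Bb = mean(phenotype[dosages == 1]),
       G_BB = mean(phenotype[dosages == 2]),
       counts = counts)
}

#' Additive and dominance decomposition of class means
#'
#' Accepts either the three class means, or a printed `(2a, d)` pair
#' directly. `a = 2a/2`; `d/a = d / a`; when `2a` is zero the ratio is
#' undefined and returned as `NA`.
#'
#' @param G_BB,G_Bb,G_bb Genotype-class means.
#' @param two_a,d Alternatively, the absolute homozygote difference and the
#'   heterozygote deviation.
#' @return List: two_a, d, d_over_a.
#' @export
dominance_ratio <- function(G_BB = NULL, G_Bb = NULL, G_bb = NULL,
                            two_a = NULL, d = NULL) {
  if (is.null(two_a)) {
    stopifnot(!is.null(G_BB), !is.null(G_Bb), !is.null(G_bb))
    two_a <- abs(G_BB - G_bb)
    d <- G_Bb - 0.5 * (G_BB + G_bb)
  }
  stopifnot(!is.null(d), all(two_a >= 0))
  ratio <- ifelse(two_a > 0, d / (two_a / 2), NA_real_)
  list(two_a = two_a, d = d, d_over_a = ratio)
}

#' Classify mode of inheritance from d/a
#'
#' @param d_over_a Ratio(s) of dominance to additive effect.
#' @return Character vector: `"additive"`, `"partial-to-full dominance"`,
#'   or `"over/underdominance"`; NA ratios stay NA.
#' @export
classify_inheritance <- function(d_over_a) {
  r <- abs(d_over_a)
  out <- rep(NA_character_, length(r))
  out[!is.na(r) & r <= 0.50] <- "additive"
  out[!is.na(r) & r > 0.50 & r <= 1.25] <- "partial-to-full dominance"
  out[!is.na(r) & r > 1.25] <- "over/underdominance"
  out
}

#' Inheritance records for called QTLs
#'
#' Computes class means, the additive/dominance decomposition and the
#' inheritance class for each (SNP, trait) pair, on raw (unadjusted)
#' phenotypes.
#'
#' @param qtls data.frame with columns snp_id and trait (e.g. from
#'   [call_qtls()]).
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes data.frame of per-individual trait values, rownames or
#'   `individual` column matching the genotype rows.
#' @return data.frame: snp_id, trait, class means, two_a, d, d_over_a, class.
#' @export
inheritance_records <- function(qtls, genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ph <- phenotypes
  if ("individual" %in% names(ph)) {
    rownames(ph) <- ph$individual
    ph$individual <- NULL
  }
  ids <- intersect(rownames(genotypes$dosage), rownames(ph))
  rows <- lapply(seq_len(nrow(qtls)), function(i) {
    snp <- qtls$snp_id[i]; tr <- qtls$trait[i]
    g <- genotypes$dosage[ids, snp]
    y <- ph[ids, tr]
    cm <- genotype_class_means(g, y)
    dr <- dominance_ratio(G_BB = cm$G_BB, G_Bb = cm$G_Bb, G_bb = cm$G_bb)
    data.frame(snp_id = snp, trait = tr, G_bb = cm$G_bb, G_Bb = cm$G_Bb,
               G_BB = cm$G_BB, two_a = dr$two_a, d = dr$d,
               d_over_a = dr$d_over_a,
               class = classify_inheritance(dr$d_over_a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mass index: biomass proxy from density and cross-sectional area
#'
#' `(individual density / population mean density) * (individual area /
#' population mean area)`; 1.0 for a tree at the population means.
#'
#' @param ind_density,ind_area Individual cross-sectional average density
#'   and area.
#' @param pop_mean_density,pop_mean_area Population means (must be > 0).
#' @return Mass index value(s).
#' @export
mass_index <- function(ind_density, ind_area, pop_mean_density,
                       pop_mean_area) {
  if (any(pop_mean_density <= 0) || any(pop_mean_area <= 0))
    stopf("population mean density and area must be positive")
  (ind_density / pop_mean_density) * (ind_area / pop_mean_area)
}
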