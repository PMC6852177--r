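# Readers and writers: minimal GT-only VCF 4.2, tab-separated phenotype and
# results tables (UTF-8, "." for missing), JSON truth sets. Every writer
# prepends a provenance header (package version, seed, config fingerprint).

provenance_line <- function(seed = NA, config = NULL, prefix = "# ") {
  sprintf("%sringwas %s; seed=%s; config=%s", prefix,
          as.character(packageVersion("ringwas")),
          as.character(seed),
          if (is.null(config)) "-" else config_fingerprint(config))
}

#' Read genotypes from a VCF file
#'
#' Bi-allelic rows only (multi-allelic rows are skipped with a count);
#' dosage is the alt-allele count of the GT field, `./.` is missing, phased
#' and unphased calls are equivalent. SNP ids follow the
#' `MA_<contig>_<pos>` convention with 1-based positions.
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stopf("no variant records in %s", path)
  multi <- grepl(",", fix$ALT %||% "") | is.na(fix$ALT)
  if (any(multi))
    message(sprintf("read_vcf: skipped %d multi-allelic row(s)", sum(multi)))
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt == "0/1" | gt == "1/0"] <- 1L
  dos[gt == "1/1"] <- 2L
  d <- t(dos)
  rownames(d) <- colnames(gt)
  pos <- as.integer(fix$POS)
  info <- data.frame(snp_id = sprintf("%s_%d", fix$CHROM, pos),
                     contig = fix$CHROM, pos = pos,
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  colnames(d) <- info$snp_id
  genotype_matrix(d, info = info)
}

#' Write a genotype matrix as minimal GT-only VCF 4.2
#'
#' @param g A `genotype_matrix` (integer dosages; imputed fractional
#'   dosages cannot be written).
#' @param path Output path (plain text).
#' @param seed,config Recorded in the provenance header line.
#' @export
write_vcf <- function(g, path, seed = NA, config = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (!all(d %in% c(0L, 1L, 2L) | is.na(d)))
    stopf("dosages must be integer 0/1/2 (write before imputation)")
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", ncol(d), nrow(d))
  for (k in 0:2) gt[t(d) == k] <- gtmap[k + 1]
  hdr <- c("##fileformat=VCFv4.2",
           provenance_line(seed, config, prefix = "##source="),
           sprintf("##contig=<ID=%s>", unique(g$info$contig)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- cbind(g$info$contig, g$info$pos, g$info$snp_id, g$info$ref,
                g$info$alt, ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a tab-separated table with a provenance header
#'
#' @param x data.frame.
#' @param path Output path.
#' @param seed,config Recorded in the header comment line.
#' @export
write_tsv <- function(x, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(seed, config), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", na.strings = c("NA", "."),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a longitudinal ring-trait table
#'
#' Tab-separated with mandatory columns individual, site, block, family,
#' ring and one column per trait; `#` lines are comments, `.` is missing.
#'
#' @param path TSV path.
#' @return data.frame ring table.
#' @export
read_rings <- function(path) {
  d <- read_tsv(path)
  check_ring_table(d)
  d
}

#' @rdname read_rings
#' @param rings Ring table to write.
#' @param seed,config Provenance.
#' @export
write_rings <- function(rings, path, seed = NA, config = NULL) {
  check_ring_table(rings)
  write_tsv(rings, path, seed = seed, config = config)
}

#' Write called QTLs in the catalogue layout
#'
#' Columns follow the conventional QTL-catalogue layout: Phenotype,
#' Latent_trait, SNP, Frequency, Effect, PVE_percent.
#'
#' @param qtls data.frame with snp_id, trait, latent_trait, frequency and
#'   optionally effect, pve.
#' @param path Output TSV.
#' @param seed,config Provenance.
#' @export
write_qtl_table <- function(qtls, path, seed = NA, config = NULL) {
  out <- data.frame(Phenotype = qtls$trait,
                    Latent_trait = qtls$latent_trait,
                    SNP = qtls$snp_id,
                    Frequency = qtls$frequency,
                    Effect = qtls$effect %||% rep(NA_real_, nrow(qtls)),
                    PVE_percent = qtls$pve %||% rep(NA_real_, nrow(qtls)))
  write_tsv(out, path, seed = seed, config = config)
}

#' Write inheritance records in the mode-of-inheritance layout
#'
#' @param records data.frame from [inheritance_records()].
#' @param path Output TSV.
#' @param seed,config Provenance.
#' @export
write_inheritance_table <- function(records, path, seed = NA, config = NULL) {
  out <- data.frame(Phenotype = records$trait, SNP = records$snp_id,
                    G_bb = records$G_bb, G_Bb = records$G_Bb,
                    G_BB = records$G_BB, two_a = records$two_a,
                    d = records$d, d_over_a = records$d_over_a,
                    Class = records$class)
  write_tsv(out, path, seed = seed, config = config)
}

#' Save / load a truth set as JSON
#'
#' @param truth A [truth_set()].
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  x <- list(qtls = lapply(truth$qtls, unclass),
            archetypes = truth$archetypes,
            variances = lapply(truth$variances, function(v)
              if (!is.null(names(v))) as.list(v) else v),
            seed = truth$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  qtls <- lapply(x$qtls, function(q)
    qtl_spec(q$snp_id, q$latent_trait, q$trait_name,
             q$additive_effect %||% 1, q$dominance_effect %||% 0,
             q$target_pve))
  arch <- do.call(rbind, lapply(x$archetypes, as.data.frame))
  for (j in which(vapply(arch, is.integer, TRUE))) arch[[j]] <- as.numeric(arch[[j]])
  vv <- lapply(x$variances, function(v) {
    u <- unlist(v)
    storage.mode(u) <- "double"
    u
  })
  truth_set(qtls, archetypes = arch, variances = vv, seed = x$seed)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized fields (all optional, with the package defaults otherwise):
#' `traits` (character), `knots` (length-2 or `"search"`), `n_pcs`,
#' `maf_min`, `max_missing`, `seed`, and a `stability` block with
#' `n_subsamples`, `subsample_fraction`, `EV`, `q`, `threshold`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A list with `traits`, `knots`, `n_pcs`, `maf_min`, `max_missing`
#'   and a [stability_config()] in `$stability`, ready to pass to
#'   [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  st <- x$stability %||% list()
  seed <- x$seed %||% 1L
  stab <- stability_config(
    n_subsamples = st$n_subsamples %||% 1000,
    subsample_fraction = st$subsample_fraction %||% 0.5,
    EV = st$EV %||% 1,
    q = st$q,
    threshold = st$threshold,
    seed = st$seed %||% seed)
  knots <- x$knots %||% c(6, 10)
  if (!identical(knots, "search")) knots <- as.numeric(unlist(knots))
  list(traits = x$traits,
       knots = knots,
       n_pcs = x$n_pcs %||% 5,
       maf_min = x$maf_min %||% 0.05,
       max_missing = x$max_missing %||% 0.20,
       seed = as.integer(seed),
       stability = stab)
}
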