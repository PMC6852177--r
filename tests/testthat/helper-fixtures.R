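# Fixture builders shared across test files; everything is generated in code.

# genotype matrix of independent SNPs at given allele frequencies
toy_genotypes <- function(n, mafs, seed = 1) {
  set.seed(seed)
  d <- vapply(mafs, function(p) rbinom(n, 2, p), numeric(n))
  colnames(d) <- sprintf("MA_%d_%d", seq_along(mafs), 100 * seq_along(mafs))
  genotype_matrix(d)
}

# balanced single-site trial: n_fam families x n_per progeny, one block
toy_rings_one_site <- function(n_fam = 5, n_per = 4, sigma_f = 2,
                               sigma_e = 1, mu = 10, seed = 1, ring = 1) {
  set.seed(seed)
  fam <- rep(sprintf("F%02d", seq_len(n_fam)), each = n_per)
  u <- rnorm(n_fam, 0, sigma_f)
  y <- mu + u[as.integer(factor(fam))] + rnorm(n_fam * n_per, 0, sigma_e)
  data.frame(individual = sprintf("i%03d", seq_along(fam)), site = "S1",
             block = "S1_B1", family = fam, ring = ring, WD = y,
             stringsAsFactors = FALSE)
}

# two-site single-ring data drawn directly from the joint-site model
sim_ring_direct <- function(n_fam, n_per_site, sigma_f2, sigma_sf2,
                            sigma_e2 = c(1, 1), n_blocks = 5, seed = 1) {
  set.seed(seed)
  fams <- sprintf("F%03d", seq_len(n_fam))
  u <- rnorm(n_fam, 0, sqrt(sigma_f2))
  rows <- list()
  for (s in 1:2) {
    sf <- rnorm(n_fam, 0, sqrt(sigma_sf2))
    blk <- rnorm(n_blocks, 0, 1)
    for (k in seq_len(n_fam)) {
      bidx <- sample.int(n_blocks, n_per_site, replace = TRUE)
      y <- 10 + (s - 1) * 3 + blk[bidx] + u[k] + sf[k] +
        rnorm(n_per_site, 0, sqrt(sigma_e2[s]))
      rows[[length(rows) + 1L]] <- data.frame(
        individual = sprintf("%s_S%d_%d", fams[k], s, seq_len(n_per_site)),
        site = paste0("S", s), block = sprintf("S%d_B%d", s, bidx),
        family = fams[k], ring = 1, WD = y, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "true_u") <- stats::setNames(u, fams)
  out
}
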