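# Independent oracles, deliberately written by a different route than the
# package implementations they check.

# Weir-Cockerham theta via the underlying nested random-effects ANOVA:
# allele copies (gametes) nested in individuals nested in populations.
# Variance components are recovered from the expected mean squares of the
# unbalanced nested ANOVA; theta = sigma2_pop / total.  This is the model
# from which the 1984 moment estimator is derived, so the two routes must
# agree exactly, but the code paths share nothing.
fst_anova_oracle <- function(geno, pop_map) {
  per_locus <- lapply(seq_len(nrow(geno)), function(l) {
    g <- geno[l, ]
    keep <- !is.na(g)
    g <- g[keep]
    pops <- pop_map[names(g)]
    # two gametes per individual, allele indicator 0/1
    y <- rbind(as.integer(g >= 1), as.integer(g == 2))  # one possible split
    # the split into gametes is arbitrary for unphased data; each column's
    # mean (p_ind) and within-individual SS depend only on the genotype
    n_i <- tapply(g, pops, length)
    if (length(n_i) < 2 || any(n_i < 1)) return(NULL)
    N <- sum(n_i)
    r <- length(n_i)
    p_ind <- colMeans(y)
    p_pop <- vapply(split(p_ind, pops), mean, numeric(1))
    p_all <- sum(n_i * p_pop) / N
    SSP <- sum(2 * n_i * (p_pop - p_all)^2)
    SSI <- sum(2 * (p_ind - p_pop[pops])^2)
    SSG <- sum((y[1, ] - p_ind)^2 + (y[2, ] - p_ind)^2)
    dfP <- r - 1
    dfI <- N - r
    dfG <- N
    MSP <- SSP / dfP; MSI <- SSI / dfI; MSG <- SSG / dfG
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    s2g <- MSG
    s2i <- (MSI - MSG) / 2
    s2p <- (MSP - MSI) / (2 * nc)
    c(a = s2p, b = s2i, c = s2g)
  })
  per_locus <- do.call(rbind, per_locus)
  denom <- rowSums(per_locus)
  usable <- is.finite(denom) & denom > 0
  sum(per_locus[usable, "a"]) / sum(denom[usable])
}

# spherical law of cosines: an independent great-circle formula
slc_km <- function(lon1, lat1, lon2, lat2, radius_km = 6378.137) {
  to_rad <- pi / 180
  d <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  radius_km * acos(pmin(1, pmax(-1, d)))
}

# random small genotype matrix for oracle-equivalence checks
random_genotypes <- function(n_loci, n_per_pop, n_pops = 2, maf = c(0.1, 0.9)) {
  pops <- paste0("p", seq_len(n_pops))
  ids <- paste0(rep(pops, each = n_per_pop), "_i",
                rep(seq_len(n_per_pop), n_pops))
  g <- matrix(NA_integer_, n_loci, length(ids),
              dimnames = list(paste0("L", seq_len(n_loci)), ids))
  for (p in seq_len(n_pops)) {
    freq <- runif(n_loci, maf[1], maf[2])
    cols <- (p - 1) * n_per_pop + seq_len(n_per_pop)
    g[, cols] <- rbinom(n_loci * n_per_pop, 2L, freq)
  }
  structure(list(genotypes = g,
                 populations = setNames(rep(pops, each = n_per_pop), ids)),
            class = "genotype_matrix")
}
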