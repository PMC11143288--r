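#' Simulate occurrence records with joined environmental variables
#'
#' Draws, for each configured species, environmental vectors from a
#' multivariate normal and coordinates uniformly within the species'
#' bounding box.  The default configuration gives the second species a
#' narrower spread on the first environmental variable, emulating the
#' one-niche-inside-the-other pattern seen between broadly sympatric
#' congeners.
#'
#' @param params A [simulation_params()] object; the `occurrence_species`
#'   element configures the draw.
#' @return Data frame of class `"occurrence_set"`: `species`, `lon`, `lat`
#'   plus one column per environmental variable.  No duplicated
#'   (species, lon, lat) rows.
#' @export
simulate_occurrences <- function(params) {
  set.seed(stage_seed(params$seed, "occurrences"))
  spp <- params$occurrence_species
  if (length(spp) < 2)
    stop("at least two species must be configured")
  out <- lapply(names(spp), function(sp) {
    cfg <- spp[[sp]]
    vars <- names(cfg$mean)
    R <- tryCatch(chol(cfg$cov),
                  error = function(e) stop("covariance for species '", sp,
                                           "' is not positive definite",
                                           call. = FALSE))
    z <- matrix(rnorm(cfg$n * length(vars)), cfg$n)
    env <- sweep(z %*% R, 2, cfg$mean, "+")
    colnames(env) <- vars
    bb <- cfg$bbox
    cbind(
      data.frame(species = sp,
                 lon = runif(cfg$n, bb[["lon_min"]], bb[["lon_max"]]),
                 lat = runif(cfg$n, bb[["lat_min"]], bb[["lat_max"]]),
                 stringsAsFactors = FALSE),
      as.data.frame(env)
    )
  })
  out <- do.call(rbind, out)
  out <- out[!duplicated(out[c("species", "lon", "lat")]), ]
  rownames(out) <- NULL
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Deterministic environmental vectors for named sites
#'
#' Evaluates a smooth latitude/longitude gradient for every configured
#' environmental variable at the given sites (population collection sites,
#' garden sites).  Deterministic — the environment is a function of the
#' location — so environmental distance co-varies with geographic distance
#' the way field data do, and a site co-located with a garden has
#' environmental distance exactly zero.
#'
#' @param params A [simulation_params()] object (variable names are taken
#'   from the occurrence configuration).
#' @param sites Data frame with `lon` and `lat` columns.
#' @return `sites` with one appended column per environmental variable.
#' @export
site_environment <- function(params, sites) {
  vars <- names(params$occurrence_species[[1]]$mean)
  lat0 <- mean(vapply(params$occurrence_species, function(s)
    mean(s$bbox[c("lat_min", "lat_max")]), numeric(1)))
  lon0 <- mean(vapply(params$occurrence_species, function(s)
    mean(s$bbox[c("lon_min", "lon_max")]), numeric(1)))
  for (j in seq_along(vars)) {
    wlat <- if (j %% 2 == 1) 0.6 else 0.15
    wlon <- if (j %% 2 == 1) 0.15 else 0.45
    sites[[vars[j]]] <- wlat * (sites$lat - lat0) + wlon * (sites$lon - lon0)
  }
  sites
}

#' Simulate structured biallelic genotypes (Balding-Nichols model)
#'
#' Per locus an ancestral allele frequency `p` is drawn uniformly within
#' `params$ancestral_freq`; each population's frequency is then
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` (or exactly `p` when `F = 0`),
#' and individual diploid genotypes are `Binomial(2, pop frequency)`.  The
#' expected Weir-Cockerham differentiation among the resulting populations
#' is `F`, which is what makes the estimator's parameter recovery testable.
#'
#' @param params A [simulation_params()] object (`fst_param`, `n_loci`,
#'   `n_ind_per_pop`, `missing_rate`).
#' @param populations Optional character vector of population names; by
#'   default all populations of all taxa in `population_table(params)`.
#' @return A `"genotype_matrix"`: list with `genotypes` (loci x individuals
#'   integer matrix of alternative-allele counts 0/1/2, `NA` = missing) and
#'   `populations` (named character vector, individual -> population).
#' @export
simulate_genotypes <- function(params, populations = NULL) {
  set.seed(stage_seed(params$seed, "genotypes"))
  if (is.null(populations))
    populations <- population_table(params)$population
  if (length(populations) < 2)
    stop("at least two populations are required")
  F <- params$fst_param
  L <- params$n_loci
  n <- params$n_ind_per_pop
  p_anc <- runif(L, params$ancestral_freq[1], params$ancestral_freq[2])
  ind_pop <- rep(populations, each = n)
  ids <- sprintf("%s_i%d", ind_pop, rep(seq_len(n), times = length(populations)))
  geno <- matrix(NA_integer_, nrow = L, ncol = length(ids),
                 dimnames = list(sprintf("locus_%05d", seq_len(L)), ids))
  for (pop in populations) {
    if (F > 0) {
      shape_mult <- (1 - F) / F
      p_pop <- rbeta(L, p_anc * shape_mult, (1 - p_anc) * shape_mult)
    } else {
      p_pop <- p_anc
    }
    cols <- which(ind_pop == pop)
    geno[, cols] <- rbinom(L * length(cols), 2L, p_pop)
  }
  if (params$missing_rate > 0) {
    drop <- runif(length(geno)) < params$missing_rate
    geno[drop] <- NA_integer_
  }
  structure(list(genotypes = geno,
                 populations = setNames(ind_pop, ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d individuals, %d populations\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$populations))))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Simulate a reciprocal-transplant fitness dataset
#'
#' Each genotype is planted (clonally) in every garden; one taxon can be
#' replicated more than once per garden (the default plants the rare taxon
#' twice, giving 321 plants per garden).  Trait values are drawn from a
#' generalized linear predictor
#' `eta = mu + taxon + garden + taxon:garden + pop + genotype`, where the
#' population effect is `-b * d(pop, garden) + N(0, sigma_pop)` with `d`
#' the great-circle distance in km — so fitness declines with provenance
#' distance when `b > 0`.  Binary traits are Bernoulli(logit^-1(eta)),
#' counts are Poisson(exp(eta)) and biomass is LogNormal(eta, sigma_resid).
#'
#' @param params A [simulation_params()] object.
#' @return Data frame of class `"fitness_dataset"` with columns `garden`,
#'   `taxon`, `population`, `genotype`, `replicate`, `herbivory` (1 = no
#'   herbivore damage), `flower_number`, `fruit_number`, `biomass` (g) and
#'   `survival`.  Attributes: `true_population_effects` (the simulated
#'   per-population-per-garden effects, for recovery tests), `populations`
#'   (coordinate table) and `gardens`.
#' @export
simulate_transplant <- function(params) {
  pops <- population_table(params)
  roster <- genotype_roster(params)
  gardens <- params$gardens
  set.seed(stage_seed(params$seed, "transplant"))

  fe <- params$fixed_effects
  b <- params$distance_decay_slope

  # per (population, garden): distance-driven effect plus a population draw
  pe <- expand.grid(population = pops$population, garden = gardens$garden,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pe <- merge(pe, pops, by = "population")
  pe <- merge(pe, gardens[c("garden", "lon", "lat")], by = "garden",
              suffixes = c("_pop", "_garden"))
  pe$distance_km <- haversine_km(pe$lon_pop, pe$lat_pop,
                                 pe$lon_garden, pe$lat_garden)
  pe <- pe[order(pe$garden, pe$population), ]
  pe$effect <- -b * pe$distance_km + rnorm(nrow(pe), 0, params$sigma_pop)

  gen_eff <- setNames(rnorm(nrow(roster), 0, params$sigma_genotype),
                      roster$genotype)

  reps <- params$taxa$replicates_per_garden[match(roster$taxon, params$taxa$taxon)]
  plants <- roster[rep(seq_len(nrow(roster)), reps), ]
  plants$replicate <- unlist(lapply(reps, seq_len), use.names = FALSE)
  dat <- merge(plants, data.frame(garden = gardens$garden), by = NULL)

  key <- paste(dat$population, dat$garden)
  pe_key <- paste(pe$population, pe$garden)
  tx_eff <- fe$taxon[dat$taxon]
  gd_eff <- fe$garden[dat$garden]
  local_tx <- gardens$local_taxon[match(dat$garden, gardens$garden)]
  int_eff <- ifelse(dat$taxon == local_tx, fe$local_advantage, 0)
  base_eta <- tx_eff + gd_eff + int_eff +
    pe$effect[match(key, pe_key)] + gen_eff[dat$genotype]

  n <- nrow(dat)
  dat$herbivory <- rbinom(n, 1L, plogis(fe$intercepts[["herbivory"]] + base_eta))
  dat$flower_number <- rpois(n, exp(fe$intercepts[["flower_number"]] + base_eta))
  dat$fruit_number <- rpois(n, exp(fe$intercepts[["fruit_number"]] + base_eta))
  dat$biomass <- rlnorm(n, fe$intercepts[["biomass"]] + base_eta,
                        params$sigma_resid)
  dat$survival <- rbinom(n, 1L, plogis(fe$intercepts[["survival"]] + base_eta))

  dat <- dat[order(dat$garden, dat$taxon, dat$population,
                   dat$genotype, dat$replicate), ]
  rownames(dat) <- NULL
  dat <- dat[c("garden", "taxon", "population", "genotype", "replicate",
               "herbivory", "flower_number", "fruit_number", "biomass",
               "survival")]
  attr(dat, "true_population_effects") <-
    pe[c("population", "garden", "distance_km", "effect")]
  attr(dat, "populations") <- pops
  attr(dat, "gardens") <- gardens
  class(dat) <- c("fitness_dataset", "data.frame")
  dat
}

#' Simulate leaf traits and fitness from a two-axis latent landscape
#'
#' One latent axis (`axis1`) separates the taxa (each taxon has its own
#' mean) while the second (`axis2`) varies within every taxon.  Leaf
#' measurements load on the axes through `params$trait_loadings`.  Each
#' axis is under selection at its own scale: fitness is generated as
#' `log W = mu + gamma1 * mean_axis1(taxon) + gamma2 * axis2 + noise`,
#' so axis 1 drives fitness differences *between* taxa (through the
#' taxon-typical value; residual axis-1 variation within a taxon is
#' selectively neutral) while axis 2 drives fitness variation *within*
#' every taxon.  Ratio and SLA are derived exactly (`length/width`,
#' `area/dry mass`) via [derive_leaf_traits()].
#'
#' @param params A [simulation_params()] object.
#' @return Data frame of class `"trait_matrix"`: one row per genotype with
#'   taxon/population/genotype ids, raw measurements (`length_mm`,
#'   `width_mm`, `area_cm2`, `fresh_mass_g`, `dry_mass_g`, `chlorophyll`),
#'   derived `ratio` and `sla_cm2_g`, the generating latents `axis1` and
#'   `axis2` (for recovery tests only) and fitness columns
#'   `flower_number`, `fruit_number`, `biomass`.
#' @export
simulate_traits_fitness <- function(params) {
  roster <- genotype_roster(params)
  set.seed(stage_seed(params$seed, "traits"))
  Ld <- params$trait_loadings
  cs <- sum(Ld[, 1] * Ld[, 2]) /
    max(sqrt(sum(Ld[, 1]^2)) * sqrt(sum(Ld[, 2]^2)), .Machine$double.eps)
  if (abs(cs) > 1e-8)
    warning("trait_loadings columns are not orthogonal (cosine = ",
            signif(cs, 3), "); the two latent axes will be conflated")
  ratio_gap <- Ld["ratio", ] - (Ld["length", ] - Ld["width", ])
  if (any(abs(ratio_gap) > 1e-8))
    warning("ratio loadings differ from length - width; using length - width ",
            "because the ratio is derived exactly")

  n <- nrow(roster)
  mu1 <- params$taxa$latent_mean[match(roster$taxon, params$taxa$taxon)]
  axis1 <- rnorm(n, mu1, params$latent_sd)
  axis2 <- rnorm(n, 0, 1)
  L <- cbind(axis1, axis2)

  base <- params$trait_base
  nsd <- params$trait_noise_sd
  log_len <- base[["length"]] + L %*% Ld["length", ] + rnorm(n, 0, nsd)
  log_wid <- base[["width"]] + L %*% Ld["width", ] + rnorm(n, 0, nsd)
  log_area <- base[["area"]] + L %*% Ld["area", ] + rnorm(n, 0, nsd)
  log_sla <- base[["sla"]] + L %*% Ld["sla", ] + rnorm(n, 0, nsd)
  chl <- base[["chlorophyll"]] + 10 * (L %*% Ld["chlorophyll", ]) +
    rnorm(n, 0, params$chlorophyll_noise_sd)
  chl <- pmax(chl, 1)  # relative units, device floor

  raw <- data.frame(
    taxon = roster$taxon,
    population = roster$population,
    genotype = roster$genotype,
    length_mm = exp(drop(log_len)),
    width_mm = exp(drop(log_wid)),
    area_cm2 = exp(drop(log_area)),
    dry_mass_g = exp(drop(log_area - log_sla)),
    chlorophyll = drop(chl),
    stringsAsFactors = FALSE
  )
  raw$fresh_mass_g <- raw$dry_mass_g * exp(rnorm(n, log(3.2), 0.05))
  out <- derive_leaf_traits(raw)

  eta_sel <- params$gamma1 * mu1 + params$gamma2 * axis2
  eta_fl <- 2.0 + eta_sel
  eta_fr <- 1.5 + eta_sel
  eta_bm <- 0.7 + eta_sel
  out$flower_number <- rpois(n, exp(eta_fl))
  out$fruit_number <- rpois(n, exp(eta_fr))
  out$biomass <- rlnorm(n, eta_bm, 0.3)
  out$axis1 <- axis1
  out$axis2 <- axis2
  class(out) <- c("trait_matrix", "data.frame")
  out
}
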