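#' Parameters for the synthetic transplant-study generator
#'
#' Builds the parameter list consumed by the `simulate_*()` generators.  The
#' defaults emulate a three-garden reciprocal transplant of three perennial
#' wildflower taxa: 321 plants per garden drawn from 122 `amoena` genotypes
#' (8 source populations), 125 `pilosa` genotypes (9 populations) and 37
#' `deamii` genotypes (3 populations, two clonal replicates per genotype per
#' garden).  Gardens sit within ~120 km of each other in the zone of
#' sympatry while source populations span ~900 km, so provenance distances
#' have real leverage.
#'
#' @param seed Integer master seed.  Each generator derives its own
#'   substream from it (see [stage_seed()]), so stages are independently
#'   reproducible.
#' @param gardens Data frame with columns `garden`, `lon`, `lat`,
#'   `local_taxon`: one row per experimental garden.
#' @param taxa Data frame with columns `taxon`, `n_populations`,
#'   `n_genotypes`, `replicates_per_garden`, `latent_mean` (taxon mean on
#'   the first latent trait axis).
#' @param taxon_bbox Named list of `c(lon_min, lon_max, lat_min, lat_max)`
#'   bounding boxes from which source-population coordinates are drawn.
#' @param fixed_effects List with elements `intercepts` (named per fitness
#'   trait, linear-predictor scale), `taxon` and `garden` (named main
#'   effects), and `local_advantage` (taxon-by-garden interaction added to
#'   each local taxon in its home garden, link scale).
#' @param distance_decay_slope Decline in the population effect per km
#'   between source population and garden (link-scale units/km); positive
#'   values produce local adaptation.
#' @param sigma_pop,sigma_genotype,sigma_resid Standard deviations of the
#'   population deviation, genotype intercept, and residual of log biomass.
#' @param fst_param Balding-Nichols `F` in `[0, 1)`: the expected
#'   differentiation of population allele frequencies around the ancestral
#'   frequency.
#' @param n_loci,n_ind_per_pop Number of biallelic loci and diploid
#'   individuals genotyped per population.
#' @param ancestral_freq Length-2 bounds of the uniform ancestral allele
#'   frequency.
#' @param missing_rate Fraction of genotype calls set missing at random.
#' @param trait_loadings 6 x 2 matrix mapping the two latent axes to the six
#'   leaf traits (rows `length`, `width`, `ratio`, `area`, `chlorophyll`,
#'   `sla`; log scale except chlorophyll).  Columns should be orthogonal:
#'   axis 1 separates taxa, axis 2 varies within taxa.  Because the ratio
#'   is length/width and SLA is area/dry-mass by definition, the `ratio`
#'   row must equal `length - width`; the dry-mass loading is derived as
#'   `area - sla`.
#' @param latent_sd Within-taxon standard deviation of latent axis 1 (axis
#'   2 is standard normal within every taxon).
#' @param trait_base Named baseline values: log mm for `length`/`width`,
#'   log cm^2 for `area`, log cm^2/g for `sla`, relative units for
#'   `chlorophyll`.
#' @param trait_noise_sd Residual SD of the log-scale leaf measurements.
#' @param chlorophyll_noise_sd Residual SD of chlorophyll (linear scale).
#' @param gamma1,gamma2 Selection strengths on log fitness.  `gamma1`
#'   multiplies the taxon-typical value of latent axis 1 (selection at
#'   the between-taxon scale; the default reproduces roughly 3-4-fold
#'   fitness differentials between the extreme taxa), `gamma2` multiplies
#'   latent axis 2 (within-taxon directional selection of moderate,
#'   field-typical strength).
#' @param occurrence_species Named list configuring [simulate_occurrences()]:
#'   per species `n` (records), `mean` and `cov` over the environmental
#'   variables, and a coordinate `bbox`.
#'
#' @return A list of class `"simulation_params"`.
#' @seealso [simulate_occurrences()], [simulate_genotypes()],
#'   [simulate_transplant()], [simulate_traits_fitness()]
#' @export
#' @examples
#' p <- simulation_params(seed = 42)
#' fit <- simulate_transplant(p)
#' table(fit$garden)
simulation_params <- function(seed = 1,
                              gardens = default_gardens(),
                              taxa = default_taxa(),
                              taxon_bbox = default_taxon_bbox(),
                              fixed_effects = default_fixed_effects(),
                              distance_decay_slope = 0.001,
                              sigma_pop = 0.2,
                              sigma_genotype = 0.2,
                              sigma_resid = 0.4,
                              fst_param = 0.1,
                              n_loci = 1000,
                              n_ind_per_pop = 5,
                              ancestral_freq = c(0.1, 0.9),
                              missing_rate = 0,
                              trait_loadings = default_trait_loadings(),
                              latent_sd = 0.5,
                              trait_base = c(length = log(25), width = log(6),
                                             area = log(4), sla = log(150),
                                             chlorophyll = 35),
                              trait_noise_sd = 0.08,
                              chlorophyll_noise_sd = 2,
                              gamma1 = 0.6,
                              gamma2 = 0.25,
                              occurrence_species = default_occurrence_species()) {
  params <- list(
    seed = as.integer(seed),
    gardens = gardens,
    taxa = taxa,
    taxon_bbox = taxon_bbox,
    fixed_effects = fixed_effects,
    distance_decay_slope = distance_decay_slope,
    sigma_pop = sigma_pop,
    sigma_genotype = sigma_genotype,
    sigma_resid = sigma_resid,
    fst_param = fst_param,
    n_loci = as.integer(n_loci),
    n_ind_per_pop = as.integer(n_ind_per_pop),
    ancestral_freq = ancestral_freq,
    missing_rate = missing_rate,
    trait_loadings = trait_loadings,
    latent_sd = latent_sd,
    trait_base = trait_base,
    trait_noise_sd = trait_noise_sd,
    chlorophyll_noise_sd = chlorophyll_noise_sd,
    gamma1 = gamma1,
    gamma2 = gamma2,
    occurrence_species = occurrence_species
  )
  class(params) <- "simulation_params"
  validate_simulation_params(params)
  params
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Synthetic transplant-study parameters\n")
  cat("  seed:", x$seed, "\n")
  cat("  gardens:", nrow(x$gardens),
      sprintf("(%s)", paste(x$gardens$garden, collapse = ", ")), "\n")
  for (i in seq_len(nrow(x$taxa))) {
    t <- x$taxa[i, ]
    cat(sprintf("  %s: %d genotypes / %d populations, %d replicate(s) per garden\n",
                t$taxon, t$n_genotypes, t$n_populations,
                t$replicates_per_garden))
  }
  cat(sprintf("  plants per garden: %d\n",
              sum(x$taxa$n_genotypes * x$taxa$replicates_per_garden)))
  cat(sprintf("  F = %.3g over %d loci; distance decay %.3g per km\n",
              x$fst_param, x$n_loci, x$distance_decay_slope))
  invisible(x)
}

validate_simulation_params <- function(p) {
  stopifnot(is.data.frame(p$gardens),
            all(c("garden", "lon", "lat", "local_taxon") %in% names(p$gardens)),
            is.data.frame(p$taxa),
            all(c("taxon", "n_populations", "n_genotypes",
                  "replicates_per_garden", "latent_mean") %in% names(p$taxa)))
  if (any(c(p$sigma_pop, p$sigma_genotype, p$sigma_resid) < 0))
    stop("sigma_pop, sigma_genotype and sigma_resid must be non-negative")
  if (p$fst_param < 0 || p$fst_param >= 1)
    stop("fst_param must lie in [0, 1); F = 1 makes the Balding-Nichols Beta degenerate")
  if (!is.matrix(p$trait_loadings) ||
      nrow(p$trait_loadings) != 6L || ncol(p$trait_loadings) != 2L)
    stop("trait_loadings must be a 6 x 2 matrix (six leaf traits, two latent axes)")
  if (!all(p$gardens$local_taxon %in% p$taxa$taxon))
    stop("every garden's local_taxon must be a configured taxon")
  if (abs(p$missing_rate) > 0.5)
    stop("missing_rate above 0.5 would violate the per-population call guarantee")
  bad_bbox <- setdiff(p$taxa$taxon, names(p$taxon_bbox))
  if (length(bad_bbox))
    stop("no bounding box for taxa: ", paste(bad_bbox, collapse = ", "))
  invisible(p)
}

#' @rdname simulation_params
#' @export
default_gardens <- function() {
  data.frame(
    garden = c("amoena_garden", "deamii_garden", "pilosa_garden"),
    lon = c(-86.95, -87.60, -87.10),
    lat = c(36.50, 36.95, 37.25),
    local_taxon = c("amoena", "deamii", "pilosa"),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulation_params
#' @export
default_taxa <- function() {
  data.frame(
    taxon = c("amoena", "deamii", "pilosa"),
    n_populations = c(8L, 3L, 9L),
    n_genotypes = c(122L, 37L, 125L),
    replicates_per_garden = c(1L, 2L, 1L),
    latent_mean = c(-1.2, -0.8, 1.2),
    stringsAsFactors = FALSE
  )
}

#' @rdname simulation_params
#' @export
default_taxon_bbox <- function() {
  list(
    amoena = c(lon_min = -88.5, lon_max = -81.5, lat_min = 31.0, lat_max = 36.8),
    deamii = c(lon_min = -89.0, lon_max = -86.0, lat_min = 36.2, lat_max = 38.0),
    pilosa = c(lon_min = -93.0, lon_max = -83.0, lat_min = 31.0, lat_max = 38.0)
  )
}

#' @rdname simulation_params
#' @export
default_fixed_effects <- function() {
  list(
    intercepts = c(herbivory = 0.5, flower_number = 2.0, fruit_number = 1.5,
                   biomass = 0.7, survival = 1.0),
    taxon = c(amoena = 0, deamii = -0.2, pilosa = 0.2),
    garden = c(amoena_garden = 0, deamii_garden = -0.1, pilosa_garden = 0.1),
    local_advantage = 1.0
  )
}

#' @rdname simulation_params
#' @export
default_trait_loadings <- function() {
  m <- matrix(c(
    #  axis1   axis2
      0.35,    0.00,   # log leaf length
     -0.25,    0.00,   # log leaf width
      0.60,    0.00,   # log length/width ratio == length - width
      0.00,    0.45,   # log leaf area
     -0.30,    0.00,   # chlorophyll (linear, scaled by 10 internally)
      0.00,   -0.50    # log SLA
  ), nrow = 6, byrow = TRUE,
  dimnames = list(c("length", "width", "ratio", "area", "chlorophyll", "sla"),
                  c("axis1", "axis2")))
  m
}

#' @rdname simulation_params
#' @export
default_occurrence_species <- function() {
  vars <- c("temp_mean", "temp_seasonality", "precip_ann",
            "precip_seasonality", "soil_ph", "soil_sand")
  base_cov <- diag(c(2.0, 1.5, 1.5, 1.0, 1.0, 1.0))
  dimnames(base_cov) <- list(vars, vars)
  # amoena occupies a narrower slice of variable 1 (the niche-subset pattern)
  amo_cov <- base_cov
  amo_cov[1, 1] <- 0.5
  list(
    pilosa = list(n = 87L,
                  mean = setNames(rep(0, length(vars)), vars),
                  cov = base_cov,
                  bbox = c(lon_min = -93, lon_max = -83,
                           lat_min = 31, lat_max = 38)),
    amoena = list(n = 33L,
                  mean = setNames(c(-1.5, rep(0, length(vars) - 1)), vars),
                  cov = amo_cov,
                  bbox = c(lon_min = -88.5, lon_max = -81.5,
                           lat_min = 31, lat_max = 36.8))
  )
}

#' Derive a per-stage random seed from the master seed
#'
#' Each generator seeds its own substream so that, e.g., changing the
#' number of loci never perturbs the transplant draw.
#'
#' @param seed Integer master seed.
#' @param stage One of `"populations"`, `"occurrences"`, `"genotypes"`,
#'   `"transplant"`, `"traits"`.
#' @return An integer below 2^31.
#' @export
stage_seed <- function(seed, stage = c("populations", "occurrences",
                                       "genotypes", "transplant", "traits")) {
  stage <- match.arg(stage)
  idx <- match(stage, c("populations", "occurrences", "genotypes",
                        "transplant", "traits"))
  as.integer((abs(as.numeric(seed)) %% 214748357) * 10 + idx)
}

#' Source-population coordinate table
#'
#' Draws one coordinate per source population, uniformly within the
#' configured per-taxon bounding box.  Deterministic in `params$seed`
#' (its own substream), so every generator sees the same geography.
#'
#' @param params A [simulation_params()] object.
#' @return Data frame with columns `taxon`, `population`, `lon`, `lat`.
#' @export
population_table <- function(params) {
  set.seed(stage_seed(params$seed, "populations"))
  out <- lapply(seq_len(nrow(params$taxa)), function(i) {
    tx <- params$taxa$taxon[i]
    np <- params$taxa$n_populations[i]
    bb <- params$taxon_bbox[[tx]]
    data.frame(
      taxon = tx,
      population = sprintf("%s_p%02d", tx, seq_len(np)),
      lon = runif(np, bb[["lon_min"]], bb[["lon_max"]]),
      lat = runif(np, bb[["lat_min"]], bb[["lat_max"]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# split n genotypes as evenly as possible over k populations
split_genotypes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
}

#' Genotype roster: which genotype belongs to which population
#'
#' @param params A [simulation_params()] object.
#' @return Data frame with columns `taxon`, `population`, `genotype`.
#' @export
genotype_roster <- function(params) {
  pops <- population_table(params)
  out <- lapply(seq_len(nrow(params$taxa)), function(i) {
    tx <- params$taxa$taxon[i]
    tx_pops <- pops$population[pops$taxon == tx]
    sizes <- split_genotypes(params$taxa$n_genotypes[i], length(tx_pops))
    data.frame(
      taxon = tx,
      population = rep(tx_pops, sizes),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  idx <- stats::ave(seq_len(nrow(out)), out$population, FUN = seq_along)
  out$genotype <- sprintf("%s_g%03d", out$population, idx)
  rownames(out) <- NULL
  out
}
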