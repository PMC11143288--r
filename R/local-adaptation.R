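#' Great-circle distance between coordinate pairs (Haversine formula)
#'
#' `2 R asin(sqrt(sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2)))`
#' with all angles in radians.  The default radius is the WGS84 equatorial
#' radius 6378.137 km, the convention of common geodesy libraries; pass
#' `radius_km = 6371.0088` for the mean-Earth-radius convention.
#' Vectorized over coordinate vectors.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @param radius_km Sphere radius in km.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 90, 0)  # quarter circumference
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6378.137) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(h)))
}

#' Environmental distance between two sites in PC1/PC2 space
#'
#' Projects both sites' environmental vectors with the stored scaling and
#' eigenvectors of a fitted [fit_env_pca()] and returns the Euclidean
#' distance using the first two components only.  Invariant to eigenvector
#' sign flips.
#'
#' @param env_pca A fitted [fit_env_pca()] object.
#' @param site_a,site_b Named numeric vectors (or one-row data frames)
#'   containing every fitted variable.
#' @return Euclidean distance in PC units.
#' @export
environmental_distance <- function(env_pca, site_a, site_b) {
  pa <- predict(env_pca, site_a)[1, 1:2]
  pb <- predict(env_pca, site_b)[1, 1:2]
  sqrt(sum((pa - pb)^2))
}

#' Weir-Cockerham F_ST between two populations
#'
#' Implements the Weir & Cockerham (1984) theta estimator for biallelic
#' diploid loci from per-locus variance components: `a` (among
#' populations), `b` (among individuals within populations) and `c`
#' (within individuals), computed from sample sizes, allele frequencies
#' and observed heterozygosity.  The multi-locus estimate is the ratio of
#' sums `sum(a) / sum(a + b + c)`; loci with an undefined or zero
#' denominator (e.g. monomorphic across both populations) are excluded and
#' counted.  Negative estimates are retained — they are part of the
#' estimator's sampling distribution.
#'
#' @param genotypes A `"genotype_matrix"` (see [simulate_genotypes()] or
#'   [read_genotypes()]), or a plain loci x individuals matrix of 0/1/2
#'   allele counts, in which case `pop_map` must be supplied.
#' @param pop_a,pop_b The two population labels to compare.
#' @param pop_map Named character vector individual -> population (only
#'   when `genotypes` is a bare matrix).
#' @return Object of class `"wc_fst"`: `theta` (multi-locus estimate),
#'   `per_locus` (data frame of `a`, `b`, `c` and per-locus theta),
#'   `n_loci_used`, `n_loci_excluded`, and the population labels.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst <- function(genotypes, pop_a, pop_b, pop_map = NULL) {
  if (inherits(genotypes, "genotype_matrix")) {
    pop_map <- genotypes$populations
    genotypes <- genotypes$genotypes
  }
  if (is.null(pop_map))
    stop("pop_map is required when genotypes is a bare matrix")
  if (identical(pop_a, pop_b)) stop("pop_a and pop_b must differ")
  ga <- genotypes[, names(pop_map)[pop_map == pop_a], drop = FALSE]
  gb <- genotypes[, names(pop_map)[pop_map == pop_b], drop = FALSE]
  if (ncol(ga) == 0 || ncol(gb) == 0)
    stop("population not found in pop_map: ",
         paste(c(pop_a, pop_b)[c(ncol(ga) == 0, ncol(gb) == 0)], collapse = ", "))

  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- rowMeans(ga, na.rm = TRUE) / 2
  p2 <- rowMeans(gb, na.rm = TRUE) / 2
  h1 <- rowMeans(ga == 1L, na.rm = TRUE)
  h2 <- rowMeans(gb == 1L, na.rm = TRUE)

  r <- 2
  nbar <- (n1 + n2) / r
  nsum <- n1 + n2
  nc <- (nsum - (n1^2 + n2^2) / nsum) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / nsum

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  denom <- a + b + cc
  usable <- is.finite(denom) & denom > 0 & n1 >= 1 & n2 >= 1 & nbar > 1
  n_excl <- sum(!usable)
  if (!any(usable))
    stop("no usable locus: every locus monomorphic or undefined")

  per_locus <- data.frame(
    locus = if (!is.null(rownames(genotypes))) rownames(genotypes)
            else seq_along(a),
    a = a, b = b, c = cc,
    theta = ifelse(usable, a / denom, NA_real_),
    used = usable,
    row.names = NULL
  )
  structure(list(theta = sum(a[usable]) / sum(denom[usable]),
                 per_locus = per_locus,
                 n_loci_used = sum(usable),
                 n_loci_excluded = n_excl,
                 populations = c(pop_a, pop_b)),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST (%s vs %s): theta = %.4f\n",
              x$populations[1], x$populations[2], x$theta))
  cat(sprintf("  %d loci used, %d excluded (monomorphic/undefined)\n",
              x$n_loci_used, x$n_loci_excluded))
  invisible(x)
}

#' Distance table between source populations and gardens
#'
#' Builds the per-(population, garden) table of the three provenance
#' distances: great-circle geographic distance, Euclidean distance in
#' environmental PC1/PC2 space, and Weir-Cockerham F_ST between the source
#' population and the intraspecific population adjacent to the garden.
#'
#' @param populations Data frame `population`, `lon`, `lat` (plus optional
#'   env variable columns for the environmental distance).
#' @param gardens Data frame `garden`, `lon`, `lat` (plus env columns).
#' @param env_pca Optional fitted [fit_env_pca()]; if supplied, both
#'   tables must carry its variables as columns.
#' @param genotypes Optional `"genotype_matrix"` for the genetic distance.
#' @param garden_pops Optional named character vector garden -> reference
#'   population.  By default the reference for each source population is
#'   the nearest population *of the same taxon* to the garden (the
#'   intraspecific garden-adjacent population), which requires a `taxon`
#'   column in `populations`.
#' @param radius_km Sphere radius for the geographic distance.
#' @return Data frame with columns `population`, `garden`,
#'   `geographic_km` and, when computable, `environmental` and `fst`.
#' @export
distance_table <- function(populations, gardens, env_pca = NULL,
                           genotypes = NULL, garden_pops = NULL,
                           radius_km = 6378.137) {
  out <- expand.grid(population = populations$population,
                     garden = gardens$garden,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ip <- match(out$population, populations$population)
  ig <- match(out$garden, gardens$garden)
  out$geographic_km <- haversine_km(populations$lon[ip], populations$lat[ip],
                                    gardens$lon[ig], gardens$lat[ig],
                                    radius_km = radius_km)
  if (!is.null(env_pca)) {
    pp <- predict(env_pca, populations)[, 1:2, drop = FALSE]
    pg <- predict(env_pca, gardens)[, 1:2, drop = FALSE]
    out$environmental <- sqrt(rowSums((pp[ip, , drop = FALSE] -
                                         pg[ig, , drop = FALSE])^2))
  }
  if (!is.null(genotypes)) {
    if (is.null(garden_pops) && !"taxon" %in% names(populations))
      stop("genetic distance needs either garden_pops or a taxon column ",
           "in populations (to pick the intraspecific garden-adjacent ",
           "reference)")
    ref_for <- function(i) {
      if (!is.null(garden_pops)) return(garden_pops[[out$garden[i]]])
      tx <- populations$taxon[ip[i]]
      cand <- which(populations$taxon == tx)
      d <- haversine_km(populations$lon[cand], populations$lat[cand],
                        gardens$lon[ig[i]], gardens$lat[ig[i]],
                        radius_km = radius_km)
      populations$population[cand[which.min(d)]]
    }
    fst_cache <- new.env(parent = emptyenv())
    out$fst <- vapply(seq_len(nrow(out)), function(i) {
      ref <- ref_for(i)
      if (identical(ref, out$population[i])) return(0)
      key <- paste(sort(c(ref, out$population[i])), collapse = "\r")
      if (is.null(fst_cache[[key]]))
        fst_cache[[key]] <- wc_fst(genotypes, out$population[i], ref)$theta
      fst_cache[[key]]
    }, numeric(1))
  }
  out
}

#' Extract per-population random effects on a fitness trait
#'
#' Fits, for one species, the intercept-only generalized linear mixed
#' model of the trait with random intercepts for garden and for population
#' nested within garden (`~ 1 + (1 | garden) + (1 | garden:population)`),
#' and returns the conditional modes (BLUPs) of the nested term: the
#' estimated average effect of coming from each population, per garden,
#' on the link scale.  `mode = "per_garden"` instead fits one model per
#' garden with a plain population intercept.
#'
#' Families follow the trait support: binomial-logit for binary traits,
#' Poisson-log for counts, and a Gaussian mixed model on `ln(biomass)`.
#' A trait with no variation in the species (e.g. every plant survived)
#' cannot support population effects; a structured result with
#' `insufficient_variation = TRUE` is returned instead of an error.
#'
#' @param dataset A `"fitness_dataset"` (or data frame with `garden`,
#'   `taxon`, `population`, `genotype` and the trait column).
#' @param species Taxon to subset to.
#' @param trait One of `"herbivory"`, `"flower_number"`, `"fruit_number"`,
#'   `"biomass"`, `"survival"` (or any column with a compatible family).
#' @param family `"binomial"`, `"poisson"` or `"gaussian"`; default
#'   chosen from the trait name.
#' @param mode `"nested"` (one model, populations nested in gardens;
#'   default) or `"per_garden"`.
#' @return Object of class `"population_effects"`: data frame `effects`
#'   with columns `species`, `garden`, `population`, `trait`, `effect`,
#'   `cond_sd`, plus `insufficient_variation`, the fitted model(s) and
#'   metadata.
#' @export
extract_population_effects <- function(dataset, species, trait,
                                       family = NULL,
                                       mode = c("nested", "per_garden")) {
  mode <- match.arg(mode)
  family <- family %||% default_family(trait)
  d <- as.data.frame(dataset)
  d <- d[d$taxon == species, , drop = FALSE]
  if (length(unique(d$population)) < 3)
    stop("need at least 3 populations of ", species)
  y <- trait_response(d, trait, family)
  if (length(unique(na.omit(y))) < 2) {
    return(structure(list(effects = NULL, species = species, trait = trait,
                          family = family, mode = mode,
                          insufficient_variation = TRUE),
                     class = "population_effects"))
  }
  d$.y <- y
  d$garden <- factor(d$garden)
  d$population <- factor(d$population)
  d$gp <- interaction(d$garden, d$population, sep = "|", drop = TRUE)

  fit_one <- function(dd, form) {
    if (family == "gaussian")
      lme4::lmer(form, data = dd,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    else
      lme4::glmer(form, data = dd, family = family,
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               optCtrl = list(maxfun = 1e5),
                                               check.conv.singular = "ignore"))
  }

  if (mode == "nested") {
    fit <- fit_one(d, .y ~ 1 + (1 | garden) + (1 | gp))
    re <- lme4::ranef(fit, condVar = TRUE)$gp
    pv <- attr(re, "postVar")
    keys <- do.call(rbind, strsplit(rownames(re), "|", fixed = TRUE))
    eff <- data.frame(species = species, garden = keys[, 1],
                      population = keys[, 2], trait = trait,
                      effect = re[, 1],
                      cond_sd = sqrt(pv[1, 1, ]),
                      row.names = NULL, stringsAsFactors = FALSE)
    fits <- list(fit)
  } else {
    fits <- list()
    eff <- NULL
    for (g in levels(d$garden)) {
      dd <- d[d$garden == g, , drop = FALSE]
      if (length(unique(na.omit(dd$.y))) < 2) next
      fit <- fit_one(dd, .y ~ 1 + (1 | population))
      re <- lme4::ranef(fit, condVar = TRUE)$population
      pv <- attr(re, "postVar")
      eff <- rbind(eff, data.frame(species = species, garden = g,
                                   population = rownames(re), trait = trait,
                                   effect = re[, 1], cond_sd = sqrt(pv[1, 1, ]),
                                   row.names = NULL, stringsAsFactors = FALSE))
      fits[[g]] <- fit
    }
  }
  structure(list(effects = eff, species = species, trait = trait,
                 family = family, mode = mode,
                 insufficient_variation = FALSE, fits = fits),
            class = "population_effects")
}

#' @export
print.population_effects <- function(x, ...) {
  if (x$insufficient_variation) {
    cat(sprintf("Population effects for %s / %s: insufficient variation to model\n",
                x$species, x$trait))
  } else {
    cat(sprintf("Population effects for %s / %s (%s, %s): %d (garden, population) modes\n",
                x$species, x$trait, x$family, x$mode, nrow(x$effects)))
  }
  invisible(x)
}

#' Regress population effects on provenance distance
#'
#' Ordinary least squares of the extracted population random effects on
#' one distance measure.  A negative slope — genotypes from farther away
#' perform worse — is the signature of local adaptation; the fit is
#' flagged as supportive when the slope is negative and the model F-test
#' p-value is below `alpha`.
#'
#' @param effects A [extract_population_effects()] result (or its
#'   `effects` data frame).
#' @param distances A [distance_table()] data frame.
#' @param distance_type Column of `distances` to regress on:
#'   `"geographic_km"`, `"environmental"` or `"fst"`.
#' @param garden Optional garden to subset to (the provenance analysis is
#'   usually read per garden); default uses all rows.
#' @param alpha Significance level for the local-adaptation flag.
#' @return Object of class `"provenance_regression"`: slope, intercept,
#'   `r_squared`, `p_value`, `n`, `local_adaptation` flag and metadata.
#' @export
provenance_regression <- function(effects, distances,
                                  distance_type = c("geographic_km",
                                                    "environmental", "fst"),
                                  garden = NULL, alpha = 0.05) {
  distance_type <- match.arg(distance_type)
  meta <- list(species = NA_character_, trait = NA_character_)
  if (inherits(effects, "population_effects")) {
    if (effects$insufficient_variation)
      stop("no population effects: trait had insufficient variation")
    meta <- effects[c("species", "trait")]
    effects <- effects$effects
  }
  if (!distance_type %in% names(distances))
    stop("distance column '", distance_type, "' not present")
  d <- merge(effects, distances[c("population", "garden", distance_type)],
             by = c("population", "garden"))
  if (!is.null(garden)) d <- d[d$garden %in% garden, , drop = FALSE]
  d <- d[complete.cases(d[c("effect", distance_type)]), , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 (population, garden) pairs with effect and distance")
  x <- d[[distance_type]]
  if (sd(x) == 0) stop("all distances equal: no design variation")
  fit <- lm(d$effect ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(species = meta$species, trait = meta$trait,
                 garden = if (is.null(garden)) "all" else garden,
                 distance_type = distance_type,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p, n = nrow(d), alpha = alpha,
                 local_adaptation = unname(coef(fit)[2]) < 0 && p < alpha,
                 fit = fit),
            class = "provenance_regression")
}

#' @export
print.provenance_regression <- function(x, ...) {
  cat(sprintf("Provenance regression (%s / %s, %s): slope = %.4g, R2 = %.3f, p = %.3g%s\n",
              x$species, x$trait, x$distance_type, x$slope, x$r_squared,
              x$p_value,
              if (isTRUE(x$local_adaptation)) "  [local adaptation]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_family <- function(trait) {
  switch(trait,
         herbivory = , survival = "binomial",
         flower_number = , fruit_number = "poisson",
         biomass = "gaussian",
         stop("no default family for trait '", trait,
              "'; supply family explicitly"))
}

# response on the model scale: biomass is log-transformed before the LMM
trait_response <- function(d, trait, family) {
  if (!trait %in% names(d)) stop("trait column '", trait, "' not present")
  y <- d[[trait]]
  if (trait == "biomass" && family == "gaussian") {
    if (any(y <= 0, na.rm = TRUE)) stop("biomass must be positive to log")
    y <- log(y)
  }
  y
}
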