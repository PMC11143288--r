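test_that("generators are pure functions of (params, seed), with independent substreams", {
  p <- simulation_params(seed = 31)
  expect_identical(simulate_transplant(p), simulate_transplant(p))
  expect_identical(simulate_occurrences(p), simulate_occurrences(p))
  expect_identical(simulate_genotypes(p)$genotypes,
                   simulate_genotypes(p)$genotypes)
  expect_identical(simulate_traits_fitness(p), simulate_traits_fitness(p))
  # changing a genotype-stage parameter must not perturb the other streams
  p2 <- simulation_params(seed = 31, n_loci = 77)
  expect_identical(simulate_transplant(p), simulate_transplant(p2))
  expect_identical(simulate_traits_fitness(p), simulate_traits_fitness(p2))
  # a different seed changes everything
  p3 <- simulation_params(seed = 32)
  expect_false(identical(simulate_transplant(p), simulate_transplant(p3)))
})

test_that("transplant dataset reproduces the three-garden design", {
  d <- simulate_transplant(simulation_params(seed = 5))
  expect_equal(unname(table(d$garden)), rep(321L, 3), ignore_attr = TRUE)
  # the rare taxon is planted twice per garden, the others once
  per <- table(d$garden, d$taxon)
  expect_true(all(per[, "deamii"] == 74))
  expect_true(all(per[, "amoena"] == 122))
  expect_true(all(per[, "pilosa"] == 125))
  # every genotype appears in all gardens
  gg <- table(d$genotype, d$garden)
  expect_true(all(gg > 0))
  # trait supports
  expect_true(all(d$herbivory %in% 0:1) && all(d$survival %in% 0:1))
  expect_true(all(d$flower_number >= 0 & d$flower_number == round(d$flower_number)))
  expect_true(all(d$fruit_number >= 0 & d$fruit_number == round(d$fruit_number)))
  expect_true(all(d$biomass > 0))
})

test_that("population effects decline with provenance distance by construction", {
  p <- simulation_params(seed = 8, sigma_pop = 0)
  d <- simulate_transplant(p)
  pe <- attr(d, "true_population_effects")
  expect_equal(pe$effect, -p$distance_decay_slope * pe$distance_km,
               tolerance = 1e-12)
  expect_true(all(pe$distance_km >= 0))
})

test_that("genotype matrices are diploid counts with Balding-Nichols structure", {
  p <- simulation_params(seed = 3, n_loci = 500)
  g <- simulate_genotypes(p)
  expect_true(all(g$genotypes %in% c(0L, 1L, 2L)))
  expect_gte(length(unique(g$populations)), 2)
  expect_identical(colnames(g$genotypes), names(g$populations))
  # F = 1 is a degenerate Beta
  expect_error(simulation_params(fst_param = 1), "fst_param")
  # missing calls appear at roughly the configured rate
  gm <- simulate_genotypes(simulation_params(seed = 3, n_loci = 2000,
                                             missing_rate = 0.05))
  expect_lt(abs(mean(is.na(gm$genotypes)) - 0.05), 0.01)
})

test_that("trait matrix satisfies its exact derivations and positivity", {
  tr <- simulate_traits_fitness(simulation_params(seed = 4))
  expect_equal(tr$ratio, tr$length_mm / tr$width_mm, tolerance = 1e-15)
  expect_equal(tr$sla_cm2_g, tr$area_cm2 / tr$dry_mass_g, tolerance = 1e-15)
  for (v in c("length_mm", "width_mm", "area_cm2", "dry_mass_g",
              "chlorophyll", "sla_cm2_g"))
    expect_true(all(tr[[v]] > 0), info = v)
  # one row per genotype
  expect_equal(nrow(tr), sum(default_taxa()$n_genotypes))
  # axis 1 separates taxa; axis 2 does not
  m1 <- tapply(tr$axis1, tr$taxon, mean)
  expect_gt(m1[["pilosa"]], m1[["amoena"]] + 1)
  m2 <- tapply(tr$axis2, tr$taxon, mean)
  expect_lt(max(abs(m2)), 0.5)
})

test_that("marginal trait moments match their configured values at n = 10,000", {
  taxa <- data.frame(taxon = "pilosa", n_populations = 5L,
                     n_genotypes = 10000L, replicates_per_garden = 1L,
                     latent_mean = 0)
  gardens <- default_gardens()
  gardens$local_taxon <- "pilosa"
  p <- simulation_params(seed = 60, taxa = taxa, gardens = gardens)
  tr <- simulate_traits_fitness(p)
  ld <- default_trait_loadings()
  # E[log length] = base; sd combines the axis-1 pathway and trait noise
  expect_equal(mean(log(tr$length_mm)), log(25), tolerance = 0.01)
  sd_len <- sqrt((ld["length", 1] * p$latent_sd)^2 + p$trait_noise_sd^2)
  expect_equal(sd(log(tr$length_mm)), sd_len, tolerance = 0.02)
  sd_area <- sqrt(ld["area", 2]^2 + p$trait_noise_sd^2)
  expect_equal(sd(log(tr$area_cm2)), sd_area, tolerance = 0.02)
  expect_equal(mean(tr$chlorophyll), 35, tolerance = 0.2)
  expect_equal(sd(tr$axis2), 1, tolerance = 0.03)
})

test_that("non-orthogonal trait loadings warn instead of erroring", {
  ld <- default_trait_loadings()
  ld["chlorophyll", 2] <- 0.4
  expect_warning(simulate_traits_fitness(simulation_params(seed = 1,
                                                           trait_loadings = ld)),
                 "orthogonal")
})

test_that("occurrence generator honors configured means and niche-subset structure", {
  spp <- default_occurrence_species()
  # offset of 10 on the first variable, independent unit variances
  for (s in names(spp)) spp[[s]]$cov <- diag(nrow(spp[[s]]$cov))
  dimnames(spp$pilosa$cov) <- dimnames(spp$amoena$cov) <-
    list(names(spp$pilosa$mean), names(spp$pilosa$mean))
  spp$pilosa$mean[1] <- 10
  spp$amoena$mean[1] <- 0
  spp$pilosa$n <- spp$amoena$n <- 600L
  occ <- simulate_occurrences(simulation_params(seed = 10,
                                                occurrence_species = spp))
  med <- tapply(occ[[names(spp$pilosa$mean)[1]]], occ$species, median)
  expect_equal(unname(med["pilosa"] - med["amoena"]), 10, tolerance = 0.3)
  expect_false(any(duplicated(occ[c("species", "lon", "lat")])))
  expect_true(all(abs(occ$lat) <= 90) && all(abs(occ$lon) <= 180))
  # non-positive-definite covariance is a configuration error
  spp$pilosa$cov[1, 2] <- spp$pilosa$cov[2, 1] <- 2
  expect_error(simulate_occurrences(simulation_params(seed = 10,
                                                      occurrence_species = spp)),
               "positive definite")
})

test_that("parameter validation rejects impossible configurations", {
  expect_error(simulation_params(sigma_pop = -1), "non-negative")
  expect_error(simulation_params(trait_loadings = matrix(0, 3, 2)), "6 x 2")
  g <- default_gardens(); g$local_taxon[1] <- "nope"
  expect_error(simulation_params(gardens = g), "local_taxon")
})
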