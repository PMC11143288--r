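test_that("haversine distance matches closed forms and an independent oracle", {
  expect_equal(haversine_km(-87, 36.5, -87, 36.5), 0)
  expect_equal(haversine_km(0, 0, 90, 0), pi * 6378.137 / 2, tolerance = 1e-10)
  expect_equal(haversine_km(0, -90, 0, 90), pi * 6378.137, tolerance = 1e-10)
  # agreement with the spherical law of cosines on random pairs
  set.seed(11)
  lon <- runif(200, -180, 180); lat <- runif(200, -85, 85)
  lon2 <- runif(200, -180, 180); lat2 <- runif(200, -85, 85)
  d1 <- haversine_km(lon, lat, lon2, lat2)
  d2 <- slc_km(lon, lat, lon2, lat2)
  expect_equal(d1, d2, tolerance = 1e-6)
  # and with the geodesy-package implementation (same default radius)
  d3 <- geosphere::distHaversine(cbind(lon, lat), cbind(lon2, lat2),
                                 r = 6378137) / 1000
  expect_equal(d1, d3, tolerance = 1e-9)
  expect_error(haversine_km(0, 95, 0, 0), "latitude")
})

test_that("geographic distance is symmetric and satisfies the triangle inequality", {
  set.seed(12)
  for (i in 1:50) {
    pt <- cbind(runif(3, -180, 180), runif(3, -88, 88))
    dab <- haversine_km(pt[1, 1], pt[1, 2], pt[2, 1], pt[2, 2])
    dba <- haversine_km(pt[2, 1], pt[2, 2], pt[1, 1], pt[1, 2])
    dbc <- haversine_km(pt[2, 1], pt[2, 2], pt[3, 1], pt[3, 2])
    dac <- haversine_km(pt[1, 1], pt[1, 2], pt[3, 1], pt[3, 2])
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("environmental distance is Euclidean in PC1/PC2 and sign-flip invariant", {
  set.seed(13)
  x <- as.data.frame(matrix(rnorm(300 * 4), ncol = 4))
  pca <- fit_env_pca(x)
  site0 <- setNames(pca$center, pca$variables)  # projects to the origin
  expect_equal(environmental_distance(pca, site0, site0), 0)
  # engineer a site projecting to (3, 4): distance 5
  xb <- pca$center + pca$scale * drop(pca$rotation %*% c(3, 4, 0, 0))
  expect_equal(environmental_distance(pca, site0, setNames(xb, pca$variables)),
               5, tolerance = 1e-10)
  # flipping eigenvector signs cannot change a norm
  flipped <- pca
  flipped$rotation <- -flipped$rotation
  expect_equal(environmental_distance(flipped, site0, setNames(xb, pca$variables)),
               5, tolerance = 1e-10)
  expect_error(environmental_distance(pca, site0[-1], site0), "V1")
})

test_that("wc_fst reproduces the frozen hand-worked example exactly", {
  # locus 1: pop A genotypes (0,0,1), pop B (2,2,1); locus 2: all het
  g <- rbind(L1 = c(0L, 0L, 1L, 2L, 2L, 1L), L2 = rep(1L, 6))
  colnames(g) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  pm <- setNames(rep(c("A", "B"), each = 3), colnames(g))
  res <- wc_fst(g, "A", "B", pop_map = pm)
  # value frozen from the independent nested-ANOVA oracle
  expect_equal(res$theta, 7 / 22, tolerance = 1e-10)
  expect_equal(fst_anova_oracle(g, pm), res$theta, tolerance = 1e-12)
  # all-het locus contributes theta = 0 with a negative b component
  expect_equal(res$per_locus$theta[2], 0)
  expect_lt(res$per_locus$b[2], 0)
})

test_that("wc_fst equals the nested-ANOVA oracle on random small matrices", {
  set.seed(14)
  for (i in 1:20) {
    gm <- random_genotypes(sample(3:15, 1), sample(3:10, 1))
    main <- wc_fst(gm, "p1", "p2")
    expect_equal(main$theta, fst_anova_oracle(gm$genotypes, gm$populations),
                 tolerance = 1e-10)
  }
})

test_that("fixed differences give theta = 1; identical pools give theta near 0", {
  g <- matrix(c(rep(0L, 12), rep(2L, 12)), nrow = 3,
              dimnames = list(paste0("L", 1:3), paste0("i", 1:8)))
  pm <- setNames(rep(c("A", "B"), each = 4), colnames(g))
  expect_equal(wc_fst(g, "A", "B", pop_map = pm)$theta, 1)
  # same allele frequencies in both populations: theta ~ 0
  p <- simulation_params(seed = 21, fst_param = 0, n_loci = 5000,
                         n_ind_per_pop = 25)
  gm <- simulate_genotypes(p, populations = c("A", "B"))
  expect_lt(abs(wc_fst(gm, "A", "B")$theta), 0.01)
})

test_that("wc_fst is symmetric, permutation-invariant, and counts exclusions", {
  set.seed(15)
  gm <- random_genotypes(25, 8)
  expect_equal(wc_fst(gm, "p1", "p2")$theta, wc_fst(gm, "p2", "p1")$theta,
               tolerance = 1e-12)
  # permute individuals within a population
  ids <- names(gm$populations)
  p1 <- ids[gm$populations == "p1"]
  perm <- c(sample(p1), ids[gm$populations == "p2"])
  gm2 <- gm
  gm2$genotypes <- gm$genotypes[, perm]
  gm2$populations <- gm$populations[perm]
  expect_equal(wc_fst(gm2, "p1", "p2")$theta, wc_fst(gm, "p1", "p2")$theta,
               tolerance = 1e-12)
  # monomorphic locus excluded and counted
  gm$genotypes[1, ] <- 0L
  res <- wc_fst(gm, "p1", "p2")
  expect_equal(res$n_loci_excluded, 1)
  expect_false(res$per_locus$used[1])
  # every locus unusable -> error
  mono <- matrix(2L, 4, 6, dimnames = list(NULL, paste0("i", 1:6)))
  expect_error(wc_fst(mono, "A", "B",
                      pop_map = setNames(rep(c("A", "B"), each = 3),
                                         paste0("i", 1:6))),
               "no usable locus")
})

test_that("increasing Balding-Nichols F increases the estimated theta", {
  thetas <- sapply(c(0, 0.05, 0.1, 0.2), function(F) {
    p <- simulation_params(seed = 77, fst_param = F, n_loci = 2000,
                           n_ind_per_pop = 25)
    gm <- simulate_genotypes(p, populations = c("A", "B"))
    wc_fst(gm, "A", "B")$theta
  })
  expect_true(all(diff(thetas) > 0))
})

test_that("population effects are near zero when populations are exchangeable", {
  p <- small_params(seed = 16, fixed_effects = null_effects(),
                    sigma_pop = 0, sigma_genotype = 0, sigma_resid = 0.3,
                    distance_decay_slope = 0)
  d <- simulate_transplant(p)
  pe <- extract_population_effects(d, "pilosa", "biomass")
  expect_false(pe$insufficient_variation)
  expect_lt(max(abs(pe$effects$effect)), 0.2)
  # centered near zero within 3 conditional SDs
  expect_lte(abs(mean(pe$effects$effect)),
             3 * mean(pe$effects$cond_sd) + 1e-10)
})

test_that("degenerate traits return a structured insufficient-variation result", {
  d <- simulate_transplant(small_params(seed = 17))
  d$survival[d$taxon == "pilosa"] <- 1L
  pe <- extract_population_effects(d, "pilosa", "survival")
  expect_true(pe$insufficient_variation)
  expect_null(pe$effects)
  expect_error(provenance_regression(pe, data.frame()), "insufficient")
})

test_that("simulated distance-decaying population effects are recovered in rank order", {
  p <- simulation_params(seed = 18, fixed_effects = null_effects(),
                         sigma_pop = 0.02, sigma_genotype = 0.1,
                         sigma_resid = 0.3, distance_decay_slope = 0.001)
  d <- simulate_transplant(p)
  truth <- attr(d, "true_population_effects")
  pe <- extract_population_effects(d, "pilosa", "biomass")
  m <- merge(pe$effects, truth, by = c("population", "garden"))
  expect_gt(cor(m$effect.x, m$effect.y, method = "spearman"), 0.8)
  # per-garden mode returns the same (garden, population) grid
  pg <- extract_population_effects(d, "pilosa", "biomass", mode = "per_garden")
  expect_setequal(paste(pg$effects$garden, pg$effects$population),
                  paste(pe$effects$garden, pe$effects$population))
})

test_that("provenance regression recovers exact linear structure and its R2 identity", {
  set.seed(19)
  km <- seq(0, 900, length.out = 12)
  eff <- data.frame(population = paste0("p", 1:12), garden = "g1",
                    effect = -0.001 * km)
  dist <- data.frame(population = paste0("p", 1:12), garden = "g1",
                     geographic_km = km)
  # a perfectly linear toy: summary.lm warns about the perfect fit
  r <- suppressWarnings(provenance_regression(eff, dist, "geographic_km"))
  expect_equal(r$slope, -0.001, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_true(r$local_adaptation)
  # R2 equals the squared Pearson correlation
  eff$effect <- eff$effect + rnorm(12, 0, 0.1)
  r2 <- provenance_regression(eff, dist, "geographic_km")
  expect_equal(r2$r_squared, cor(eff$effect, km)^2, tolerance = 1e-12)
  # degenerate designs error
  dist$geographic_km <- 5
  expect_error(provenance_regression(eff, dist, "geographic_km"),
               "no design variation")
  expect_error(provenance_regression(eff[1:2, ], dist, "geographic_km"),
               "at least 3")
})

test_that("distance table uses intraspecific garden-adjacent references for F_ST", {
  p <- small_params(seed = 20)
  pops <- population_table(p)
  gardens <- default_gardens()
  gm <- simulate_genotypes(p)
  dt <- distance_table(pops, gardens, genotypes = gm)
  # own-reference populations sit at exactly zero genetic distance
  expect_true(any(dt$fst == 0))
  expect_true(all(dt$fst >= -0.05 & dt$fst <= 1))
  expect_true(all(dt$geographic_km >= 0))
  expect_equal(nrow(dt), nrow(pops) * nrow(gardens))
  # co-located population and garden: geographic distance 0
  pops2 <- rbind(pops, data.frame(taxon = "pilosa", population = "pilosa_pX",
                                  lon = gardens$lon[3], lat = gardens$lat[3]))
  dt2 <- distance_table(pops2, gardens)
  expect_equal(dt2$geographic_km[dt2$population == "pilosa_pX" &
                                   dt2$garden == gardens$garden[3]], 0)
})
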