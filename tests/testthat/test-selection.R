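test_that("derived leaf traits obey their defining ratios", {
  raw <- data.frame(length_mm = c(30, 12, 7), width_mm = c(3, 12, 7),
                    area_cm2 = c(10, 4, 2), dry_mass_g = c(0.05, 0.02, 0.01),
                    chlorophyll = c(35, 40, 28))
  out <- derive_leaf_traits(raw)
  expect_equal(out$sla_cm2_g[1], 200)
  expect_equal(out$ratio[1], 10)
  expect_equal(out$ratio[2], 1)  # square leaf
  raw$dry_mass_g[2] <- 0
  expect_error(derive_leaf_traits(raw), "dry mass.*2")
  expect_error(derive_leaf_traits(raw[-1]), "length_mm")
})

test_that("trait PCA recovers the two generating axes from synthetic data", {
  tr <- simulate_traits_fitness(simulation_params(seed = 30))
  pca <- fit_trait_pca(tr)
  expect_gt(sum(pca$var_prop[1:2]), 0.9)
  # the leading component is the between-taxon shape axis: its scores
  # track latent axis 1, the second tracks axis 2 (up to sign)
  expect_gt(abs(cor(pca$scores[, 1], tr$axis1)), 0.9)
  expect_gt(abs(cor(pca$scores[, 2], tr$axis2)), 0.9)
  # loading sign pattern matches the generating loadings up to a flip
  s <- sign(pca$rotation[c("length_mm", "width_mm", "ratio", "chlorophyll"), 1])
  gen <- sign(default_trait_loadings()[c("length", "width", "ratio",
                                         "chlorophyll"), 1])
  expect_true(all(s == gen) || all(s == -gen))
  # z-transformed scores are exactly standardized
  expect_lt(max(abs(colMeans(pca$scores_z))), 1e-10)
  expect_equal(unname(apply(pca$scores_z, 2, sd)), rep(1, 6),
               tolerance = 1e-10)
})

test_that("trait PCA output is invariant to row order and rejects degenerate input", {
  tr <- simulate_traits_fitness(simulation_params(seed = 31))
  pca <- fit_trait_pca(tr)
  idx <- sample(nrow(tr))
  pca2 <- fit_trait_pca(tr[idx, ])
  expect_equal(pca2$rotation, pca$rotation, tolerance = 1e-10)
  expect_equal(pca2$scores[order(idx), ], pca$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  tr$chlorophyll <- 35
  expect_error(fit_trait_pca(tr), "constant")
})

test_that("relative fitness normalizes to mean exactly one", {
  expect_equal(relative_fitness(rep(7, 5)), rep(1, 5))
  expect_equal(relative_fitness(c(0, 2)), c(0, 2))
  set.seed(32)
  w <- rpois(100, 4)
  expect_equal(mean(relative_fitness(w)), 1, tolerance = 1e-12)
  expect_error(relative_fitness(rep(0, 5)), "positive")
  expect_error(relative_fitness(c(-1, 2)), "non-negative")
})

test_that("selection-model slopes obey the OLS identity and recover the landscape", {
  tr <- simulate_traits_fitness(simulation_params(seed = 33))
  pca <- fit_trait_pca(tr)
  w <- relative_fitness(tr$fruit_number)
  res <- fit_selection_model(pca$scores_z, w, tr$taxon, scope = "all")
  sl <- res$estimate[res$term == "pc"]
  for (j in 1:2) {
    expect_equal(sl[j],
                 cov(pca$scores_z[, j], w) / var(pca$scores_z[, j]),
                 tolerance = 1e-10)
  }
  # within a species, the between-scale axis (PC1) does not predict fitness
  # but the within-scale axis (PC2) does
  within <- fit_selection_model(pca$scores_z, relative_fitness(
    tr$fruit_number[tr$taxon == "pilosa"]), tr$taxon, scope = "pilosa")
  p_pc <- setNames(within$p_value[within$term == "pc"],
                   within$pc[within$term == "pc"])
  expect_gt(p_pc[["PC1"]], 0.01)
  expect_lt(p_pc[["PC2"]], 1e-4)
  # interaction formula needs >= 2 taxa in scope
  expect_error(fit_selection_model(pca$scores_z, w, tr$taxon,
                                   scope = "pilosa",
                                   formula = "pc_plus_taxon_interaction"),
               "two taxa")
  res_int <- fit_selection_model(pca$scores_z, w, tr$taxon, scope = "all",
                                 formula = "pc_plus_taxon_interaction")
  expect_true(any(grepl("pc:taxon", res_int$term)))
})

test_that("a gamma2-only landscape shows no selection on the species axis", {
  tr <- simulate_traits_fitness(simulation_params(seed = 34, gamma1 = 0,
                                                  gamma2 = 0.3))
  pca <- fit_trait_pca(tr)
  w <- relative_fitness(tr$biomass)
  res <- fit_selection_model(pca$scores_z, w, tr$taxon, scope = "all")
  sl <- setNames(res$estimate[res$term == "pc"], res$pc[res$term == "pc"])
  expect_lt(abs(sl[["PC1"]]), 0.08)
  expect_gt(abs(sl[["PC2"]]), 0.15)
})

test_that("reconstitution is the exact eigenvector-coefficient product", {
  tr <- simulate_traits_fitness(simulation_params(seed = 35))
  pca <- fit_trait_pca(tr)
  A <- c(0.4, -0.2, 0.1)
  g <- reconstitute_gradients(pca, A, k = 3)
  expect_equal(unname(g$beta),
               unname(drop(pca$rotation[, 1:3] %*% A)), tolerance = 1e-12)
  expect_length(g$beta, 6)
  # identity eigenvectors return A itself
  fake <- pca
  fake$rotation <- diag(3)
  rownames(fake$rotation) <- colnames(fake$rotation) <- paste0("t", 1:3)
  expect_equal(unname(reconstitute_gradients(fake, A)$beta), A)
  expect_error(reconstitute_gradients(pca, A, k = 2), "length")
  expect_error(reconstitute_gradients(pca, rep(1, 7)), "exceeds")
})

test_that("beta is invariant to paired sign flips and zero-coefficient components", {
  tr <- simulate_traits_fitness(simulation_params(seed = 36))
  pca <- fit_trait_pca(tr)
  A <- c(0.3, -0.5, 0.2)
  g <- reconstitute_gradients(pca, A, k = 3)
  flipped <- pca
  flipped$rotation[, 2] <- -flipped$rotation[, 2]
  g2 <- reconstitute_gradients(flipped, A * c(1, -1, 1), k = 3)
  expect_equal(g2$beta, g$beta, tolerance = 1e-12)
  # adding a component with zero coefficient changes nothing
  g3 <- reconstitute_gradients(pca, c(A, 0), k = 4)
  expect_equal(g3$beta, g$beta, tolerance = 1e-12)
})

test_that("with z-scores each coefficient equals cov(score, relative fitness)", {
  tr <- simulate_traits_fitness(simulation_params(seed = 37))
  pca <- fit_trait_pca(tr)
  w <- relative_fitness(tr$flower_number)
  A <- pc_selection_coefficients(pca, w, k = 3)
  n <- length(w)
  for (j in 1:3) {
    # population (divide-by-n) covariance of the unit-SD regressor
    expect_equal(unname(A$A[j]),
                 cov(pca$scores_z[, j], w) * (n - 1) / n /
                   (var(pca$scores_z[, j]) * (n - 1) / n),
                 tolerance = 1e-10)
  }
})

test_that("full-rank reconstitution on raw scores equals direct trait-space OLS", {
  set.seed(38)
  for (i in 1:20) {
    n <- 60
    base <- matrix(rnorm(n * 3), n)
    x <- base %*% matrix(rnorm(18), 3) + matrix(rnorm(n * 6), n) * 0.5
    colnames(x) <- paste0("t", 1:6)
    w <- relative_fitness(exp(rnorm(n)))
    pca <- fit_trait_pca(as.data.frame(x))
    A <- pc_selection_coefficients(pca, w, k = 6, rescale = FALSE)
    beta <- reconstitute_gradients(pca, A)$beta
    direct <- coef(lm(w ~ scale(x)))[-1]
    expect_equal(unname(beta), unname(direct), tolerance = 1e-8)
  }
})

test_that("scale comparison reports angles and sign agreement", {
  b1 <- setNames(c(1, 0, 0, 0, 0, 0), paste0("t", 1:6))
  cmp0 <- compare_scales(b1, b1)
  expect_equal(cmp0$angle_deg, 0)
  expect_true(all(cmp0$table$sign_agree))
  b2 <- setNames(c(0, 1, 0, 0, 0, 0), paste0("t", 1:6))
  expect_equal(compare_scales(b1, b2)$angle_deg, 90)
  expect_error(compare_scales(b1, setNames(b2, paste0("u", 1:6))),
               "different traits")
})
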