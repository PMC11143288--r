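#' Derive composite leaf traits from raw measurements
#'
#' Appends the length/width ratio and the specific leaf area
#' `SLA = area (cm^2) / dry mass (g)` to a table of raw leaf
#' measurements; length, width, area and chlorophyll pass through.
#'
#' @param raw Data frame with columns `length_mm`, `width_mm`, `area_cm2`,
#'   `dry_mass_g` and `chlorophyll` (other columns are passed through).
#' @return The input with `ratio` and `sla_cm2_g` appended.
#' @export
#' @examples
#' derive_leaf_traits(data.frame(length_mm = 30, width_mm = 3,
#'                               area_cm2 = 10, dry_mass_g = 0.05,
#'                               chlorophyll = 35))
derive_leaf_traits <- function(raw) {
  need <- c("length_mm", "width_mm", "area_cm2", "dry_mass_g", "chlorophyll")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing measurement column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(raw$dry_mass_g) | raw$dry_mass_g <= 0)
  if (length(bad))
    stop("non-positive dry mass in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad2 <- which(raw$length_mm <= 0 | raw$width_mm <= 0 | raw$area_cm2 <= 0)
  if (length(bad2))
    stop("non-positive length/width/area in row(s): ",
         paste(utils::head(bad2, 10), collapse = ", "))
  raw$ratio <- raw$length_mm / raw$width_mm
  raw$sla_cm2_g <- raw$area_cm2 / raw$dry_mass_g
  raw
}

# canonical trait order used throughout the selection analysis
leaf_trait_columns <- function() {
  c("length_mm", "width_mm", "ratio", "area_cm2", "chlorophyll", "sla_cm2_g")
}

#' Correlation-matrix PCA of the leaf traits
#'
#' Scales each trait to unit variance, decomposes, fixes each
#' eigenvector's sign by making its largest-magnitude loading positive,
#' and emits both the raw scores and z-transformed scores (each retained
#' component rescaled to mean 0, SD 1).  The per-component standard
#' deviations used for the z-transform are stored so coefficient scales
#' can be undone.
#'
#' @param traits Data frame containing the six leaf-trait columns (see
#'   `leaf_trait_columns()`), or any all-numeric trait table.
#' @param columns Trait columns to use; defaults to the six leaf traits
#'   when present, otherwise all numeric columns.
#' @return Object of class `"trait_pca"`: `traits` (names), `center`,
#'   `scale`, `rotation` (eigenvector matrix E), `eigenvalues`,
#'   `var_prop`, `scores` (raw PC scores), `scores_z` (z-transformed),
#'   `score_sd` (SD removed by the z-transform).
#' @export
fit_trait_pca <- function(traits, columns = NULL) {
  traits <- as.data.frame(traits)
  if (is.null(columns)) {
    columns <- if (all(leaf_trait_columns() %in% names(traits)))
      leaf_trait_columns()
    else names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  x <- as.matrix(traits[columns])
  if (nrow(x) <= ncol(x))
    stop("need more rows than traits (", ncol(x), ") for a stable PCA")
  if (anyNA(x)) stop("missing values in trait columns")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant trait(s): ", paste(columns[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  eig <- pc$sdev^2
  score_sd <- apply(pc$x, 2, sd)
  structure(list(traits = columns,
                 center = pc$center, scale = pc$scale,
                 rotation = pc$rotation,
                 eigenvalues = eig, var_prop = eig / sum(eig),
                 scores = pc$x,
                 scores_z = sweep(pc$x, 2, score_sd, "/"),
                 score_sd = score_sd),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("Leaf-trait correlation PCA (%d traits, %d rows)\n",
              length(x$traits), nrow(x$scores)))
  vp <- round(100 * x$var_prop, 1)
  cat("  variance explained:",
      paste0("PC", seq_along(vp), " ", vp, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Relative fitness: normalize a fitness measure around its mean
#'
#' @param w Non-negative fitness vector with positive mean.
#' @return `w / mean(w)`; the output mean is exactly 1.
#' @export
relative_fitness <- function(w) {
  if (any(w < 0, na.rm = TRUE)) stop("fitness must be non-negative")
  m <- mean(w, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("mean fitness must be positive")
  w / m
}

#' Selection models of fitness on PC scores
#'
#' Ordinary least squares of relative fitness on leaf-trait PC scores, at
#' a chosen scope.  `formula = "pc_only"` fits one simple regression per
#' requested PC (how does each axis predict fitness in this subset?);
#' `"pc_plus_taxon_interaction"` fits, per PC, `w ~ PC * taxon` (does the
#' strength of selection on the axis differ among taxa?).
#'
#' @param scores Matrix of PC scores (rows = individuals); typically
#'   `pca$scores_z`.
#' @param fitness Relative-fitness vector (see [relative_fitness()]).
#' @param taxon Taxon label per individual (needed for scoping and the
#'   interaction formula).
#' @param scope `"all"` or one taxon label; rows outside the scope are
#'   dropped before fitting.
#' @param formula `"pc_only"` (default) or `"pc_plus_taxon_interaction"`.
#' @param pcs Which components to model (default first two).
#' @return Data frame with one row per coefficient: `scope`, `fitness`,
#'   `pc`, `term`, `estimate`, `se`, `p_value`, `r_squared`, `n`.
#' @export
fit_selection_model <- function(scores, fitness, taxon = NULL, scope = "all",
                                formula = c("pc_only",
                                            "pc_plus_taxon_interaction"),
                                pcs = 1:2) {
  formula <- match.arg(formula)
  scores <- as.matrix(scores)
  if (scope != "all") {
    if (is.null(taxon)) stop("taxon labels required to subset to a scope")
    keep <- taxon == scope
    if (!any(keep)) stop("scope '", scope, "' matches no rows")
    scores <- scores[keep, , drop = FALSE]
    # fitness may already be normalized within (and aligned to) the scope
    if (length(fitness) != sum(keep)) fitness <- fitness[keep]
    taxon <- taxon[keep]
  }
  if (formula == "pc_plus_taxon_interaction" &&
      (is.null(taxon) || length(unique(taxon)) < 2))
    stop("interaction formula requires at least two taxa in scope")
  out <- NULL
  for (j in pcs) {
    pc_name <- colnames(scores)[j] %||% paste0("PC", j)
    d <- data.frame(w = fitness, pc = scores[, j])
    if (formula == "pc_only") {
      fit <- lm(w ~ pc, data = d)
    } else {
      d$taxon <- factor(taxon)
      fit <- lm(w ~ pc * taxon, data = d)
    }
    sm <- summary(fit)
    co <- sm$coefficients
    out <- rbind(out, data.frame(
      scope = scope, pc = pc_name, term = rownames(co),
      estimate = co[, 1], se = co[, 2], p_value = co[, 4],
      r_squared = sm$r.squared, n = nrow(d),
      row.names = NULL, stringsAsFactors = FALSE))
  }
  out
}

#' Selection coefficients on the first k PC scores
#'
#' Multiple regression of relative fitness on the first `k` z-transformed
#' PC scores jointly; the coefficient vector is the `A` of the
#' reconstitution `beta = E_k A`.
#'
#' @param pca A [fit_trait_pca()] object.
#' @param fitness Relative-fitness vector aligned with the PCA rows.
#' @param k Number of leading components (default 3).
#' @param subset Optional logical/integer subset of rows (e.g. one taxon);
#'   scores are re-z-transformed within the subset by default
#'   (`rescale = TRUE`), matching a subset-then-transform order.
#' @param rescale Re-standardize the subset scores to mean 0, SD 1.
#' @return List with `A` (coefficients), `se`, `p_value`, `k`,
#'   `scaling` (`"z"` or `"raw"`), and the `lm` fit.
#' @export
pc_selection_coefficients <- function(pca, fitness, k = 3, subset = NULL,
                                      rescale = TRUE) {
  S <- pca$scores[, seq_len(k), drop = FALSE]
  if (!is.null(subset)) {
    S <- S[subset, , drop = FALSE]
    # fitness may already be given for the subset only (e.g. normalized
    # within it); subset it only when it still spans all rows
    if (length(fitness) != nrow(S)) fitness <- fitness[subset]
  }
  if (rescale) S <- scale(S)
  fit <- lm(fitness ~ S)
  co <- summary(fit)$coefficients
  A <- setNames(coef(fit)[-1], colnames(S))
  list(A = A, se = co[-1, 2], p_value = co[-1, 4], k = k,
       scaling = if (rescale) "z" else "raw", fit = fit)
}

#' Reconstitute selection gradients from PC space onto the traits
#'
#' Multiplies the eigenvector submatrix of the leaf-trait PCA by the
#' vector of PC-score selection coefficients: `beta = E_k A`, mapping
#' selection measured on `k` principal components back onto the original
#' (unit-variance) traits, where the entries are biologically readable.
#'
#' @param pca A [fit_trait_pca()] object (provides `E`).
#' @param A Numeric vector of PC selection coefficients (length `k`), as
#'   from [pc_selection_coefficients()] (a list result is also accepted).
#' @param k Number of leading components; default `length(A)`.
#' @param scope,fitness_trait Optional labels carried into the result.
#' @param scaling `"z"` if `A` was estimated on z-transformed scores,
#'   `"raw"` otherwise; recorded in the result.
#' @return Object of class `"selection_gradients"`: `beta` (named
#'   6-vector), `A`, `E_k`, `k`, `scaling`, `scope`, `fitness_trait`.
#' @export
reconstitute_gradients <- function(pca, A, k = NULL, scope = "all",
                                   fitness_trait = NA_character_,
                                   scaling = "z") {
  if (is.list(A) && !is.null(A$A)) {
    scaling <- A$scaling %||% scaling
    A <- A$A
  }
  A <- as.numeric(A)
  k <- k %||% length(A)
  if (length(A) != k)
    stop("A has length ", length(A), " but k = ", k)
  if (k > ncol(pca$rotation))
    stop("k = ", k, " exceeds the ", ncol(pca$rotation), " available components")
  Ek <- pca$rotation[, seq_len(k), drop = FALSE]
  beta <- drop(Ek %*% A)
  names(beta) <- rownames(Ek)
  structure(list(beta = beta, A = setNames(A, colnames(Ek)), E_k = Ek,
                 k = k, scaling = scaling, scope = scope,
                 fitness_trait = fitness_trait),
            class = "selection_gradients")
}

#' @export
print.selection_gradients <- function(x, ...) {
  cat(sprintf("Reconstituted selection gradients (scope %s, fitness %s, k = %d, %s scores)\n",
              x$scope, x$fitness_trait, x$k, x$scaling))
  print(round(x$beta, 3))
  invisible(x)
}

#' Compare selection gradients between scales
#'
#' Tabulates, per trait, the between-scale (all species) and within-scale
#' (one species) reconstituted gradients, whether their signs agree and
#' their absolute difference, plus the angle in degrees between the two
#' full gradient vectors.  Orthogonal axes of selection at the two scales
#' show up as angles near 90 degrees.
#'
#' @param between,within Two [reconstitute_gradients()] objects (or named
#'   beta vectors) over the same traits.
#' @return List with `table` (per-trait data frame) and `angle_deg`.
#' @export
compare_scales <- function(between, within) {
  b <- if (inherits(between, "selection_gradients")) between$beta else between
  w <- if (inherits(within, "selection_gradients")) within$beta else within
  if (!identical(names(b), names(w)))
    stop("gradient vectors cover different traits")
  cosang <- sum(b * w) / (sqrt(sum(b^2)) * sqrt(sum(w^2)))
  cosang <- max(-1, min(1, cosang))
  list(
    table = data.frame(trait = names(b),
                       beta_between = unname(b), beta_within = unname(w),
                       sign_agree = sign(b) == sign(w),
                       abs_difference = abs(b - w),
                       row.names = NULL, stringsAsFactors = FALSE),
    angle_deg = acos(cosang) * 180 / pi
  )
}

#' Two-scale selection-gradient analysis of a trait/fitness table
#'
#' Runs the full selection stage: leaf-trait PCA, relative fitness per
#' fitness measure, PC selection coefficients at the all-species scale
#' and within one focal species, reconstitution at both scales, and the
#' between-vs-within comparison.
#'
#' @param traits Data frame with the leaf-trait columns, a `taxon` column
#'   and the fitness columns.
#' @param fitness_traits Fitness columns to analyse.
#' @param focal_species The within-scale species.
#' @param k Components used for reconstitution (default 3).
#' @return List with the `pca`, per-fitness-measure `gradients`
#'   (`between`, `within`, `comparison`) and a long `beta_table`.
#' @export
selection_analysis <- function(traits,
                               fitness_traits = c("flower_number",
                                                  "fruit_number", "biomass"),
                               focal_species, k = 3) {
  pca <- fit_trait_pca(traits)
  res <- list()
  beta_table <- NULL
  for (ft in fitness_traits) {
    w_all <- relative_fitness(traits[[ft]])
    sub <- traits$taxon == focal_species
    w_sub <- relative_fitness(traits[[ft]][sub])
    A_all <- pc_selection_coefficients(pca, w_all, k = k)
    A_sub <- pc_selection_coefficients(pca, w_sub, k = k,
                                       subset = which(sub))
    g_all <- reconstitute_gradients(pca, A_all, scope = "all",
                                    fitness_trait = ft)
    g_sub <- reconstitute_gradients(pca, A_sub, scope = focal_species,
                                    fitness_trait = ft)
    cmp <- compare_scales(g_all, g_sub)
    res[[ft]] <- list(between = g_all, within = g_sub, comparison = cmp)
    beta_table <- rbind(beta_table,
                        data.frame(fitness_trait = ft, cmp$table,
                                   angle_deg = cmp$angle_deg,
                                   stringsAsFactors = FALSE))
  }
  list(pca = pca, gradients = res, beta_table = beta_table)
}
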