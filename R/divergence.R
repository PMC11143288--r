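#' Fit the per-trait adaptive-divergence mixed model
#'
#' For one fitness trait, fits the generalized linear mixed model with
#' fixed effects of taxon, garden and their interaction and random
#' intercepts of genotype nested within source population:
#' `trait ~ taxon * garden + (1 | population) + (1 | population:genotype)`.
#' Binary traits use a binomial-logit family, counts Poisson-log, and
#' biomass is natural-log transformed and fit with a Gaussian linear
#' mixed model.  Estimation is by Laplace-approximate maximum likelihood
#' (REML for the Gaussian path), recorded in the metadata.  Clonal
#' replicates of a genotype (e.g. the duplicated rare-taxon plants) are
#' absorbed by the genotype intercept.
#'
#' Non-convergence is flagged, never silent.  For binomial traits the
#' taxon-by-garden cells are checked for complete separation (a cell with
#' all 0 or all 1 responses); offending cells are recorded in
#' `separation_cells`.
#'
#' @param dataset A `"fitness_dataset"` (or data frame with `garden`,
#'   `taxon`, `population`, `genotype` and the trait column).
#' @param trait Trait column name.
#' @param family `"binomial"`, `"poisson"` or `"gaussian"`; default
#'   chosen from the trait name ([default_family] rules).
#' @return Object of class `"fitness_model_fit"`: the `lme4` fit,
#'   coefficients with covariance, variance components, conditional
#'   modes, convergence flag and metadata.
#' @export
fit_fitness_model <- function(dataset, trait, family = NULL) {
  family <- family %||% default_family(trait)
  d <- as.data.frame(dataset)
  for (v in c("garden", "taxon", "population", "genotype"))
    d[[v]] <- factor(d[[v]])
  if (nlevels(d$taxon) < 2 || nlevels(d$garden) < 2)
    stop("need at least 2 taxa and 2 gardens")
  d$.y <- trait_response(d, trait, family)
  d$pg <- interaction(d$population, d$genotype, sep = "|", drop = TRUE)

  separation <- character(0)
  if (family == "binomial") {
    cell_tab <- tapply(d$.y, list(d$taxon, d$garden), function(v)
      length(unique(na.omit(v))) < 2)
    bad <- which(cell_tab, arr.ind = TRUE)
    if (nrow(bad))
      separation <- paste(rownames(cell_tab)[bad[, 1]],
                          colnames(cell_tab)[bad[, 2]], sep = ":")
  }

  form <- .y ~ taxon * garden + (1 | population) + (1 | pg)
  fit <- if (family == "gaussian") {
    lme4::lmer(form, data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    lme4::glmer(form, data = d, family = family,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             optCtrl = list(maxfun = 1e5),
                                             check.conv.singular = "ignore"))
  }
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, trait = trait, family = family,
                 coefficients = lme4::fixef(fit),
                 vcov = as.matrix(vcov(fit)),
                 variance_components = setNames(vc$vcov, vc$grp),
                 conditional_modes = lme4::ranef(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 converged = conv,
                 separation_cells = separation,
                 taxa = levels(d$taxon), gardens = levels(d$garden),
                 estimation = if (family == "gaussian") "REML"
                              else "Laplace ML",
                 data = d),
            class = "fitness_model_fit")
}

#' @export
print.fitness_model_fit <- function(x, ...) {
  cat(sprintf("Adaptive-divergence GLMM: %s (%s, %s)\n",
              x$trait, x$family, x$estimation))
  cat(sprintf("  %d taxa x %d gardens; converged: %s\n",
              length(x$taxa), length(x$gardens), x$converged))
  if (length(x$separation_cells))
    cat("  separation in cells:", paste(x$separation_cells, collapse = ", "), "\n")
  vc <- x$variance_components
  cat(sprintf("  variance components: population %.3g, genotype %.3g\n",
              vc[["population"]], vc[["pg"]]))
  invisible(x)
}

#' Wald chi-square test of the taxon-by-garden interaction
#'
#' Analysis-of-deviance evaluation of the fitted divergence model: a Wald
#' chi-square test of the joint taxon-by-garden coefficient block, Type II
#' by default (main effects retained), with
#' `df = (n_taxa - 1)(n_gardens - 1)`.  A significant interaction means
#' the relative performance of the taxa depends on the garden — the
#' statistical footprint of adaptive divergence.
#'
#' @param fit A [fit_fitness_model()] result.
#' @param type `"II"` (default) or `"III"` sums-of-squares ordering.
#' @return List with `statistic` (chi-square), `df`, `p_value`, `type`
#'   and `trait`.
#' @export
test_interaction <- function(fit, type = c("II", "III")) {
  type <- match.arg(type)
  if (!fit$converged)
    warning("model for ", fit$trait, " did not converge; test may be unreliable")
  if (any(!is.finite(fit$vcov)) ||
      qr(fit$vcov)$rank < nrow(fit$vcov))
    stop("singular coefficient covariance: interaction test undefined")
  an <- car::Anova(fit$fit, type = type, test.statistic = "Chisq")
  row <- grep("taxon:garden", rownames(an))
  stat_col <- intersect(c("Chisq", "F"), colnames(an))[1]
  list(statistic = an[row, stat_col],
       df = an[row, "Df"],
       p_value = an[row, grep("^Pr", colnames(an))],
       type = type, trait = fit$trait)
}

# model matrix rows for the taxon x garden cell means (link scale),
# averaged over nothing: random effects are 0 at the conditional mean
cell_mean_matrix <- function(fit) {
  cells <- expand.grid(taxon = fit$taxa, garden = fit$gardens,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$taxon <- factor(cells$taxon, levels = fit$taxa)
  cells$garden <- factor(cells$garden, levels = fit$gardens)
  X <- model.matrix(~ taxon * garden, cells)
  rownames(X) <- paste(cells$taxon, cells$garden, sep = ":")
  list(cells = cells, X = X)
}

#' Local-vs-foreign and home-vs-away contrasts among cell means
#'
#' Builds linear contrasts among the taxon-by-garden cell means of a
#' fitted divergence model, on the link scale, and tests them jointly
#' with a single-step (Tukey-style) adjustment over the contrast set
#' using the joint normal approximation (via \pkg{multcomp}); if the
#' joint covariance is unusable a Holm adjustment is applied instead and
#' recorded.
#'
#' Contrast sign convention: positive estimates are the pattern predicted
#' by adaptive divergence.  `local_vs_foreign` compares, within each
#' garden, the garden's local taxon minus each foreign taxon;
#' `home_vs_away` compares, within each taxon, its home garden minus each
#' away garden.
#'
#' @param fit A [fit_fitness_model()] result.
#' @param scheme `"local_vs_foreign"` or `"home_vs_away"`.
#' @param garden_to_taxon Named character vector mapping each garden to
#'   its local taxon.
#' @return Data frame of class `"contrast_result"`: `trait`, `scheme`,
#'   `garden`, `focal_taxon`, `comparison`, `estimate` (link scale),
#'   `se`, `p_adj`, `supports_adaptation` (estimate > 0 and `p_adj` <
#'   0.05); attribute `adjustment` records the method used.
#' @export
cell_mean_contrasts <- function(fit,
                                scheme = c("local_vs_foreign", "home_vs_away"),
                                garden_to_taxon) {
  scheme <- match.arg(scheme)
  if (!fit$converged)
    warning("model for ", fit$trait, " did not converge; contrasts may be unreliable")
  stopifnot(all(fit$gardens %in% names(garden_to_taxon)))
  if (!all(garden_to_taxon[fit$gardens] %in% fit$taxa))
    stop("garden_to_taxon maps to taxa absent from the fit")
  cm <- cell_mean_matrix(fit)
  X <- cm$X
  rows <- list()
  meta <- list()
  if (scheme == "local_vs_foreign") {
    for (g in fit$gardens) {
      local <- garden_to_taxon[[g]]
      for (foreign in setdiff(fit$taxa, local)) {
        k <- X[paste(local, g, sep = ":"), ] - X[paste(foreign, g, sep = ":"), ]
        nm <- sprintf("%s: %s - %s", g, local, foreign)
        rows[[nm]] <- k
        meta[[nm]] <- data.frame(garden = g, focal_taxon = local,
                                 comparison = foreign,
                                 stringsAsFactors = FALSE)
      }
    }
  } else {
    taxon_home <- setNames(names(garden_to_taxon), garden_to_taxon)
    missing_home <- setdiff(fit$taxa, names(taxon_home))
    if (length(missing_home))
      stop("no home garden mapped for taxa: ",
           paste(missing_home, collapse = ", "))
    for (tx in fit$taxa) {
      home <- taxon_home[[tx]]
      for (away in setdiff(fit$gardens, home)) {
        k <- X[paste(tx, home, sep = ":"), ] - X[paste(tx, away, sep = ":"), ]
        nm <- sprintf("%s: %s - %s", tx, home, away)
        rows[[nm]] <- k
        meta[[nm]] <- data.frame(garden = home, focal_taxon = tx,
                                 comparison = away,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  K <- do.call(rbind, rows)
  adj <- "single-step"
  sm <- tryCatch(
    summary(multcomp::glht(fit$fit, linfct = K),
            test = multcomp::adjusted("single-step")),
    error = function(e) NULL)
  if (is.null(sm)) {
    adj <- "holm"
    sm <- summary(multcomp::glht(fit$fit, linfct = K),
                  test = multcomp::adjusted("holm"))
  }
  out <- cbind(
    data.frame(trait = fit$trait, scheme = scheme, stringsAsFactors = FALSE),
    do.call(rbind, meta),
    data.frame(estimate = unname(sm$test$coefficients),
               se = unname(sm$test$sigma),
               p_adj = unname(sm$test$pvalues),
               stringsAsFactors = FALSE)
  )
  out$supports_adaptation <- out$estimate > 0 & out$p_adj < 0.05
  rownames(out) <- NULL
  attr(out, "adjustment") <- adj
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Full divergence analysis for a set of fitness traits
#'
#' Convenience wrapper producing the per-trait interaction tests and both
#' contrast schemes (the shape of a reciprocal-transplant results table).
#'
#' @param dataset A `"fitness_dataset"`.
#' @param traits Trait columns to analyse.
#' @param garden_to_taxon Named character vector garden -> local taxon.
#' @return List with `interaction_tests` (data frame) and `contrasts`
#'   (data frame over both schemes and all traits), plus the fits.
#' @export
divergence_analysis <- function(dataset,
                                traits = c("herbivory", "flower_number",
                                           "fruit_number", "biomass",
                                           "survival"),
                                garden_to_taxon) {
  fits <- lapply(traits, function(tr) fit_fitness_model(dataset, tr))
  names(fits) <- traits
  itests <- do.call(rbind, lapply(fits, function(f) {
    t <- test_interaction(f)
    data.frame(trait = t$trait, chisq = t$statistic, df = t$df,
               p_value = t$p_value, stringsAsFactors = FALSE)
  }))
  contrasts <- do.call(rbind, lapply(fits, function(f) {
    rbind(as.data.frame(cell_mean_contrasts(f, "local_vs_foreign",
                                            garden_to_taxon)),
          as.data.frame(cell_mean_contrasts(f, "home_vs_away",
                                            garden_to_taxon)))
  }))
  rownames(itests) <- rownames(contrasts) <- NULL
  list(interaction_tests = itests, contrasts = contrasts, fits = fits)
}
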