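#' Run the full multi-scale adaptation pipeline
#'
#' Orchestrates the four analysis stages — `niche`, `divergence`,
#' `provenance`, `selection` — over either user-supplied input files or a
#' synthetic dataset generated in-run, writes every stage's tables under
#' `out_dir`, and returns a run report (per-stage status, warnings, file
#' manifest with checksums).  Deterministic given the config and seed.
#'
#' The config (a list, or the path of a YAML file with the same shape)
#' holds exactly one of:
#' * `synthetic`: a list passed to [simulation_params()]; `seed` is
#'   mandatory here.
#' * `inputs`: paths `fitness`, `traits`, `occurrences`, `genotypes`
#'   (+`genotype_format`, `pop_map`), `populations`, `gardens` — only the
#'   ones the requested stages need.
#'
#' plus optional `stages` (default all four), `garden_to_taxon` (default
#' taken from the gardens table), `focal_species` (default the taxon
#' local to `focal_garden`, falling back to the last garden's taxon),
#' `alpha` (0.05), `n_perm` (1000), and `niche_threshold` (0.8).
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return A `"run_report"`: per-stage status, warnings, the file
#'   manifest (path + md5), the config hash, package version, and the
#'   stage results themselves in `$results`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings <- character(0)
  note <- function(...) warnings <<- c(warnings, sprintf(...))
  status <- setNames(rep("skipped", 4),
                     c("niche", "divergence", "provenance", "selection"))
  results <- list()
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    if (grepl("\\.json$", name))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    else write.csv(as.data.frame(x), p, row.names = FALSE)
    files <<- c(files, p)
    invisible(p)
  }

  # ---- assemble inputs ------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    params <- do.call(simulation_params, cfg$synthetic)
    occ <- simulate_occurrences(params)
    fitness <- simulate_transplant(params)
    traits <- simulate_traits_fitness(params)
    genotypes <- simulate_genotypes(params)
    populations <- site_environment(params, attr(fitness, "populations"))
    gardens <- site_environment(params, attr(fitness, "gardens"))
    write_params_yaml(params, file.path(out_dir, "params.yaml"))
    files <- c(files, file.path(out_dir, "params.yaml"))
  } else {
    ins <- cfg$inputs
    need <- function(what, stage) {
      if (is.null(ins[[what]]))
        stop("stage '", stage, "' requires input '", what, "'")
      ins[[what]]
    }
    occ <- fitness <- traits <- genotypes <- populations <- gardens <- NULL
    if ("niche" %in% cfg$stages)
      occ <- read.csv(need("occurrences", "niche"), stringsAsFactors = FALSE)
    if (any(c("divergence", "provenance") %in% cfg$stages))
      fitness <- read.csv(need("fitness", "divergence/provenance"),
                          stringsAsFactors = FALSE)
    if ("selection" %in% cfg$stages)
      traits <- read.csv(need("traits", "selection"), stringsAsFactors = FALSE)
    if ("provenance" %in% cfg$stages) {
      populations <- read.csv(need("populations", "provenance"),
                              stringsAsFactors = FALSE)
      gardens <- read.csv(need("gardens", "provenance"),
                          stringsAsFactors = FALSE)
      if (!is.null(ins$genotypes))
        genotypes <- read_genotypes(ins$genotypes,
                                    ins$genotype_format %||% "vcf",
                                    ins$pop_map)
    }
    if (!is.null(gardens) && is.null(cfg$garden_to_taxon) &&
        "local_taxon" %in% names(gardens))
      cfg$garden_to_taxon <- setNames(gardens$local_taxon, gardens$garden)
  }
  if (is.null(cfg$garden_to_taxon) && !is.null(gardens))
    cfg$garden_to_taxon <- setNames(gardens$local_taxon, gardens$garden)

  env_pca <- NULL

  # ---- niche ----------------------------------------------------------
  if ("niche" %in% cfg$stages) {
    env_cols <- setdiff(names(occ)[vapply(occ, is.numeric, logical(1))],
                        c("lon", "lat"))
    retained <- filter_collinear(occ[env_cols], cfg$niche_threshold)
    env_pca <- fit_env_pca(occ, retained)
    nt <- permutation_niche_test(env_pca$scores[, 1:2], occ$species,
                                 n_perm = cfg$n_perm, seed = cfg$seed)
    emit(data.frame(variable = rownames(env_pca$rotation),
                    env_pca$rotation, check.names = FALSE),
         "niche_loadings.csv")
    emit(data.frame(species = occ$species, env_pca$scores, check.names = FALSE),
         "niche_scores.csv")
    emit(list(species = nt$species,
              observed = as.data.frame(t(nt$observed)),
              p_values = as.data.frame(t(nt$p_values)),
              n_perm = nt$n_perm, seed = nt$seed, resample = nt$resample,
              retained_variables = retained),
         "niche_comparison.json")
    results$niche <- list(pca = env_pca, test = nt, retained = retained)
    status["niche"] <- "ok"
  }

  # ---- divergence -----------------------------------------------------
  if ("divergence" %in% cfg$stages) {
    traits_avail <- intersect(c("herbivory", "flower_number", "fruit_number",
                                "biomass", "survival"), names(fitness))
    div <- divergence_analysis(fitness, traits_avail, cfg$garden_to_taxon)
    for (tr in traits_avail) {
      f <- div$fits[[tr]]
      if (!f$converged) note("divergence model for %s did not converge", tr)
      if (length(f$separation_cells))
        note("separation in %s cells: %s", tr,
             paste(f$separation_cells, collapse = ", "))
    }
    emit(div$interaction_tests, "divergence_interaction_tests.csv")
    emit(div$contrasts, "divergence_contrasts.csv")
    results$divergence <- div
    status["divergence"] <- "ok"
  }

  # ---- provenance -----------------------------------------------------
  if ("provenance" %in% cfg$stages) {
    use_env <- !is.null(env_pca) &&
      all(env_pca$variables %in% names(populations)) &&
      all(env_pca$variables %in% names(gardens))
    if (!is.null(env_pca) && !use_env)
      note("environmental distance skipped: PCA variables absent from site tables")
    dt <- distance_table(populations, gardens,
                         env_pca = if (use_env) env_pca else NULL,
                         genotypes = genotypes)
    emit(dt, "distance_table.csv")
    dist_types <- intersect(c("geographic_km", "environmental", "fst"),
                            names(dt))
    species <- cfg$provenance_species %||%
      names(which(table(populations$taxon[match(unique(fitness$population),
                                                populations$population)]) >= 3))
    traits_avail <- intersect(c("herbivory", "flower_number", "fruit_number",
                                "biomass", "survival"), names(fitness))
    eff_rows <- NULL
    reg_rows <- NULL
    for (sp in species) {
      for (tr in traits_avail) {
        pe <- extract_population_effects(fitness, sp, tr)
        if (pe$insufficient_variation) {
          note("insufficient variation in %s among %s populations", tr, sp)
          next
        }
        eff_rows <- rbind(eff_rows, pe$effects)
        for (g in unique(pe$effects$garden)) {
          for (dty in dist_types) {
            r <- tryCatch(provenance_regression(pe, dt, dty, garden = g,
                                                alpha = cfg$alpha),
                          error = function(e) NULL)
            if (is.null(r)) next
            reg_rows <- rbind(reg_rows, data.frame(
              species = sp, garden = g, trait = tr, distance_type = dty,
              slope = r$slope, intercept = r$intercept,
              r_squared = r$r_squared, p_value = r$p_value, n = r$n,
              local_adaptation = r$local_adaptation,
              stringsAsFactors = FALSE))
          }
        }
      }
    }
    emit(eff_rows, "population_effects.csv")
    emit(reg_rows, "provenance_regressions.csv")
    results$provenance <- list(distances = dt, effects = eff_rows,
                               regressions = reg_rows)
    status["provenance"] <- "ok"
  }

  # ---- selection ------------------------------------------------------
  if ("selection" %in% cfg$stages) {
    focal <- cfg$focal_species %||%
      cfg$garden_to_taxon[[length(cfg$garden_to_taxon)]]
    sel <- selection_analysis(traits, focal_species = focal)
    emit(data.frame(trait = rownames(sel$pca$rotation), sel$pca$rotation,
                    check.names = FALSE), "selection_loadings.csv")
    emit(sel$beta_table, "selection_gradients.csv")
    results$selection <- sel
    status["selection"] <- "ok"
  }

  manifest <- data.frame(path = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  report <- structure(list(
    status = status,
    warnings = warnings,
    manifest = manifest,
    config_hash = unname(tools::md5sum(write_tmp_yaml(config))),
    version = as.character(packageVersion("adaptscape")),
    results = results
  ), class = "run_report")
  jsonlite::write_json(
    list(status = as.list(status), warnings = warnings,
         manifest = manifest, config_hash = report$config_hash,
         version = report$version),
    file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

write_tmp_yaml <- function(config) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, f)
  f
}

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or YAML path")
  has_syn <- !is.null(config$synthetic)
  has_in <- !is.null(config$inputs)
  if (has_syn == has_in)
    stop("config must contain exactly one of 'synthetic' or 'inputs'")
  if (has_syn && is.null(config$synthetic$seed))
    stop("seed is mandatory for a synthetic run")
  config$stages <- config$stages %||%
    c("niche", "divergence", "provenance", "selection")
  bad <- setdiff(config$stages,
                 c("niche", "divergence", "provenance", "selection"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$alpha <- config$alpha %||% 0.05
  config$n_perm <- config$n_perm %||% 1000
  config$niche_threshold <- config$niche_threshold %||% 0.8
  config$seed <- config$seed %||% config$synthetic$seed %||% 1
  if (!is.null(config$garden_to_taxon))
    config$garden_to_taxon <- unlist(config$garden_to_taxon)
  config
}

#' @export
print.run_report <- function(x, ...) {
  cat("adaptscape pipeline run (v", x$version, ")\n", sep = "")
  for (s in names(x$status))
    cat(sprintf("  %-10s %s\n", s, x$status[s]))
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  cat(nrow(x$manifest), "files written\n")
  invisible(x)
}
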