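# shared simulation shorthands for the test suite

garden_taxon_map <- function() {
  g <- default_gardens()
  setNames(g$local_taxon, g$garden)
}

# zeroed fixed effects (intercepts kept) for null-model simulations
null_effects <- function(intercepts = c(herbivory = 0.5, flower_number = 2,
                                        fruit_number = 1.5, biomass = 0.7,
                                        survival = 1)) {
  list(intercepts = intercepts,
       taxon = c(amoena = 0, deamii = 0, pilosa = 0),
       garden = c(amoena_garden = 0, deamii_garden = 0, pilosa_garden = 0),
       local_advantage = 0)
}

# a reduced design for structural tests where model fits must be quick
small_params <- function(seed = 1, n_loci = 200, ...) {
  taxa <- default_taxa()
  taxa$n_populations <- c(3L, 3L, 3L)
  taxa$n_genotypes <- c(18L, 9L, 18L)
  simulation_params(seed = seed, taxa = taxa, n_loci = n_loci, ...)
}
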