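# Shared fixtures, all generated in code. `tiny_cfg()` is a fast 24 x 24
# domain for unit tests; `study_fixture()` builds (and caches) the full
# 120 x 120 / 12 x 12, 10-year study-scale fixture used by the
# property-based suite.

tiny_cfg <- function(seed = 42, ...) {
  synthetic_config(seed = seed, fine_grid = c(24L, 24L), coarsening_factor = 4L,
                   ...)
}

# deterministic small emissions field: values 1..n laid out by cell, constant
# over months
ramp_field <- function(nr, nc, n_months = 2, years = 2005, species = "DM",
                       units = "kg") {
  data <- array(rep(seq_len(nr * nc), n_months), c(nr, nc, n_months))
  time <- data.frame(year = rep(years, each = n_months / length(years)),
                     month = seq_len(n_months / length(years)))
  if (nrow(time) != n_months)
    time <- data.frame(year = years[1], month = seq_len(n_months))
  emissions_field(data, time, species, units)
}

.fixture_cache <- new.env(parent = emptyenv())

# Full study-scale synthetic fixture: observation record 2005-2009, land use
# projected to 2030, BAU emissions 2020-2029, sensitivities for met years
# 2005-2009, population and smoke (OC+BC) fields.
study_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  cfg <- synthetic_config(seed = 2024)
  maps <- gen_lulc_series(cfg, 2)          # 2005, 2010
  truth <- gen_fire_truth(cfg, maps, years = 2005:2009)
  S <- gen_sensitivities(cfg, 2005:2009)
  pop <- gen_population(cfg)
  labels <- transition_labels(maps[[1]], maps[[2]])
  rates <- estimate_scaling_factors(truth$emissions, maps, factor = cfg$coarsening_factor)
  fx <- list(cfg = cfg, maps = maps, truth = truth, S = S, pop = pop,
             labels = labels, rates = rates)
  .fixture_cache$fx <- fx
  fx
}

# Fine-grid OC+BC smoke field for the observation years of the fixture.
study_smoke <- function(fx = study_fixture()) {
  if (!is.null(.fixture_cache$smoke)) return(.fixture_cache$smoke)
  sp <- speciate(fx$truth$emissions, default_emission_factors(),
                 fire_type_from_labels(fx$labels))
  smoke <- add_fields(sp$OC, sp$BC)
  .fixture_cache$smoke <- smoke
  smoke
}
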