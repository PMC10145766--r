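# The niche-recovery fixture: the bundled 100 x 100 virtual-species
# landscape run through the full pipeline at reduced settings (2 PA sets x
# 3 replicates, 150-tree random forests), with contracting and expanding
# future scenarios. Computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

niche_fixture <- function() {
  if (!is.null(.fixture_cache$res)) return(.fixture_cache$res)
  landscape <- gen_landscape(demo_landscape_config(seed = 42))
  species <- demo_species_config(seed = 42)
  truth <- true_suitability(landscape, species)
  occ <- sample_occurrences(truth, species)
  cfg <- pipeline_config(
    species = "virtualis", occ = occ, stack = landscape,
    scenarios = demo_scenarios(seed = 42),
    thin_min_dist_km = 10, thin_iterations = 50,
    buffer_deg = 1.0, keep_list = "bio_10",
    n_pseudoabsence = 2000, n_pa_sets = 2, replicates = 3,
    split = 0.7, algorithms = "RF",
    hyperparameters = list(RF = list(n_trees = 150)),
    auc_gate = 0.8, add_slope = FALSE, seed = 11)
  res <- suppressMessages(run_pipeline(cfg))
  res$truth_masked <- true_suitability(res$stack, species)
  res$species <- species
  .fixture_cache$res <- res
  res
}
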