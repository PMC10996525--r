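# Shared simulated fixtures, built once per test run. The planted
# species uses the generator defaults (the study conditions) at seed 1.

.fixture_cache <- new.env(parent = emptyenv())

planted_species <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- simulation_config(seed = 1)
    sim <- simulate_species(cfg)
    repeats <- resolve_repeat_overlaps(sim$repeats)
    profiles <- flank_profiles(sim$ann, repeats, cfg$flank_len)
    .fixture_cache$sim <- list(cfg = cfg, sim = sim, repeats = repeats,
                               profiles = profiles)
  }
  .fixture_cache$sim
}

# a small, fast species for pipeline-level tests (overrides win)
small_sim_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 2L, chrom_length = 1.5e7, n_genes = 250L,
         n_families = 100L, n_te_variants = 300L, n_snvs = 300L,
         sites_per_family = 60L),
    list(...))
  do.call(simulation_config, args)
}
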