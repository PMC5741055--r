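# Shared fixtures: simulated worlds are expensive, so they are cached per
# (config hash, seed) for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small world: fast enough for unit tests, large enough for calling/stats
tiny_config <- function(seed = 1, ...) {
  args <- list(genome_size = 6e5, n_chroms = 2, n_genes = 60,
               n_truth_peaks = 150, fragments_per_replicate = 30000,
               input_depth = 15000, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

tiny_world <- function(seed = 1) {
  cached(paste0("tiny_world_", seed), simulate_world(tiny_config(seed)))
}

tiny_frags <- function(stage = "L3", rep = "rep1", seed = 1) {
  cached(paste0("tiny_frags_", stage, rep, seed),
         simulate_atac_fragments(tiny_world(seed), stage, rep,
                                 seed = derive_seed(seed,
                                                    paste(stage, rep))))
}

# default-config world (the study conditions); used by acceptance tests
default_world <- function(seed = 1) {
  cached(paste0("default_world_", seed),
         simulate_world(sim_config(seed = seed)))
}

# a minimal hand-built genome for interval/IO unit tests
toy_genome <- function() {
  genome_model(c(chrI = 10000, chrII = 8000))
}
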