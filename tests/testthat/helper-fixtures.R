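# Shared fixtures: small configurations keep the stochastic tests fast
# while exercising the same engine paths as full-length runs.

quick_cfg <- function(...) {
  simulation_config(horizon = 60, sample_interval = 5, ...)
}

# single-promoter genome with a terminator between genes 1 and 2
terminated_genome <- function(strength, n = 3) {
  add_element(make_starting_genome(n), "terminator", 1L, strength)
}

temp_path <- function(ext) tempfile(fileext = ext)

# mean final-time count of a gene over n seeded replicates
mean_final_count <- function(genome, cfg, gene, n, seed) {
  tc <- simulate_replicates(genome, cfg, n = n, seed = seed)
  as.data.frame(tc)[nrow(tc), gene]
}
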