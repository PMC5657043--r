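# Shared small fixtures: a fast simulated dataset and a light training
# configuration so cross-validation tests stay quick.

tiny_sim_config <- function(seed = 7, ...) {
  args <- list(n_chromosomes = 2, chromosome_length = 2e5, n_positives = 50,
               region_length_mean = 500, region_length_sd = 100,
               region_length_min = 200, n_histone_marks = 3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# full-architecture configuration used for the synthetic study: the
# 50-50-200 stack with shortened training (10 CD epochs, 100 BP epochs),
# which plateaus on these problem sizes well before the package defaults
cv_model_config <- function(seed = 1) {
  dbn_model_config(hidden_sizes = c(50, 50, 200),
                   rbm = rbm_config(epochs = 10),
                   bp = finetune_config(epochs = 100),
                   seed = seed)
}

fast_model_config <- function(seed = 1, hidden = c(12, 6), rbm_epochs = 10,
                              bp_epochs = 60) {
  dbn_model_config(hidden_sizes = hidden,
                   rbm = rbm_config(epochs = rbm_epochs, batch_size = 16),
                   bp = finetune_config(epochs = bp_epochs, batch_size = 16),
                   seed = seed)
}

# evaluate `code` under a seed without disturbing the suite's RNG state
with_seed_helper <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# a handful of single-interval tracks, enough to exercise column plumbing
constant_tracks <- function(n, chrom = "chr1", len = 1000, value = 1) {
  tracks <- lapply(seq_len(n), function(i) {
    signal_track(data.frame(chrom = chrom, start = 0, end = len, value = value * i))
  })
  names(tracks) <- sprintf("mark_%03d", seq_len(n))
  tracks
}
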