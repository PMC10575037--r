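# Shared fixtures: small synthetic configurations used across test files.

# a quick low-noise linear configuration for plumbing tests
tiny_synth <- function(n_trials = 3L, duration_s = 10, n_channels = 4L,
                       seed = 42L, ...) {
  synth_config(n_subjects = 1L, n_trials = n_trials, duration_s = duration_s,
               n_channels = n_channels, mixing = c(1, rep(0.3, n_channels - 1)),
               coupling = "linear", noise_sigma = 0.5,
               noise_spatial_corr = 0, artifact_rate = 0, seed = seed, ...)
}

# the desk-scale run configuration: small hidden layers, short training
tiny_run <- function(w = 64L, o = 32L, p = 12L, seed = 1L, ...) {
  run_config(window = w, overlap = o, n_components = p,
             hidden = c(32L, 16L),
             train = train_config(max_epochs = 30L, patience = 8L,
                                  batch_size = 16L),
             seed = seed, ...)
}

# read a shipped reference table, dropping printed Overall rows
read_reference <- function(name) {
  path <- system.file("extdata", name, package = "stimcorr")
  stopifnot(nzchar(path))
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
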