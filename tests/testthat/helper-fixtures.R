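# Shared fixtures: small, fast generator configurations.

# Minimal recording for connectivity-style tests: one hemisphere, one LFP
# channel, contiguous REM block.
small_config <- function(seed, coupling = 0.8, ...) {
  generator_config(
    seed = seed, coupling_strength = coupling,
    n_hemispheres = 1L, n_lfp_channels = 1L,
    hypnogram_pattern = data.frame(stage = c("N2", "R"), n = c(2L, 6L)),
    n_isolated = 0L, ...)
}

# Small mixed-stage recording exercising the full pipeline (wake for channel
# selection, NREM for thresholds, two REM periods).
mixed_config <- function(seed, coupling = 0.8, ...) {
  generator_config(
    seed = seed, coupling_strength = coupling,
    n_hemispheres = 1L, n_lfp_channels = 2L,
    hypnogram_pattern = data.frame(stage = c("W", "N2", "R", "N2", "R"),
                                   n = c(2L, 4L, 5L, 3L, 5L)),
    n_isolated = 0L, ...)
}

# Hand-built envelope_pairs object from raw envelope vectors.
make_pairs <- function(beta_list, emg_list, whiten = TRUE,
                       hemisphere = "L") {
  stopifnot(length(beta_list) == length(emg_list))
  out <- lapply(seq_along(beta_list), function(k) {
    b <- beta_list[[k]]; e <- emg_list[[k]]
    if (whiten) { b <- whiten_ar2(b); e <- whiten_ar2(e) }
    list(hemisphere = hemisphere, epoch = k - 1L, beta = b, emg = e)
  })
  structure(out, class = "envelope_pairs", env_fs = 200)
}
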