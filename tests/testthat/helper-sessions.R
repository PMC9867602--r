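# Small synthetic sessions shared across test files.

tiny_scene <- function(..., seed = 1) {
  args <- list(height = 16, width = 16, duration_s = 60,
               motifs = list(motif_spec(rate_hz = 0.2, l_frames = 20)),
               couplings = list(coupling_spec(delay_ms = 300)),
               noise_sd_widefield = 0.2, noise_sd_photometry = 0.02,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_config, args)
}
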