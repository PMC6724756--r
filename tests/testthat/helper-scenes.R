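# standard simulated scenes used across tests (small = fast)

# compact tissue: 6 well-separated nuclei, one ZIP channel with strays
small_scene_config <- function(seed = 1, n_nuclei = 6, stray_rate = 2,
                               channels = NULL) {
  if (is.null(channels))
    channels <- list(channel_spec("probeA", pi = 0.2, lambda = 5,
                                  stray_rate = stray_rate))
  simulation_config(width = 192, height = 192, n_nuclei = n_nuclei,
                    nucleus_radius_mean = 10, nucleus_radius_sd = 1,
                    min_center_spacing = 26, channels = channels,
                    seed = seed)
}

# the easy quantification regime: many nuclei, high SNR, resolvable spots
easy_scene_config <- function(seed = 1, n_nuclei = 50, channels = NULL) {
  if (is.null(channels))
    channels <- list(channel_spec("probeA", pi = 0.2, lambda = 5),
                     channel_spec("probeB", pi = 0.5, lambda = 4))
  simulation_config(width = 416, height = 416, n_nuclei = n_nuclei,
                    channels = channels, seed = seed)
}

# detect with the workflow defaults; tolerance = half the planted amplitude
detect_default <- function(img, spec) {
  detect_foci(img, tolerance = spec$amplitude / 2, sigma = 1,
              channel = spec$name)
}
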