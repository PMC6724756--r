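# shared fixture: a small two-probe scene with left/right region masks

pipeline_fixture <- function(seed = 37, dir = tempfile("scene")) {
  cfg <- simulation_config(
    width = 256, height = 256, n_nuclei = 12, nucleus_radius_mean = 12,
    nucleus_radius_sd = 1, min_center_spacing = 30,
    channels = list(channel_spec("HCN4", pi = 0.2, lambda = 6),
                    channel_spec("HCN2", pi = 0.4, lambda = 5)),
    seed = seed)
  sim <- simulate_image(cfg)
  write_fixture(sim, dir)
  # two vertical half-image regions
  left <- matrix(0, 256, 256); left[, 1:128] <- 1
  right <- matrix(0, 256, 256); right[, 129:256] <- 1
  tiff::writeTIFF(left, file.path(dir, "left.tif"), bits.per.sample = 8L,
                  compression = "none")
  tiff::writeTIFF(right, file.path(dir, "right.tif"), bits.per.sample = 8L,
                  compression = "none")
  list(sim = sim, dir = dir)
}

pipeline_config <- function(dir, out) {
  run_config(
    image = file.path(dir, "images.tif"),
    channels = c("DAPI", "HCN4", "HCN2"),
    dapi = "DAPI",
    detection = list(HCN4 = list(tolerance = 60, sigma = 1),
                     HCN2 = list(tolerance = 60, sigma = 1)),
    segmentation = list(min_area = 40),
    regions = list(left = file.path(dir, "left.tif"),
                   right = file.path(dir, "right.tif")),
    output_dir = out)
}
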