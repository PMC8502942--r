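# Shared fixture builders: all synthetic, generated at test time.

default_disc <- function(excess = 0.16, radius = 1.5) {
  tumor_disc(5, 5, radius, excess)
}

default_spec <- function(..., excess = 0.16, radius = 1.5) {
  phantom_spec(tumor_regions = default_disc(excess, radius), ...)
}

# Independent oracle for disc membership: plain double loop over pixel
# centers, no shared code with build_phantom().
brute_force_disc_count <- function(width, height, pitch, cx, cy, r) {
  nx <- ceiling(width / pitch)
  ny <- ceiling(height / pitch)
  count <- 0L
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      x <- (j - 0.5) * pitch
      y <- (i - 0.5) * pitch
      if ((x - cx)^2 + (y - cy)^2 <= r^2) count <- count + 1L
    }
  }
  count
}

# Run the standard phantom pipeline and return the report row.
run_default_pipeline <- function(seed, snr = 1e4, excess = 0.16,
                                 skin_depth = 0.05) {
  cfg <- pipeline_config(
    subject_id = paste0("s", seed),
    phantom = phantom_spec(skin_optical_depth = skin_depth,
                           tumor_regions = default_disc(excess)),
    acquisition = acquisition_config(snr = snr),
    skin = skin_fixed(skin_depth),
    rng_seed = seed
  )
  run_pipeline(cfg)$report
}
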