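# Shared fixtures, built in code at test time.

# Noise-free voxel signal for given truth under a protocol.
voxel_signal <- function(rho_w, rho_f, field_hz, r2star, protocol) {
  wf_signal_model(rho_w, rho_f, field_hz, r2star, protocol$echo_times,
                  protocol$fat_shift_hz)[1, ]
}

# Small phantom with constant PDFF, optionally R2* = 0 and flat field.
flat_phantom <- function(pdff, seed, shape = c(48L, 48L), r2 = c(0, 0),
                         field = c(0)) {
  simulate_parameter_maps(shape, list(kind = "point", value = pdff),
                          r2star_range = r2, field_poly = field,
                          seed = seed)
}

# The swap-study phantom: voxelwise-uniform PDFF, constant background
# field 2 Hz past flat, low channel noise; a rectangle covering ~25% of
# the mask (by area, rightmost columns) gets the half-fat-shift offset.
swap_phantom <- function(seed, shape = c(64L, 64L), noise_sd = 2e-4) {
  maps <- simulate_parameter_maps(
    shape, list(kind = "uniform", min = 0.1, max = 0.3),
    r2star_range = c(0, 0), field_poly = c(2), seed = seed)
  cols <- which(colSums(maps$mask) > 0)
  cut <- as.integer(stats::quantile(
    rep(cols, colSums(maps$mask)[cols]), 0.75))
  region <- c(1L, shape[1], cut, max(cols))
  maps2 <- inject_swap_region(maps, region, fat_shift_hz = 217)
  img <- simulate_multiecho(maps2, gre_protocol(noise_sd = noise_sd),
                            seed = seed + 10000L)
  list(maps = maps, region = region, image = img)
}

roi_overlaps <- function(roi, region) {
  roi[1] <= region[2] && roi[2] >= region[1] &&
    roi[3] <= region[4] && roi[4] >= region[3]
}
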