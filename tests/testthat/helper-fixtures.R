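# Small in-code fixtures shared across test files.

# Digitized sphere mask: voxel centers within radius_mm of the grid's
# physical midpoint.
sphere_mask <- function(radius_mm, spacing = c(1, 1, 1), pad_mm = 2,
                        lesion_id = "sphere") {
  extent <- 2 * (radius_mm + pad_mm)
  shape <- pmax(3L, ceiling(extent / spacing) + 1L)
  g <- image_grid(shape, spacing)
  ctr <- g$origin + (g$shape - 1) * g$spacing / 2
  vox <- qeasl3d:::distance2_field(g, ctr) <= radius_mm^2
  segmentation_mask(vox, g, lesion_id)
}

# Uniform-intensity volume pair on a shared grid.
flat_phases <- function(grid, unenh = 100, art = 150) {
  list(unenhanced = volume_image(array(unenh, dim = grid$shape), grid, "unenhanced_T1"),
       arterial = volume_image(array(art, dim = grid$shape), grid, "arterial_T1"))
}

# A small noise-free phantom spec for fast end-to-end checks.
quick_phantom_spec <- function(fraction = 0.4, noise_sd = 0, seed = 1L,
                               radius_mm = 12, shape = c(48L, 48L, 40L)) {
  phantom_spec(shape = shape,
               lesions = data.frame(lesion_id = "L1", cx = shape[1] / 2,
                                    cy = shape[2] / 2, cz = shape[3] / 2,
                                    radius_mm = radius_mm,
                                    enhancing_fraction = fraction),
               noise_sd = noise_sd, seed = seed)
}

# Survival records from bare vectors.
recs <- function(time, event, group = NULL) {
  survival_records(seq_along(time), time, event, group)
}
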