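# Small-scale fixtures built in code. The reduced geometries keep unit-test
# grids small; the full protocol geometry is exercised in the acceptance
# tests.

small_uniform <- function() {
  geom <- phantom_geometry("uniform_cylinder", cylinder_height = 60,
                           cylinder_diameter = 60,
                           fill_volume_ml = pi * 30^2 * 60 / 1000)
  spec <- activity_spec(50, fill_volume_ml = geom$fill_volume_ml)
  list(geom = geom, spec = spec)
}

small_revolver <- function(size = 2.5, radionuclide = "tc99m") {
  geom <- phantom_geometry("revolver_body", syringe_volume_ml = size,
                           body_axes = c(55, 45), body_length = 70)
  prof <- radionuclide_profile(radionuclide)
  spec <- revolver_activity_spec(geom, prof$background_activity_MBq)
  list(geom = geom, spec = spec)
}

small_run_config <- function(out_dir, seed = 1L, radionuclide = "tc99m") {
  run_config(radionuclide, out_dir = out_dir, seed = seed, n_repeats = 2L,
             insert_sizes = 2.5,
             voi = list(d_min = 10, d_max = 46, step = 4),
             uniform = list(height = 60, diameter = 60,
                            fill_volume_ml = pi * 30^2 * 60 / 1000,
                            activity_MBq = 50),
             body = list(axes = c(55, 45), length = 70,
                         background_activity_MBq = NULL),
             background_region = list(center = c(35, 0, 0), radius = 8))
}

# Constant-value cuboid image + full mask on a tiny grid.
tiny_image <- function(vals, spacing = 1) {
  voxel_image(vals, spacing, unit = "SUV")
}
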