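# Shared fixtures, built in code. The desk instrument (512-pixel detector)
# is used where PSF physics matters; the small instrument (256 pixels)
# keeps multi-frame tests fast.

desk_source <- make_source_spectrum(840, 50, 512)
desk_grid <- resample_to_k(desk_source)
desk_background <- simulate_ascan_spectrum(
  desk_source, desk_grid, layered_sample(numeric(0), numeric(0)))

# Noise-free fringe of a single specular layer, with the full DC (reference
# + autocorrelation) removed so only the interference term remains.
single_layer_fringe <- function(delta_z_um, reflectivity = 1, a2 = 0,
                                a3 = 0, source = desk_source,
                                grid = desk_grid) {
  s <- simulate_ascan_spectrum(source, grid,
                               layered_sample(delta_z_um, reflectivity,
                                              a2 = a2, a3 = a3))
  bg <- if (identical(grid, desk_grid)) desk_background else
    simulate_ascan_spectrum(source, grid,
                            layered_sample(numeric(0), numeric(0)))
  s - (1 + sum(reflectivity)) * bg
}

# A two-A-line raw frame around an already background-free fringe vector
# (flagged so the reconstruction chain does not subtract again).
frame_from_fringe <- function(fringe, source = desk_source,
                              grid = desk_grid) {
  fr <- octadc:::new_raw_frame(cbind(fringe, fringe), source, grid)
  fr$background_subtracted <- TRUE
  fr
}

# Small benchmark datasets are expensive; build lazily and cache per session.
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

tiny_volumes <- function() cached("tiny_volumes",
  simulate_benchmark(n_volumes = 2, locations = 2, a_lines = 48,
                     repeats = 2, n_pixels = 256, seed = 404))

tiny_dataset <- function() cached("tiny_dataset",
  build_dataset(tiny_volumes(), n_channels = 5, pool_depth = 4,
                pool_lateral = 1))   # pairs are 32 x 48
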