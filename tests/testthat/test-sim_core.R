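# Source model, wavenumber grid and interferogram synthesis.

test_that("source spectrum is a peak-normalized Gaussian with the right FWHM", {
  src <- make_source_spectrum(840, 50, 2048)
  expect_length(src$wavelengths_nm, 2048)
  expect_true(all(diff(src$wavelengths_nm) > 0))
  expect_equal(max(src$intensity_au), 1)
  expect_equal(src$wavelengths_nm[which.max(src$intensity_au)], 840,
               tolerance = 1e-3)
  for (lam in c(815, 865)) {
    at <- which.min(abs(src$wavelengths_nm - lam))
    expect_equal(src$intensity_au[at], 0.5, tolerance = 0.01)
  }
  expect_length(make_source_spectrum(840, 50, 16)$intensity_au, 16)
  expect_error(make_source_spectrum(840, 0, 512), "positive")
  expect_error(make_source_spectrum(840, 50, 8), ">= 16")
})

test_that("k grid is uniform, spans 2*pi/lambda, and centers on the centroid", {
  src <- make_source_spectrum(840, 50, 1024)
  grid <- resample_to_k(src)
  k <- grid$k_values
  expect_length(k, 1024)
  expect_equal(min(k), 2 * pi / (max(src$wavelengths_nm) / 1000))
  expect_equal(max(k), 2 * pi / (min(src$wavelengths_nm) / 1000))
  expect_lt(diff(range(diff(k))) / mean(diff(k)), 1e-9)
  # independent centroid oracle on the k-resampled envelope
  intens <- octadc:::source_intensity_on_k(src, k)
  k0_oracle <- sum(k * intens) / sum(intens)
  expect_equal(grid$k0, k0_oracle)
  expect_true(grid$k0 > min(k) && grid$k0 < max(k))
  expect_identical(resample_to_k(src), grid)
})

test_that("single-layer fringe oscillates at the pathlength frequency", {
  fr <- single_layer_fringe(200, 1)
  # consecutive maxima of cos(k * dz) are separated by 2*pi/dz in k
  pk <- which(diff(sign(diff(fr))) == -2) + 1
  spacing <- mean(diff(desk_grid$k_values[pk]))
  expect_equal(spacing, 2 * pi / 200, tolerance = 0.01)
})

test_that("zero reflectivity gives exactly the DC background", {
  empty <- layered_sample(numeric(0), numeric(0))
  dark <- layered_sample(c(100, 250), c(0, 0))
  expect_equal(simulate_ascan_spectrum(desk_source, desk_grid, dark),
               desk_background)
})

test_that("multilayer fringes superpose from single-layer fringes", {
  zs <- c(150, 300); rs <- c(0.8, 0.4); a2s <- c(-20, 25)
  multi <- simulate_ascan_spectrum(
    desk_source, desk_grid, layered_sample(zs, rs, a2 = a2s))
  singles <- lapply(1:2, function(i)
    simulate_ascan_spectrum(desk_source, desk_grid,
                            layered_sample(zs[i], rs[i], a2 = a2s[i])))
  lhs <- multi - desk_background
  rhs <- (singles[[1]] - desk_background) + (singles[[2]] - desk_background)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-10)
})

test_that("pure phase distortion leaves the interference energy invariant", {
  # the analytic (complex) AC energy is exactly phase-invariant; building
  # it from the real fringe by the Hilbert construction leaks ~1e-7 of the
  # conjugate peak, which bounds the achievable agreement here
  base <- single_layer_fringe(250, 0.7)
  e0 <- sum(Mod(octadc:::analytic_fringe(matrix(base, ncol = 1)))^2)
  for (a2 in c(-35, 12, 40)) {
    f <- single_layer_fringe(250, 0.7, a2 = a2)
    e <- sum(Mod(octadc:::analytic_fringe(matrix(f, ncol = 1)))^2)
    expect_lt(abs(e - e0) / e0, 1e-6)
  }
})

test_that("deep layers trigger an aliasing warning but still simulate", {
  z_bad <- octadc:::max_depth_um(desk_grid) + 50
  expect_warning(
    fr <- simulate_ascan_spectrum(desk_source, desk_grid,
                                  layered_sample(z_bad, 0.5)),
    "unambiguous depth")
  expect_true(all(is.finite(fr)))
})

test_that("volume simulation is deterministic and groups repeats correctly", {
  samp <- synth_retina_sample(400, seed = 9)
  v1 <- simulate_volume(samp, n_bscans = 4, a_lines_per_bscan = 16,
                        repeats = 4, rng_seed = 7,
                        source = make_source_spectrum(n_pixels = 256))
  expect_length(v1$frames, 16)
  expect_equal(vapply(v1$frames, `[[`, integer(1), "location_index"),
               rep(1:4, each = 4))
  v2 <- simulate_volume(samp, n_bscans = 4, a_lines_per_bscan = 16,
                        repeats = 4, rng_seed = 7,
                        source = make_source_spectrum(n_pixels = 256))
  expect_identical(lapply(v1$frames, `[[`, "fringes"),
                   lapply(v2$frames, `[[`, "fringes"))
  # noise-free repeats are identical; noisy repeats share geometry only
  v0 <- simulate_volume(samp, n_bscans = 1, a_lines_per_bscan = 16,
                        repeats = 4, noise = NULL, rng_seed = 7,
                        source = make_source_spectrum(n_pixels = 256))
  expect_identical(v0$frames[[1]]$fringes, v0$frames[[4]]$fringes)
  expect_false(identical(v1$frames[[1]]$fringes, v1$frames[[2]]$fringes))
})

test_that("speckle geometry is shared across repeats, noise is not", {
  samp <- synth_retina_sample(400, speckle_density = 6, seed = 2)
  v <- simulate_volume(samp, n_bscans = 1, a_lines_per_bscan = 8,
                       repeats = 2, noise = noise_model(0.05), rng_seed = 5,
                       source = make_source_spectrum(n_pixels = 256))
  d <- v$frames[[1]]$fringes - v$frames[[2]]$fringes
  # difference is pure iid noise: small and structureless
  expect_lt(max(abs(d)), 0.05 * 6)
  expect_equal(sd(as.vector(d)), 0.05 * sqrt(2), tolerance = 0.1)
})

test_that("wavelength-sampled fringes k-linearize onto the uniform grid", {
  src <- desk_source; grid <- desk_grid
  # fringe evaluated on the native (lambda-uniform) k samples
  k_native <- rev(2 * pi / (src$wavelengths_nm / 1000))
  fr_lambda <- rev(cos(200 * k_native) *
                     octadc:::source_intensity_on_k(src, k_native))
  fr_k <- linearize_fringe(fr_lambda, src, grid)
  truth <- cos(200 * grid$k_values) *
    octadc:::source_intensity_on_k(src, grid$k_values)
  expect_lt(max(abs(fr_k - truth)), 0.02)
  a <- reconstruct_ascan(fr_k, grid)
  expect_equal(which.max(a), round(200 / depth_pitch_um(grid)), tolerance = 1)
})
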