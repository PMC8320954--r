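test_that("absorbance follows the optical density definition", {
  expect_equal(absorbance(c(1, 0.1, 0.01)), c(0, 1, 2))
  expect_true(is.na(absorbance(0)))
  expect_true(is.na(absorbance(-0.2)))
  cube <- sfaox:::new_spectral_cube(array(0.1, c(2, 2, 3)), 1:3,
                                    "reflectance")
  expect_true(all(unclass(absorbance(cube)) == 1))
  cube[, , 2] <- 0
  expect_error(absorbance(cube), "fully masked")
})

test_that("zero absorbance change inverts to zero concentration change", {
  dc <- delta_concentrations(c(0, 0, 0))
  expect_equal(unname(dc), c(0, 0))
})

test_that("forward-generated absorbance changes invert exactly", {
  lib <- chromophore_library()
  wl <- c(515, 565, 601)
  dpf <- c(1.2, 1.1, 1.3)
  d <- 0.8
  true_dc <- c(0.005, -0.005)
  E <- extinction_at(lib, wl) * dpf
  dA <- as.numeric(E %*% true_dc) * d
  dc <- delta_concentrations(dA, lib, wl, dpf = dpf, d = d)
  expect_lt(max(abs(dc - true_dc)) / max(abs(true_dc)), 1e-9)
  # halving with doubled path length
  dc2 <- delta_concentrations(dA, lib, wl, dpf = dpf, d = 2 * d)
  expect_equal(unname(dc2), unname(dc) / 2, tolerance = 1e-12)
})

test_that("nearly collinear wavelengths trigger a condition warning", {
  expect_warning(delta_concentrations(c(0.01, 0.011),
                                      wavelengths = c(564.999, 565.001)),
                 "collinear")
})

test_that("key wavelengths resolve to the nearest virtual band", {
  centers <- default_band_centers(10)
  res <- resolve_bands(centers, c(515, 565, 601))
  expect_equal(res$index, c(4, 6, 8))
  expect_true(all(abs(res$center - c(515, 565, 601)) <=
                    mean(diff(centers)) / 2))
  expect_error(resolve_bands(centers, 450), "half a band spacing")
})

test_that("a constant scene yields zero concentration changes", {
  lib <- chromophore_library()
  centers <- default_band_centers(10)
  conc <- matrix(c(0.07, 0.03), 2, 12)
  cubes <- forward_cube_series(conc, centers, lib)
  res <- estimate_oxy_timeseries(cubes, lib, delta_t_config(roi = c(2, 2, 1)))
  expect_equal(res$curve$d_O2Hb_mM, rep(0, 12), tolerance = 1e-12)
  expect_equal(res$curve$d_HHb_mM, rep(0, 12), tolerance = 1e-12)
})

test_that("matched forward and inverse models recover changes exactly", {
  lib <- chromophore_library()
  centers <- default_band_centers(10)
  truth <- simulate_occlusion_truth(quiet_protocol())
  conc <- rbind(truth$c_O2Hb_mM, truth$c_HHb_mM)
  cubes <- forward_cube_series(conc, centers, lib, d = 1)
  res <- estimate_oxy_timeseries(cubes, lib,
                                 delta_t_config(baseline_frames = 5))
  base <- colMeans(truth[1:5, c("c_O2Hb_mM", "c_HHb_mM")])
  expect_lt(max(abs(res$curve$d_O2Hb_mM - (truth$c_O2Hb_mM - base[1]))),
            1e-8)
  expect_lt(max(abs(res$curve$d_HHb_mM - (truth$c_HHb_mM - base[2]))),
            1e-8)
})

test_that("time-constant per-band losses cancel in the difference", {
  lib <- chromophore_library()
  centers <- default_band_centers(10)
  truth <- simulate_occlusion_truth(quiet_protocol())
  conc <- rbind(truth$c_O2Hb_mM, truth$c_HHb_mM)
  cubes <- forward_cube_series(conc, centers, lib)
  set.seed(4)
  G <- runif(10, 0, 0.3)
  cubes_g <- lapply(cubes, function(cu) sfaox:::new_spectral_cube(
    unclass(cu) * rep(10^(-G), each = 16), centers, "reflectance"))
  a <- estimate_oxy_timeseries(cubes, lib)$curve
  b <- estimate_oxy_timeseries(cubes_g, lib)$curve
  expect_equal(a$d_O2Hb_mM, b$d_O2Hb_mM, tolerance = 1e-10)
  expect_equal(a$d_HHb_mM, b$d_HHb_mM, tolerance = 1e-10)
})

test_that("three-band and all-band modes agree on consistent signal", {
  lib <- chromophore_library()
  centers <- default_band_centers(10)
  truth <- simulate_occlusion_truth(quiet_protocol())
  conc <- rbind(truth$c_O2Hb_mM, truth$c_HHb_mM)
  cubes <- forward_cube_series(conc, centers, lib)
  three <- estimate_oxy_timeseries(cubes, lib,
                                   delta_t_config(mode = "three"))$curve
  all_b <- estimate_oxy_timeseries(cubes, lib,
                                   delta_t_config(mode = "all"))$curve
  expect_equal(three$d_O2Hb_mM, all_b$d_O2Hb_mM, tolerance = 1e-9)
  expect_equal(three$proxy, all_b$proxy, tolerance = 1e-9)
})

test_that("band-specific noise favours the mode that avoids it", {
  lib <- chromophore_library()
  centers <- default_band_centers(10)
  truth <- simulate_occlusion_truth(quiet_protocol())
  conc <- rbind(truth$c_O2Hb_mM, truth$c_HHb_mM)
  cubes <- forward_cube_series(conc, centers, lib)
  key_idx <- resolve_bands(centers, c(515, 565, 601))$index
  perturb <- function(bands, sd) {
    set.seed(8)
    lapply(cubes, function(cu) {
      v <- unclass(cu)
      for (b in bands) v[, , b] <- v[, , b] * 10^(-rnorm(16, 0, sd))
      sfaox:::new_spectral_cube(v, centers, "reflectance")
    })
  }
  err <- function(cubes, mode) {
    cv <- estimate_oxy_timeseries(cubes, lib,
                                  delta_t_config(mode = mode))$curve
    base <- mean(truth$c_O2Hb_mM[1:5])
    sqrt(mean((cv$d_O2Hb_mM - (truth$c_O2Hb_mM - base))^2))
  }
  # noise on the key bands: averaging over all bands is more robust
  noisy_key <- perturb(key_idx, 0.02)
  expect_lt(err(noisy_key, "all"), err(noisy_key, "three"))
  # noise only outside the key bands: the three-band mode is untouched
  # while the all-band estimate degrades (extra bands noise-dominated)
  noisy_rest <- perturb(setdiff(1:10, key_idx), 0.02)
  expect_lt(err(noisy_rest, "three"), err(noisy_rest, "all"))
})

test_that("a radius-zero ROI reproduces the single pixel's trace", {
  lib <- chromophore_library()
  centers <- default_band_centers(10)
  set.seed(6)
  cubes <- lapply(1:8, function(i) sfaox:::new_spectral_cube(
    array(runif(4 * 4 * 10, 0.2, 0.8), c(4, 4, 10)), centers,
    "reflectance"))
  res0 <- estimate_oxy_timeseries(cubes, lib,
                                  delta_t_config(roi = c(2, 3, 0),
                                                 baseline_frames = 2))
  # oracle: extract the pixel by hand and run the vector inversion
  wl <- resolve_bands(centers, c(515, 565, 601))
  pix <- sapply(cubes, function(cu) -log10(cu[2, 3, wl$index]))
  dA <- pix - rowMeans(pix[, 1:2])
  dc <- delta_concentrations(dA, lib, wl$center)
  expect_equal(res0$curve$d_O2Hb_mM, unname(dc["O2Hb", ]),
               tolerance = 1e-10)
})

test_that("per-pixel concentration maps match the ROI machinery", {
  lib <- chromophore_library()
  centers <- default_band_centers(10)
  truth <- simulate_occlusion_truth(quiet_protocol())
  conc <- rbind(truth$c_O2Hb_mM, truth$c_HHb_mM)
  cubes <- forward_cube_series(conc, centers, lib)
  res <- estimate_oxy_timeseries(cubes, lib, delta_t_config(),
                                 map_frames = c(30, 61))
  expect_named(res$maps, c("30", "61"))
  m61 <- res$maps[["61"]]
  expect_equal(dim(m61), c(4, 4, 2))
  # uniform scene: every pixel equals the ROI curve value
  expect_equal(as.numeric(m61[, , 1]),
               rep(res$curve$d_O2Hb_mM[61], 16), tolerance = 1e-9)
})

test_that("estimator validates frames and ROI", {
  lib <- chromophore_library()
  centers <- default_band_centers(10)
  cubes <- forward_cube_series(matrix(c(0.07, 0.03), 2, 8), centers, lib)
  expect_error(estimate_oxy_timeseries(cubes[1:4], lib,
                                       delta_t_config(baseline_frames = 5)),
               "baseline_frames")
  expect_error(estimate_oxy_timeseries(cubes, lib,
                                       delta_t_config(roi = c(50, 50, 1),
                                                      baseline_frames = 2)),
               "outside")
})
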