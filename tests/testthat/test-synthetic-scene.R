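test_that("protocol validation rejects out-of-range fields", {
  expect_error(occlusion_protocol(release_threshold_fraction = 0), "range")
  expect_error(occlusion_protocol(release_threshold_fraction = 1), "range")
  expect_error(occlusion_protocol(baseline_duration = -5), "range")
  expect_error(occlusion_protocol(frame_rate = 0), "range")
  expect_error(occlusion_protocol(noise_sd = NA), "finite")
  expect_error(occlusion_protocol(occlusion_duration = 1), "two frames")
})

test_that("desaturation rate and occlusion duration are consistent", {
  p <- occlusion_protocol(occlusion_duration = 120,
                          release_threshold_fraction = 0.4)
  expect_equal(p$desaturation_rate, 0.6 / 120)
  p2 <- occlusion_protocol(desaturation_rate = 0.005,
                           release_threshold_fraction = 0.4)
  expect_equal(p2$occlusion_duration, 120)
})

test_that("release sample carries exactly the threshold saturation", {
  # including durations that do not fall on the frame grid
  for (occ in c(40, 97.3, 61.4)) {
    p <- quiet_protocol(occlusion_duration = occ,
                        release_threshold_fraction = 0.4)
    truth <- simulate_occlusion_truth(p)
    i_rel <- attr(truth, "release_index")
    expect_identical(truth$event[i_rel], "cuff_release")
    expect_equal(truth$StO2_frac[i_rel], 0.4 * p$baseline_sto2)
    expect_equal(min(truth$StO2_frac), 0.4 * p$baseline_sto2)
    expect_equal(which.min(truth$StO2_frac), i_rel)
  }
})

test_that("saturation strictly decreases during noise-free occlusion", {
  truth <- simulate_occlusion_truth(quiet_protocol())
  i0 <- attr(truth, "occlusion_index")
  i1 <- attr(truth, "release_index")
  expect_true(all(diff(truth$StO2_frac[i0:i1]) < 0))
})

test_that("total hemoglobin is conserved even under noise", {
  truth <- simulate_occlusion_truth(
    occlusion_protocol(noise_sd = 0.02), seed = 7)
  tot <- truth$c_O2Hb_mM + truth$c_HHb_mM
  expect_equal(tot, rep(0.1, nrow(truth)), tolerance = 1e-12)
})

test_that("optional blood-volume drift breaks conservation as configured", {
  truth <- simulate_occlusion_truth(
    quiet_protocol(blood_volume_drift = 0.001))
  tot <- truth$c_O2Hb_mM + truth$c_HHb_mM
  expect_gt(max(tot) - min(tot), 0.001)
})

test_that("identical seeds give identical trajectories", {
  p <- occlusion_protocol(noise_sd = 0.01)
  a <- simulate_occlusion_truth(p, seed = 3)
  b <- simulate_occlusion_truth(p, seed = 3)
  expect_identical(a, b)
  c <- simulate_occlusion_truth(p, seed = 4)
  expect_false(identical(a$StO2_frac, c$StO2_frac))
})

test_that("zero concentrations and zero losses give unit reflectance", {
  truth <- simulate_occlusion_truth(quiet_protocol())
  truth$c_O2Hb_mM[] <- 0
  truth$c_HHb_mM[] <- 0
  params <- skin_forward_params(G = 0, melanin = 0)
  refl <- reflectance_from_concentrations(truth, params)
  expect_true(all(refl$R == 1))
})

test_that("absorbance is linear in the path length d", {
  truth <- simulate_occlusion_truth(quiet_protocol())
  r1 <- reflectance_from_concentrations(truth, skin_forward_params(d = 0.2))
  r2 <- reflectance_from_concentrations(truth, skin_forward_params(d = 0.4))
  expect_equal(-log10(r2$R), 2 * -log10(r1$R), tolerance = 1e-12)
})

test_that("log-ratio of reflectance matches the extinction model exactly", {
  # direct evaluation of the modified Beer-Lambert law as the oracle
  grid <- default_grid
  lib <- chromophore_library(grid = grid)
  params <- skin_forward_params(grid, lib, dpf = 1.5, d = 0.3,
                                G = 0.1, melanin = 0.05)
  conc <- data.frame(time_s = 0:1,
                     c_O2Hb_mM = c(0.07, 0.065),
                     c_HHb_mM = c(0.03, 0.035))
  refl <- reflectance_from_concentrations(conc, params)
  dc <- c(-0.005, 0.005)
  eps <- extinction_at(lib, grid)
  expected <- as.numeric(eps %*% dc) * 1.5 * 0.3
  expect_equal(-log10(refl$R[, 2] / refl$R[, 1]), expected,
               tolerance = 1e-12)
})

test_that("negative concentrations are rejected and R > 1 is clamped", {
  truth <- simulate_occlusion_truth(quiet_protocol())
  truth$c_O2Hb_mM[3] <- -0.01
  expect_error(reflectance_from_concentrations(truth), "non-negative")
  truth2 <- simulate_occlusion_truth(quiet_protocol())
  params <- skin_forward_params(G = -1)   # negative loss pushes R above 1
  expect_warning(r <- reflectance_from_concentrations(truth2, params),
                 "clamped")
  expect_true(all(r$R <= 1))
  expect_gt(r$n_clamped, 0)
})

test_that("reference oximeter resamples the truth as specified", {
  p <- occlusion_protocol(baseline_duration = 60, occlusion_duration = 170,
                          recovery_duration = 120, noise_sd = 0)
  truth <- simulate_occlusion_truth(p)       # 350 samples at 1 Hz
  expect_equal(nrow(truth), 350)
  ref <- simulate_reference_oximeter(truth, sample_period = 3.5,
                                     noise_sd = 0)
  expect_true(abs(nrow(ref) - 100) <= 1)
  # identity resampling at the frame period
  ref1 <- simulate_reference_oximeter(truth, sample_period = 1,
                                      noise_sd = 0)
  expect_equal(ref1$StO2_frac, truth$StO2_frac)
  # determinism and validation
  a <- simulate_reference_oximeter(truth, noise_sd = 0.01, seed = 5)
  b <- simulate_reference_oximeter(truth, noise_sd = 0.01, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_reference_oximeter(truth, sample_period = 0))
  expect_error(simulate_reference_oximeter(truth, sample_period = 0.5),
               "frame period")
})

test_that("forward model round-trips through the concentration inversion", {
  grid <- default_grid
  lib <- chromophore_library(grid = grid)
  params <- skin_forward_params(grid, lib, d = 0.25, G = 0.05)
  truth <- simulate_occlusion_truth(quiet_protocol())
  refl <- reflectance_from_concentrations(truth, params)
  wl <- c(520, 560, 600)
  idx <- match(wl, grid)
  A <- -log10(refl$R[idx, ])
  dA <- A - A[, 1]
  dc <- delta_concentrations(dA, lib, wl, d = 0.25)
  true_dc <- rbind(truth$c_O2Hb_mM - truth$c_O2Hb_mM[1],
                   truth$c_HHb_mM - truth$c_HHb_mM[1])
  scale <- max(abs(true_dc))
  expect_lt(max(abs(dc - true_dc)) / scale, 1e-9)
})

test_that("packaged extinction library has the required band structure", {
  lib <- chromophore_library()
  e <- extinction_at(lib, c(515, 565, 601))
  expect_true(all(e >= 0))
  # near-isosbestic reference at 515 nm, strong contrast at 565 and 601 nm
  expect_lt(abs(e[1, "O2Hb"] - e[1, "HHb"]),
            abs(e[2, "O2Hb"] - e[2, "HHb"]))
  expect_gt(abs(e[3, "O2Hb"] - e[3, "HHb"]), 1)
})
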