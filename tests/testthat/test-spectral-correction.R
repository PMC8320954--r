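test_that("ideal narrow-band channels are corrected exactly", {
  # channels = delta filters at the virtual centers, training spectra in
  # the span of the basis: the fitted map must return the sampled
  # reflectance to numerical precision
  grid <- default_grid
  centers <- seq(470, 650, by = 20)               # 10 on-grid centers
  B <- sfaox:::make_basis("bspline", grid, centers)(grid)
  set.seed(2)
  W <- matrix(runif(24 * 10), 24, 10)
  train <- W %*% t(B)                             # 24 x grid, span(B)
  resp <- train[, match(centers, grid)]           # delta-channel responses
  model <- fit_correction(resp, train, grid, centers = centers,
                          ridge = 1e-12)
  expect_lt(max(model$training_rmse), 1e-9)
  expect_equal(correct_responses(model, resp), resp, tolerance = 1e-7)
})

test_that("the default model reduces 16 channels to 10 virtual bands", {
  bank <- build_filter_bank()
  model <- calibrate_correction(bank, seed = 1)
  cube16 <- sfaox:::new_spectral_cube(array(runif(4 * 4 * 16), c(4, 4, 16)),
                                      bank$peaks, "raw-response")
  out <- apply_correction(model, cube16)
  expect_equal(dim(out)[3], 10)
  expect_equal(attr(out, "kind"), "reflectance")
  expect_equal(band_centers(out), model$centers)
  bad <- sfaox:::new_spectral_cube(array(0, c(4, 4, 9)), 1:9, "raw-response")
  expect_error(apply_correction(model, bad), "bands")
})

test_that("correction is linear and matches the per-pixel oracle", {
  bank <- build_filter_bank()
  model <- calibrate_correction(bank, seed = 1)
  set.seed(3)
  mk <- function() sfaox:::new_spectral_cube(
    array(runif(4 * 4 * 16), c(4, 4, 16)), bank$peaks, "raw-response")
  c1 <- mk(); c2 <- mk()
  lin <- apply_correction(model, sfaox:::new_spectral_cube(
    2 * unclass(c1) + 3 * unclass(c2), bank$peaks, "raw-response"))
  expect_equal(unclass(lin),
               2 * unclass(apply_correction(model, c1)) +
                 3 * unclass(apply_correction(model, c2)),
               tolerance = 1e-10)
  # all-zero cube maps to zero
  z <- sfaox:::new_spectral_cube(array(0, c(4, 4, 16)), bank$peaks,
                                 "raw-response")
  expect_true(all(unclass(apply_correction(model, z)) == 0))
  # loop-over-pixels oracle
  out <- apply_correction(model, c1)
  for (i in 1:4) for (j in 1:4)
    expect_equal(out[i, j, ],
                 as.numeric(model$M_eff %*% c1[i, j, ]),
                 tolerance = 1e-12)
})

test_that("duplicating every training patch leaves the model unchanged", {
  bank <- build_filter_bank()
  train <- synthetic_training_patches(24, bank$grid, seed = 1)
  resp <- channel_responses(bank, train)
  m1 <- fit_correction(resp, train, bank$grid, bank = bank)
  m2 <- fit_correction(rbind(resp, resp), rbind(train, train), bank$grid,
                       bank = bank)
  expect_equal(m1$M, m2$M, tolerance = 1e-8)
})

test_that("rank-deficient training sets are rejected with advice", {
  bank <- build_filter_bank()
  greys <- synthetic_training_patches(12, bank$grid, seed = 1, n_grey = 12)
  resp <- channel_responses(bank, greys)
  expect_error(fit_correction(resp, greys, bank$grid),
               "rank deficient")
})

test_that("correction beats the uncorrected peak readout on held-out patches", {
  bank <- build_filter_bank(second_order_height = 0.3)
  model <- calibrate_correction(bank, seed = 1)
  held <- synthetic_training_patches(24, bank$grid, seed = 99)
  resp <- channel_responses(bank, held)
  corrected <- correct_responses(model, resp)
  at <- function(wl) t(apply(held, 1, function(r)
    stats::approx(bank$grid, r, xout = wl)$y))
  rmse_corr <- sqrt(rowMeans((corrected - at(model$centers))^2))
  rmse_unc <- sqrt(rowMeans((resp - at(bank$peaks))^2))
  expect_lt(mean(rmse_corr), mean(rmse_unc))
})

test_that("corrected sensitivities are more localized than raw channels", {
  bank <- build_filter_bank(second_order_height = 0.3)
  model <- calibrate_correction(bank, seed = 1)
  es <- effective_sensitivities(model, bank)
  expect_lt(mean(es$oob_corrected), mean(es$oob_raw))
  # identity model reproduces the raw bank; zero matrix gives zero rows
  id <- identity_correction(bank$peaks)
  expect_equal(effective_sensitivities(id, bank)$S, bank$Q)
  zero <- id; zero$M_eff <- 0 * zero$M_eff
  expect_true(all(effective_sensitivities(zero, bank)$S == 0))
})

test_that("joint fit is at least as good as the two-step oracle", {
  # brute-force oracle: project spectra on the basis, then regress the
  # weights on the responses; the joint normal equations cannot do worse
  bank <- build_filter_bank()
  train <- synthetic_training_patches(24, bank$grid, seed = 1)
  resp <- channel_responses(bank, train)
  model <- fit_correction(resp, train, bank$grid, ridge = 1e-10)
  B <- model$B
  Rm <- t(train); P <- t(resp)
  W <- solve(crossprod(B) + 1e-12 * diag(10), crossprod(B, Rm))
  M2 <- W %*% t(P) %*% solve(tcrossprod(P) + 1e-10 * mean(diag(tcrossprod(P))) * diag(16))
  sse <- function(M) sum((B %*% M %*% P - Rm)^2)
  expect_lte(sse(model$M), sse(M2) + 1e-8)
})

test_that("a flat 50% reflector reads 0.5 in every virtual band", {
  bank <- build_filter_bank()
  layout <- mosaic_layout(bank$peaks)
  model <- calibrate_correction(bank, seed = 1)
  refs <- render_references(bank, layout, height = 8, width = 8,
                            noise_sd = 0, quantize = FALSE)
  f <- render_frame(rep(0.5, length(bank$grid)), bank, layout,
                    height = 8, width = 8, noise_sd = 0, quantize = FALSE)
  cube <- apply_correction(model, demosaic_subsample(
    flat_field_correct(f, refs$dark, refs$white), layout))
  expect_equal(as.numeric(unclass(cube)),
               rep(0.5, length(cube)), tolerance = 1e-3)
})

test_that("correction models serialize to JSON and back", {
  bank <- build_filter_bank()
  model <- calibrate_correction(bank, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_correction_model(model, path)
  back <- read_correction_model(path)
  expect_equal(back$M_eff, model$M_eff, ignore_attr = TRUE)
  expect_equal(back$centers, model$centers)
  p <- runif(16)
  expect_equal(correct_responses(back, p), correct_responses(model, p),
               tolerance = 1e-12)
})
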