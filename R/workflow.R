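#' Pipeline configuration
#'
#' Bundles every knob of the simulated camera, the occlusion protocol, the
#' skin forward model, the spectral-correction fit and the oxygenation
#' estimator. Partial lists are merged into the defaults.
#'
#' @param protocol an [occlusion_protocol()].
#' @param oxy a [delta_t_config()].
#' @param camera list: `height`, `width` (multiples of 4), `exposure_ms`,
#'   `gain`, `bit_depth`, `dark_level`, `noise_sd`, and filter-bank
#'   parameters `fwhm`, `second_order_height`, `second_order_offset`,
#'   `crosstalk_strength`, `bandpass`.
#' @param forward skin forward-model list: `d` (cm), `dpf`, `melanin`, `G`.
#' @param correction list: `m`, `ridge`, `n_patches`, `basis`.
#' @param simulation list: `texture_sd` (spatial albedo variation),
#'   `reference_period` (s), `reference_noise_sd`.
#' @param grid wavelength grid as a list `from`, `to`, `by` (nm).
#' @param seed master seed; all per-stage seeds are derived from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(protocol = occlusion_protocol(),
                            oxy = delta_t_config(),
                            camera = list(),
                            forward = list(),
                            correction = list(),
                            simulation = list(),
                            grid = list(),
                            seed = 1) {
  stopifnot(inherits(protocol, "occlusion_protocol"),
            inherits(oxy, "delta_t_config"))
  camera <- utils::modifyList(list(
    height = 64, width = 64, exposure_ms = 50, gain = 0.5, bit_depth = 10,
    dark_level = 12, noise_sd = 2, fwhm = 20, second_order_height = 0.25,
    second_order_offset = 115, crosstalk_strength = 0.04,
    bandpass = c(455, 645)), camera)
  forward <- utils::modifyList(list(d = 0.2, dpf = 1, melanin = 0.05, G = 0),
                               forward)
  correction <- utils::modifyList(list(m = 10, ridge = 1e-6, n_patches = 24,
                                       basis = "bspline"), correction)
  simulation <- utils::modifyList(list(texture_sd = 0.02,
                                       reference_period = 3.5,
                                       reference_noise_sd = 0.01), simulation)
  grid <- utils::modifyList(list(from = 400, to = 700, by = 10), grid)
  if (camera$height %% 4 != 0 || camera$width %% 4 != 0)
    stop("camera frame dimensions must be multiples of 4", call. = FALSE)
  structure(list(protocol = protocol, oxy = oxy, camera = camera,
                 forward = forward, correction = correction,
                 simulation = simulation, grid = grid, seed = seed),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips unchanged: classed components are stored
#' as plain lists and rebuilt through their constructors on read.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(protocol = do.call(occlusion_protocol, x$protocol),
                  oxy = do.call(delta_t_config, x$oxy),
                  camera = x$camera, forward = x$forward,
                  correction = x$correction, simulation = x$simulation,
                  grid = x$grid, seed = x$seed)
}

build_camera <- function(config) {
  grid <- do.call(wavelength_grid, config$grid)
  cam <- config$camera
  bank <- build_filter_bank(peaks = default_peak_wavelengths(),
                            grid = grid, fwhm = cam$fwhm,
                            second_order_height = cam$second_order_height,
                            second_order_offset = cam$second_order_offset,
                            crosstalk_strength = cam$crosstalk_strength,
                            bandpass = cam$bandpass)
  list(grid = grid, bank = bank, layout = mosaic_layout(bank$peaks),
       lib = chromophore_library(grid = grid))
}

render_args <- function(cam) {
  list(exposure_ms = cam$exposure_ms, gain = cam$gain,
       bit_depth = cam$bit_depth, dark_level = cam$dark_level,
       noise_sd = cam$noise_sd)
}

# full forward simulation: truth, reflectance, references and frame sequence
simulate_scene <- function(config, seed = config$seed) {
  cam <- config$camera
  sc <- build_camera(config)
  truth <- simulate_occlusion_truth(config$protocol, seed)
  params <- skin_forward_params(sc$grid, sc$lib,
                                dpf = config$forward$dpf,
                                d = config$forward$d,
                                G = config$forward$G,
                                melanin = config$forward$melanin)
  refl <- reflectance_from_concentrations(truth, params)
  texture <- with_seed(seed + 1L, pmax(matrix(
    stats::rnorm(cam$height * cam$width, 1, config$simulation$texture_sd),
    cam$height, cam$width), 0.5))
  ra <- render_args(cam)
  refs <- do.call(render_references, c(list(
    bank = sc$bank, layout = sc$layout, height = cam$height,
    width = cam$width, seed = seed + 2L), ra))
  frames <- lapply(seq_len(nrow(truth)), function(i)
    do.call(render_frame, c(list(
      R = refl$R[, i], bank = sc$bank, layout = sc$layout,
      height = cam$height, width = cam$width, texture = texture,
      seed = seed + 10L + i), ra)))
  reference <- simulate_reference_oximeter(
    truth, config$simulation$reference_period,
    config$simulation$reference_noise_sd, seed + 5L)
  c(sc, list(truth = truth, params = params, refl = refl, texture = texture,
             dark = refs$dark, white = refs$white, frames = frames,
             reference = reference))
}

#' Fit the correction model for a simulated camera
#'
#' Generates synthetic training patches, computes their flat-field-style
#' normalized channel responses through the filter bank, and fits the
#' spectral-correction model.
#'
#' @param bank a [build_filter_bank()].
#' @param m number of virtual bands.
#' @param n_patches number of training patches.
#' @param ridge,basis passed to [fit_correction()].
#' @param seed RNG seed for the patch generator.
#' @return a `correction_model`.
#' @export
calibrate_correction <- function(bank, m = 10, n_patches = 24,
                                 ridge = 1e-6, basis = "bspline",
                                 seed = 1) {
  train <- synthetic_training_patches(n_patches, bank$grid, seed)
  resp <- channel_responses(bank, train, normalize = TRUE)
  fit_correction(resp, train, bank$grid, m = m, ridge = ridge, basis = basis,
                 bank = bank)
}

#' Process a mosaic frame sequence into reflectance cubes
#'
#' Flat-field correction against the dark/white references, spatial
#' rearrangement into 16-band cubes, and spectral correction, per frame.
#'
#' @param frames list of raw mosaic frames.
#' @param dark,white reference frames.
#' @param layout [mosaic_layout()].
#' @param model a `correction_model` (use [identity_correction()] for
#'   spectrally uncorrected processing).
#' @param standard_reflectance grey-standard reflectance for absolute
#'   scaling.
#' @return list of reflectance `spectral_cube`s.
#' @export
process_sequence <- function(frames, dark, white, layout, model,
                             standard_reflectance = 0.20) {
  lapply(frames, function(f) {
    ff <- flat_field_correct(f, dark, white, standard_reflectance)
    apply_correction(model, demosaic_subsample(ff, layout))
  })
}

#' Run the full simulated occlusion experiment in memory
#'
#' Scene simulation, sensor rendering, preprocessing, spectral correction,
#' oxygenation estimation and curve comparison in one call, without disk
#' I/O. This is the end-to-end harness used to validate the pipeline
#' against the simulator's ground truth.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed.
#' @param correction `"fit"` (calibrate a model from synthetic patches,
#'   default), `"identity"` (spectrally uncorrected, with a warning), or a
#'   ready `correction_model`.
#' @param map_frames frame indices for which per-pixel concentration maps
#'   are kept.
#' @return list: `truth`, `reference`, `curve` (estimated `oxy_curve`),
#'   `comparison` (`rmse`, `gfc`, aligned pair), `slopes` (on the estimated
#'   curve), `truth_slopes` (on the noiseless ground truth), `model`,
#'   `maps`, `bank`, `layout`.
#' @export
run_occlusion_experiment <- function(config = pipeline_config(),
                                     seed = config$seed,
                                     correction = "fit",
                                     map_frames = integer()) {
  sim <- simulate_scene(config, seed)
  model <- resolve_correction(correction, sim$bank, config)
  cubes <- process_sequence(sim$frames, sim$dark, sim$white, sim$layout,
                            model)
  events <- list(occlusion_start = attr(sim$truth, "occlusion_index"),
                 cuff_release = attr(sim$truth, "release_index"))
  oxy <- estimate_oxy_timeseries(cubes, sim$lib, config$oxy,
                                 times = sim$truth$time_s, events = events,
                                 map_frames = map_frames)
  cmp <- compare_curves(oxy$curve, sim$reference)
  slopes <- fit_slopes(oxy$curve, baseline_index = events$occlusion_start)
  truth_slopes <- fit_slopes(sim$truth,
                             baseline_index = events$occlusion_start)
  list(truth = sim$truth, reference = sim$reference, curve = oxy$curve,
       comparison = cmp, slopes = slopes, truth_slopes = truth_slopes,
       model = model, maps = oxy$maps, bank = sim$bank, layout = sim$layout)
}

resolve_correction <- function(correction, bank, config) {
  if (inherits(correction, "correction_model")) return(correction)
  if (identical(correction, "identity")) {
    warning(paste("no spectral correction model supplied; falling back to",
                  "the identity mapping (spectrally uncorrected channels)"),
            call. = FALSE)
    return(identity_correction(bank$peaks))
  }
  if (identical(correction, "fit")) {
    cc <- config$correction
    return(calibrate_correction(bank, m = cc$m, n_patches = cc$n_patches,
                                ridge = cc$ridge, basis = cc$basis,
                                seed = config$seed))
  }
  if (is.character(correction) && file.exists(correction))
    return(read_correction_model(correction))
  stop("'correction' must be \"fit\", \"identity\", a model or a model path",
       call. = FALSE)
}

# ---- disk-facing entry points -------------------------------------------

#' Simulate an occlusion acquisition to disk
#'
#' Writes the raw mosaic frame sequence (16-bit multi-page TIFF), dark and
#' white reference frames, the ground-truth and reference-oximeter CSV
#' traces, the pipeline configuration and a JSON manifest recording the
#' seed. Re-running with the same seed reproduces every file byte for
#' byte.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @param seed master seed recorded in the manifest.
#' @return named list of the written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = pipeline_config(),
                         seed = config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  sim <- simulate_scene(config, seed)
  paths <- list(frames = file.path(out_dir, "frames.tiff"),
                dark = file.path(out_dir, "dark.tiff"),
                white = file.path(out_dir, "white.tiff"),
                truth = file.path(out_dir, "truth.csv"),
                reference = file.path(out_dir, "reference.csv"),
                config = file.path(out_dir, "config.yaml"),
                manifest = file.path(out_dir, "manifest.json"))
  write_frames_tiff(sim$frames, paths$frames)
  write_frames_tiff(sim$dark, paths$dark)
  write_frames_tiff(sim$white, paths$white)
  write_trace_csv(sim$truth, paths$truth)
  write_trace_csv(sim$reference, paths$reference)
  write_config(config, paths$config)
  jsonlite::write_json(list(seed = seed,
                            n_frames = length(sim$frames),
                            frame_rate = config$protocol$frame_rate,
                            height = config$camera$height,
                            width = config$camera$width),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full pipeline on a simulated acquisition directory
#'
#' Reads the frames and references written by [cmd_simulate()], executes
#' flat-field correction, demosaicking, spectral correction, oxygenation
#' estimation and curve comparison against the stored reference trace, and
#' writes the estimated curve, agreement metrics, slope report and the
#' correction model to `out_dir`. Stage timings are logged via `message()`.
#'
#' @param dir acquisition directory (as written by [cmd_simulate()]).
#' @param config a [pipeline_config()]; `NULL` reads `config.yaml` from
#'   `dir`.
#' @param correction `"fit"`, `"identity"`, a `correction_model` or a model
#'   JSON path (see [run_occlusion_experiment()]).
#' @param out_dir results directory (default `dir`/results).
#' @param verbose log per-stage timings.
#' @return list with `curve`, `comparison`, `slopes`, `model` and the
#'   output `paths`, invisibly.
#' @export
cmd_run_all <- function(dir, config = NULL, correction = "fit",
                        out_dir = file.path(dir, "results"),
                        verbose = TRUE) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    if (verbose)
      message(sprintf("[%s] %.2f s", name, proc.time()[["elapsed"]] - t0))
    val
  }
  config <- config %||% read_config(file.path(dir, "config.yaml"))
  sc <- build_camera(config)
  inputs <- stage("load", {
    list(frames = read_frames_tiff(file.path(dir, "frames.tiff"),
                                   config$camera$bit_depth),
         dark = read_frames_tiff(file.path(dir, "dark.tiff"),
                                 config$camera$bit_depth)[[1]],
         white = read_frames_tiff(file.path(dir, "white.tiff"),
                                  config$camera$bit_depth)[[1]],
         reference = utils::read.csv(file.path(dir, "reference.csv")))
  })
  model <- stage("calibrate", resolve_correction(correction, sc$bank, config))
  cubes <- stage("process", process_sequence(inputs$frames, inputs$dark,
                                             inputs$white, sc$layout, model))
  fr <- config$protocol$frame_rate
  events <- list(
    occlusion_start = round(config$protocol$baseline_duration * fr) + 1L,
    cuff_release = round((config$protocol$baseline_duration +
                            config$protocol$occlusion_duration) * fr) + 1L)
  oxy <- stage("oxygenation", estimate_oxy_timeseries(
    cubes, sc$lib, config$oxy,
    times = (seq_along(cubes) - 1) / fr, events = events))
  cmp <- stage("compare", compare_curves(oxy$curve, inputs$reference))
  slopes <- fit_slopes(oxy$curve, baseline_index = events$occlusion_start)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(curve = file.path(out_dir, "curve.csv"),
                metrics = file.path(out_dir, "metrics.json"),
                model = file.path(out_dir, "model.json"))
  write_trace_csv(oxy$curve, paths$curve)
  jsonlite::write_json(list(rmse = cmp$rmse, gfc = cmp$gfc,
                            desaturation_slope = slopes$desaturation_slope,
                            resaturation_slope = slopes$resaturation_slope,
                            dt = slopes$dt),
                       paths$metrics, auto_unbox = TRUE, digits = NA)
  if (!identical(model$basis, "identity"))
    write_correction_model(model, paths$model)
  invisible(list(curve = oxy$curve, comparison = cmp, slopes = slopes,
                 model = model, paths = paths))
}

# ---- TIFF helpers --------------------------------------------------------

#' Write mosaic frames as a 16-bit multi-page TIFF
#'
#' Integer counts are stored as `count / 65535`, which is exact for bit
#' depths up to 16.
#'
#' @param frames a `mosaic_frame` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  if (!is.list(frames)) frames <- list(frames)
  imgs <- lapply(frames, function(f) unclass(f) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read mosaic frames from a multi-page TIFF
#'
#' @param path TIFF written by [write_frames_tiff()].
#' @param bit_depth ADC bit depth recorded on the returned frames.
#' @return list of `mosaic_frame` matrices (integer counts).
#' @export
read_frames_tiff <- function(path, bit_depth = 10) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(x)
    structure(round(x * 65535), class = "mosaic_frame",
              bit_depth = bit_depth))
}

#' Write / read a reflectance cube sequence as TIFF + JSON sidecar
#'
#' Pages are ordered frame-major (all bands of frame 1, then frame 2, ...).
#' Values are affinely mapped onto \[0, 1\] for 16-bit storage; the sidecar
#' records the mapping, the band centers and the frame count.
#'
#' @param cubes list of `spectral_cube`s with identical geometry.
#' @param path TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path` (write) / list of `spectral_cube`s (read).
#' @export
write_cube_sequence <- function(cubes, path) {
  stopifnot(is.list(cubes), length(cubes) > 0)
  ctrs <- band_centers(cubes[[1]])
  lo <- min(vapply(cubes, min, 0, na.rm = TRUE))
  hi <- max(vapply(cubes, max, 0, na.rm = TRUE))
  if (hi <= lo) hi <- lo + 1
  pages <- unlist(lapply(cubes, function(cu) {
    v <- unclass(cu)
    lapply(seq_along(ctrs), function(b) {
      m <- (v[, , b] - lo) / (hi - lo)
      m[!is.finite(m)] <- 0
      m
    })
  }), recursive = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(list(band_centers = ctrs, n_frames = length(cubes),
                            lo = lo, hi = hi, kind = attr(cubes[[1]], "kind")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cube_sequence
#' @export
read_cube_sequence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nb <- length(meta$band_centers)
  lapply(seq_len(meta$n_frames), function(i) {
    slab <- pages[((i - 1) * nb + 1):(i * nb)]
    cube <- array(0, c(dim(slab[[1]]), nb))
    for (b in seq_len(nb))
      cube[, , b] <- slab[[b]] * (meta$hi - meta$lo) + meta$lo
    new_spectral_cube(cube, meta$band_centers, kind = meta$kind)
  })
}
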