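#' Vascular occlusion test protocol
#'
#' Parameters of a simulated upper-arm occlusion: a stable baseline, a linear
#' desaturation while the cuff is inflated, cuff release once tissue
#' saturation has dropped to `release_threshold_fraction` of baseline
#' (default 40%, i.e. a ~60% drop), a steep resaturation overshooting the
#' baseline, and an exponential return. Phase boundaries are snapped to the
#' frame grid so the release sample carries exactly the threshold saturation.
#'
#' Either `occlusion_duration` (s) or `desaturation_rate` (fraction of the
#' baseline saturation lost per second) may be given; the other is derived
#' from the release threshold.
#'
#' @param baseline_duration seconds of stable baseline before cuff inflation.
#' @param occlusion_duration seconds of cuff inflation (ignored when
#'   `desaturation_rate` is supplied).
#' @param desaturation_rate fraction of baseline saturation lost per second
#'   during occlusion, or `NULL` to derive it from `occlusion_duration`.
#' @param release_threshold_fraction fraction of baseline saturation at which
#'   the cuff is released; must lie in (0, 1).
#' @param overshoot_amplitude post-release overshoot, as a fraction above the
#'   baseline saturation.
#' @param overshoot_time_dt seconds from cuff release to the overshoot peak.
#' @param return_time_constant seconds; exponential return to baseline.
#' @param recovery_duration seconds recorded after cuff release.
#' @param frame_rate acquisition rate in Hz (default 1 fps).
#' @param noise_sd additive Gaussian noise on the saturation trace
#'   (StO2 fraction units).
#' @param baseline_sto2 baseline tissue oxygen saturation (fraction).
#' @param total_hb_mM total hemoglobin concentration (mM), held constant
#'   unless `blood_volume_drift` is non-zero.
#' @param blood_volume_drift optional linear drift of total hemoglobin
#'   (fraction of `total_hb_mM` per second); default 0 keeps blood volume
#'   constant.
#' @return an `occlusion_protocol` object (a validated list).
#' @export
#' @examples
#' p <- occlusion_protocol()
#' p$desaturation_rate  # (1 - 0.4) / 120
occlusion_protocol <- function(baseline_duration = 60,
                               occlusion_duration = 120,
                               desaturation_rate = NULL,
                               release_threshold_fraction = 0.40,
                               overshoot_amplitude = 0.05,
                               overshoot_time_dt = 15,
                               return_time_constant = 30,
                               recovery_duration = 120,
                               frame_rate = 1,
                               noise_sd = 0.005,
                               baseline_sto2 = 0.70,
                               total_hb_mM = 0.10,
                               blood_volume_drift = 0) {
  check_scalar(release_threshold_fraction, "release_threshold_fraction",
               0, 1, open_lower = TRUE, open_upper = TRUE)
  if (!is.null(desaturation_rate)) {
    check_scalar(desaturation_rate, "desaturation_rate", 0, open_lower = TRUE)
    occlusion_duration <- (1 - release_threshold_fraction) / desaturation_rate
  }
  check_scalar(baseline_duration, "baseline_duration", 0, open_lower = TRUE)
  check_scalar(occlusion_duration, "occlusion_duration", 0, open_lower = TRUE)
  check_scalar(overshoot_amplitude, "overshoot_amplitude", 0)
  check_scalar(overshoot_time_dt, "overshoot_time_dt", 0, open_lower = TRUE)
  check_scalar(return_time_constant, "return_time_constant", 0, open_lower = TRUE)
  check_scalar(recovery_duration, "recovery_duration", 0, open_lower = TRUE)
  check_scalar(frame_rate, "frame_rate", 0, open_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(baseline_sto2, "baseline_sto2", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(total_hb_mM, "total_hb_mM", 0, open_lower = TRUE)
  check_scalar(blood_volume_drift, "blood_volume_drift")
  if (occlusion_duration < 2 / frame_rate)
    stop("occlusion_duration must span at least two frames", call. = FALSE)
  if (baseline_sto2 * (1 + overshoot_amplitude) > 1)
    stop("overshoot_amplitude would push saturation above 1", call. = FALSE)
  rate <- (1 - release_threshold_fraction) / occlusion_duration
  structure(list(baseline_duration = baseline_duration,
                 occlusion_duration = occlusion_duration,
                 desaturation_rate = rate,
                 release_threshold_fraction = release_threshold_fraction,
                 overshoot_amplitude = overshoot_amplitude,
                 overshoot_time_dt = overshoot_time_dt,
                 return_time_constant = return_time_constant,
                 recovery_duration = recovery_duration,
                 frame_rate = frame_rate,
                 noise_sd = noise_sd,
                 baseline_sto2 = baseline_sto2,
                 total_hb_mM = total_hb_mM,
                 blood_volume_drift = blood_volume_drift),
            class = "occlusion_protocol")
}

#' Simulate ground-truth occlusion dynamics
#'
#' Generates the noiseless piecewise saturation trajectory implied by the
#' protocol (stable baseline, linear desaturation to the release threshold,
#' linear resaturation to an overshoot `overshoot_time_dt` seconds after
#' release, exponential return to baseline), adds Gaussian noise, and
#' converts saturation to oxy-/deoxy-hemoglobin concentrations. Total
#' hemoglobin is constant unless the protocol enables a blood-volume drift,
#' so noise is applied to the oxygen saturation and split between the two
#' species with opposite signs.
#'
#' @param protocol an [occlusion_protocol()].
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#' @return an `oxy_truth` data.frame with columns `time_s`, `c_O2Hb_mM`,
#'   `c_HHb_mM`, `StO2_frac` and `event` (`"occlusion_start"` /
#'   `"cuff_release"` markers), plus attributes `occlusion_index`,
#'   `release_index` and `protocol`.
#' @export
#' @examples
#' truth <- simulate_occlusion_truth(occlusion_protocol(noise_sd = 0))
#' min(truth$StO2_frac) / truth$StO2_frac[1]  # 0.4
simulate_occlusion_truth <- function(protocol = occlusion_protocol(),
                                     seed = NULL) {
  stopifnot(inherits(protocol, "occlusion_protocol"))
  p <- protocol
  fr <- p$frame_rate
  n <- floor((p$baseline_duration + p$occlusion_duration +
                p$recovery_duration) * fr)
  t <- (seq_len(n) - 1) / fr
  # phase anchors snapped to the frame grid (1-based sample indices)
  i0 <- round(p$baseline_duration * fr) + 1L            # occlusion start
  i1 <- round((p$baseline_duration + p$occlusion_duration) * fr) + 1L # release
  i2 <- min(round((p$baseline_duration + p$occlusion_duration +
                     p$overshoot_time_dt) * fr) + 1L, n) # overshoot peak
  s0 <- p$baseline_sto2
  s_rel <- p$release_threshold_fraction * s0
  s_over <- s0 * (1 + p$overshoot_amplitude)
  s <- rep(s0, n)
  occ <- i0:i1
  s[occ] <- s0 + (s_rel - s0) * (occ - i0) / (i1 - i0)
  res <- i1:i2
  s[res] <- s_rel + (s_over - s_rel) * (res - i1) / max(i2 - i1, 1L)
  if (i2 < n) {
    tail_idx <- (i2 + 1L):n
    s[tail_idx] <- s0 + (s_over - s0) * exp(-(t[tail_idx] - t[i2]) /
                                              p$return_time_constant)
  }
  if (p$noise_sd > 0)
    s <- s + with_seed(seed, stats::rnorm(n, 0, p$noise_sd))
  s <- pmin(pmax(s, 0), 1)
  thb <- p$total_hb_mM * (1 + p$blood_volume_drift * pmax(t - t[i0], 0))
  event <- character(n)
  event[i0] <- "occlusion_start"
  event[i1] <- "cuff_release"
  out <- data.frame(time_s = t,
                    c_O2Hb_mM = s * thb,
                    c_HHb_mM = (1 - s) * thb,
                    StO2_frac = s,
                    event = event,
                    stringsAsFactors = FALSE)
  structure(out, class = c("oxy_truth", "data.frame"),
            occlusion_index = i0, release_index = i1, protocol = p)
}

#' Skin forward-model parameters
#'
#' Optical parameters turning chromophore concentrations into diffuse
#' reflectance through the modified Beer-Lambert law: absorbance
#' `A(lambda, t) = eps(lambda) %*% c(t) * DPF(lambda) * d + G(lambda) +
#' melanin(lambda) + H(t)` and `R = 10^-A`. `G` and `H` are
#' oxygen-independent loss terms (wavelength- and time-dependent
#' respectively); both default to 0 so that absorbance changes depend only
#' on concentration changes.
#'
#' @param grid wavelength grid (nm).
#' @param lib [chromophore_library()] resolved on `grid`.
#' @param dpf differential pathlength factor, scalar or per-wavelength
#'   (dimensionless, >= 1).
#' @param d geometric path length in cm (> 0).
#' @param G wavelength-dependent loss (absorbance units), scalar or
#'   per-wavelength.
#' @param H time-dependent loss, scalar (constant in time by default).
#' @param melanin melanin absorbance at 694 nm; 0 disables the melanin term.
#' @param illuminant relative spectral power of the light source, scalar or
#'   per-wavelength.
#' @return a `skin_forward_params` object.
#' @export
skin_forward_params <- function(grid = wavelength_grid(),
                                lib = chromophore_library(grid = grid),
                                dpf = 1, d = 0.2, G = 0, H = 0,
                                melanin = 0, illuminant = 1) {
  validate_grid(grid)
  stopifnot(inherits(lib, "chromophore_library"))
  if (!isTRUE(all.equal(lib$grid, grid)))
    lib <- chromophore_library(
      data.frame(wavelength_nm = lib$grid, lib$extinction), grid = grid)
  n <- length(grid)
  dpf <- rep_len(dpf, n)
  if (any(!is.finite(dpf)) || any(dpf < 1))
    stop("DPF must be finite and >= 1 at every wavelength", call. = FALSE)
  check_scalar(d, "d", 0, open_lower = TRUE)
  check_scalar(H, "H")
  check_scalar(melanin, "melanin", 0)
  structure(list(grid = grid, lib = lib, dpf = dpf, d = d,
                 G = rep_len(G, n), H = H, melanin = melanin,
                 illuminant = rep_len(illuminant, n)),
            class = "skin_forward_params")
}

#' Forward-model reflectance from concentration time series
#'
#' Evaluates the modified Beer-Lambert absorbance for each time point and
#' wavelength and converts it to diffuse reflectance `R = 10^-A`. Values
#' above 1 (possible with negative loss terms) are clamped to 1 and counted.
#'
#' @param truth an `oxy_truth` data.frame (or any data.frame with
#'   `time_s`, `c_O2Hb_mM` and `c_HHb_mM` columns).
#' @param params [skin_forward_params()].
#' @return a `reflectance_series` list: `wavelength` (nm), `time` (s),
#'   `R` (wavelength x time matrix in (0, 1]), `n_clamped`.
#' @export
reflectance_from_concentrations <- function(truth,
                                            params = skin_forward_params()) {
  stopifnot(is.data.frame(truth),
            all(c("time_s", "c_O2Hb_mM", "c_HHb_mM") %in% names(truth)),
            inherits(params, "skin_forward_params"))
  conc <- rbind(truth$c_O2Hb_mM, truth$c_HHb_mM)
  if (anyNA(conc) || any(conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  eps <- extinction_at(params$lib, params$grid)          # n x 2
  A <- (eps %*% conc) * (params$dpf * params$d)          # recycles by column
  A <- A + params$G + melanin_absorbance(params$grid, params$melanin) +
    params$H
  R <- 10^(-A)
  n_clamped <- sum(R > 1)
  if (n_clamped > 0) {
    warning(sprintf("%d reflectance value(s) exceeded 1 and were clamped",
                    n_clamped), call. = FALSE)
    R[R > 1] <- 1
  }
  structure(list(wavelength = params$grid, time = truth$time_s, R = R,
                 n_clamped = n_clamped),
            class = "reflectance_series")
}

#' Simulate a slow reference oximeter trace
#'
#' Resamples the ground-truth saturation at the reference device's slower
#' sampling period (one reading every 3.5 s by default, versus the camera's
#' 1 fps) and adds measurement noise. Sampling starts at the first truth
#' sample and proceeds in steps of `sample_period` up to the last covered
#' time, so a 1 Hz truth of length `n` yields
#' `floor((n - 1) / sample_period) + 1` readings.
#'
#' @param truth an `oxy_truth` data.frame.
#' @param sample_period seconds between reference readings; must be at least
#'   the truth's frame period.
#' @param noise_sd additive Gaussian noise (StO2 fraction units).
#' @param seed integer RNG seed.
#' @return a `reference_trace` data.frame with columns `time_s`, `StO2_frac`.
#' @export
simulate_reference_oximeter <- function(truth, sample_period = 3.5,
                                        noise_sd = 0.01, seed = NULL) {
  stopifnot(is.data.frame(truth),
            all(c("time_s", "StO2_frac") %in% names(truth)))
  check_scalar(sample_period, "sample_period", 0, open_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  dt <- stats::median(diff(truth$time_s))
  if (sample_period < dt)
    stop("sample_period must be at least the truth's frame period",
         call. = FALSE)
  times <- seq(truth$time_s[1], max(truth$time_s), by = sample_period)
  sto2 <- stats::approx(truth$time_s, truth$StO2_frac, xout = times)$y
  if (noise_sd > 0)
    sto2 <- sto2 + with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  structure(data.frame(time_s = times, StO2_frac = sto2),
            class = c("reference_trace", "data.frame"))
}

#' Write a truth or reference trace to CSV
#'
#' @param x an `oxy_truth`, `reference_trace` or `oxy_curve` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
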