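#' Optical density (absorbance) of a reflectance cube
#'
#' `A = -log10(R)` per pixel and band. Non-positive or non-finite
#' reflectances are masked (`NA`); an error is raised if a whole band is
#' masked.
#'
#' @param x reflectance values: numeric vector, matrix or `spectral_cube`.
#' @return object of the same shape holding absorbance; cubes keep their
#'   band centers with kind `"absorbance"`.
#' @export
#' @examples
#' absorbance(c(1, 0.1, 0.01))  # 0 1 2
absorbance <- function(x) {
  v <- unclass(x)
  mask <- !is.finite(v) | v <= 0
  A <- suppressWarnings(-log10(v))
  A[mask] <- NA_real_
  if (inherits(x, "spectral_cube")) {
    d <- dim(v)
    all_masked <- apply(matrix(is.na(A), d[1] * d[2], d[3]), 2, all)
    if (any(all_masked))
      stop(sprintf("band(s) %s are fully masked (non-positive reflectance)",
                   paste(which(all_masked), collapse = ", ")), call. = FALSE)
    return(new_spectral_cube(A, band_centers(x), kind = "absorbance"))
  }
  A
}

#' Configuration of the delta-concentration estimator
#'
#' @param key_wavelengths wavelengths (nm) used in three-band mode; the
#'   defaults are an isosbestic reference near 515 nm and the
#'   high-contrast 565 and 601 nm bands.
#' @param mode `"three"` (key wavelengths only) or `"all"` (every virtual
#'   band).
#' @param dpf differential pathlength factor, scalar or one value per used
#'   wavelength. The default of 1 reports concentration changes in units of
#'   the geometric path; only relative changes are interpreted downstream,
#'   so the global factor cancels in the feature-scaled curves.
#' @param d source-detector distance in cm.
#' @param baseline_frames number of initial frames averaged into the
#'   baseline absorbance.
#' @param roi circular region of interest `c(row, col, radius)` in
#'   band-image coordinates; radius 0 selects the single pixel. `NULL`
#'   defaults to a centered disc of a quarter of the short image side.
#' @param proxy scalar saturation proxy derived from the concentration
#'   changes: `"diff"` (oxy minus deoxy, default), `"O2Hb"`, or
#'   `"fraction"`.
#' @return a `delta_t_config` object.
#' @export
delta_t_config <- function(key_wavelengths = c(515, 565, 601),
                           mode = c("three", "all"),
                           dpf = 1, d = 1, baseline_frames = 5,
                           roi = NULL,
                           proxy = c("diff", "O2Hb", "fraction")) {
  stopifnot(is.numeric(key_wavelengths), length(key_wavelengths) >= 2)
  check_scalar(d, "d", 0, open_lower = TRUE)
  check_scalar(baseline_frames, "baseline_frames", 1)
  if (any(!is.finite(dpf)) || any(dpf <= 0))
    stop("DPF values must be positive", call. = FALSE)
  if (!is.null(roi)) {
    roi <- as.numeric(unlist(roi))
    stopifnot(length(roi) == 3, roi[3] >= 0)
  }
  structure(list(key_wavelengths = key_wavelengths, mode = match.arg(mode),
                 dpf = dpf, d = d,
                 baseline_frames = as.integer(baseline_frames),
                 roi = roi, proxy = match.arg(proxy)),
            class = "delta_t_config")
}

#' Resolve key wavelengths to virtual bands
#'
#' Nearest-center lookup; errors when a wavelength falls farther than half
#' the band spacing from every center.
#'
#' @param centers virtual band centers (nm).
#' @param wavelengths requested wavelengths (nm).
#' @return list: `index` into the bands, `center` (the resolved
#'   wavelengths).
#' @export
resolve_bands <- function(centers, wavelengths) {
  spacing <- if (length(centers) > 1) stats::median(diff(sort(centers))) else Inf
  idx <- vapply(wavelengths, function(wl) which.min(abs(centers - wl)), 1L)
  dist <- abs(centers[idx] - wavelengths)
  if (any(dist > spacing / 2 + 1e-9))
    stop(sprintf("wavelength(s) %s fall outside half a band spacing of any center",
                 paste(wavelengths[dist > spacing / 2 + 1e-9], collapse = ", ")),
         call. = FALSE)
  list(index = idx, center = centers[idx])
}

#' Invert absorbance changes to concentration changes
#'
#' Solves the differential modified Beer-Lambert system: the wavelength x 2
#' extinction-times-DPF matrix maps `(d c_O2Hb, d c_HHb)` to absorbance
#' changes, so the least-squares pseudo-inverse divided by the path length
#' recovers the concentration changes. The wavelength- and time-constant
#' loss terms cancel in the difference, which is the point of referencing a
#' stable baseline.
#'
#' @param delta_A absorbance changes: vector of length K (one per
#'   wavelength) or K x T matrix over time.
#' @param lib [chromophore_library()].
#' @param wavelengths the K wavelengths (nm) the rows of `delta_A` refer to.
#' @param dpf differential pathlength factor, scalar or length K.
#' @param d source-detector distance (cm).
#' @return 2 x T matrix (rows `O2Hb`, `HHb`) of concentration changes in
#'   mM, or a named 2-vector for vector input.
#' @export
delta_concentrations <- function(delta_A, lib = chromophore_library(),
                                 wavelengths = c(515, 565, 601),
                                 dpf = 1, d = 1) {
  single <- is.null(dim(delta_A))
  dA <- if (single) matrix(delta_A, ncol = 1) else as.matrix(delta_A)
  if (nrow(dA) != length(wavelengths))
    stop("delta_A must have one row per wavelength", call. = FALSE)
  check_scalar(d, "d", 0, open_lower = TRUE)
  E <- extinction_at(lib, wavelengths) * rep_len(dpf, length(wavelengths))
  cond <- kappa(E, exact = TRUE)
  if (cond > 1e4)
    warning(sprintf(
      "extinction matrix is ill-conditioned (kappa = %.3g); wavelengths %s are nearly collinear",
      cond, paste(wavelengths, collapse = ", ")), call. = FALSE)
  pinv <- solve(crossprod(E), t(E))                   # 2 x K
  dc <- (pinv %*% dA) / d
  rownames(dc) <- c("O2Hb", "HHb")
  if (single) stats::setNames(drop(dc), c("O2Hb", "HHb")) else dc
}

roi_mask <- function(h, w, roi) {
  row0 <- roi[1]; col0 <- roi[2]; r <- roi[3]
  if (row0 < 1 || row0 > h || col0 < 1 || col0 > w)
    stop("ROI center lies outside the image", call. = FALSE)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - row0)^2 + (cc - col0)^2 <= r^2
}

proxy_from_dc <- function(dc, proxy) {
  switch(proxy,
         diff = dc["O2Hb", ] - dc["HHb", ],
         O2Hb = dc["O2Hb", ],
         fraction = {
           tot <- abs(dc["O2Hb", ]) + abs(dc["HHb", ])
           ifelse(tot > 0, dc["O2Hb", ] / tot, 0)
         })
}

#' Estimate oxygenation time series from a cube sequence
#'
#' The mean absorbance of the first `baseline_frames` frames estimates the
#' time-invariant contributions; the absorbance change of every later frame
#' relative to that baseline is inverted to oxy-/deoxy-hemoglobin
#' concentration changes -- averaged over the region of interest for the
#' curve, and per pixel for the optional concentration maps.
#'
#' @param cubes list of reflectance `spectral_cube`s over time (equal
#'   geometry and bands), or a 4D array `H x W x bands x T` with a
#'   `band_centers` attribute.
#' @param lib [chromophore_library()].
#' @param cfg [delta_t_config()].
#' @param times frame times in seconds (default `0:(T-1)`).
#' @param events optional named list/vector of frame indices (e.g.
#'   `occlusion_start`, `cuff_release`) recorded in the curve.
#' @param map_frames frame indices for which per-pixel concentration-change
#'   maps are returned (may be large; default none).
#' @return list with `curve` (an `oxy_curve` data.frame: `time_s`,
#'   `d_O2Hb_mM`, `d_HHb_mM`, `proxy`, `event`), `maps` (named list of
#'   `H x W x 2` arrays), `bands` (the band resolution used), `roi`
#'   (logical mask).
#' @export
estimate_oxy_timeseries <- function(cubes, lib = chromophore_library(),
                                    cfg = delta_t_config(), times = NULL,
                                    events = NULL, map_frames = integer()) {
  stopifnot(inherits(cfg, "delta_t_config"))
  if (is.array(cubes) && length(dim(cubes)) == 4) {
    ctrs <- attr(cubes, "band_centers")
    if (is.null(ctrs)) stop("4D cube array needs a band_centers attribute",
                            call. = FALSE)
    nT <- dim(cubes)[4]
    get_cube <- function(i) cubes[, , , i]
    dims <- dim(cubes)[1:3]
  } else {
    stopifnot(is.list(cubes), length(cubes) > 0)
    ctrs <- band_centers(cubes[[1]])
    nT <- length(cubes)
    get_cube <- function(i) unclass(cubes[[i]])
    dims <- dim(cubes[[1]])
  }
  if (nT < cfg$baseline_frames + 1)
    stop("need at least baseline_frames + 1 frames", call. = FALSE)
  h <- dims[1]; w <- dims[2]; nb <- dims[3]
  roi <- cfg$roi %||% c(ceiling(h / 2), ceiling(w / 2),
                        floor(min(h, w) / 4))
  mask <- roi_mask(h, w, roi)
  if (!any(mask)) stop("ROI contains no pixels", call. = FALSE)
  if (cfg$mode == "three") {
    res <- resolve_bands(ctrs, cfg$key_wavelengths)
    sel <- res$index; wl <- res$center
  } else {
    sel <- seq_len(nb); wl <- ctrs
  }
  dpf <- rep_len(cfg$dpf, length(sel))
  # per-frame absorbance: ROI band means + full arrays for baseline/maps
  roi_A <- matrix(NA_real_, nb, nT)
  base_sum <- array(0, c(h, w, nb))
  A_list <- vector("list", nT)
  keep_pix <- sort(unique(c(seq_len(cfg$baseline_frames), map_frames)))
  for (i in seq_len(nT)) {
    R <- get_cube(i)
    Ai <- suppressWarnings(-log10(R))
    Ai[!is.finite(Ai)] <- NA_real_
    roi_A[, i] <- apply(matrix(Ai, h * w, nb)[mask, , drop = FALSE], 2,
                        mean, na.rm = TRUE)
    if (i <= cfg$baseline_frames) base_sum <- base_sum + Ai
    if (i %in% keep_pix) A_list[[i]] <- Ai
  }
  if (any(!is.finite(roi_A)))
    stop("ROI absorbance is undefined (fully masked band in the ROI)",
         call. = FALSE)
  base_roi <- rowMeans(roi_A[, seq_len(cfg$baseline_frames), drop = FALSE])
  dA <- roi_A[sel, , drop = FALSE] - base_roi[sel]
  dc <- delta_concentrations(dA, lib, wl, dpf = dpf, d = cfg$d)
  event <- character(nT)
  if (!is.null(events))
    for (nm in names(events)) event[events[[nm]]] <- nm
  curve <- structure(
    data.frame(time_s = times %||% (seq_len(nT) - 1),
               d_O2Hb_mM = dc["O2Hb", ], d_HHb_mM = dc["HHb", ],
               proxy = proxy_from_dc(dc, cfg$proxy),
               event = event, stringsAsFactors = FALSE),
    class = c("oxy_curve", "data.frame"), proxy = cfg$proxy,
    mode = cfg$mode, wavelengths = wl)
  maps <- list()
  if (length(map_frames)) {
    base_pix <- base_sum / cfg$baseline_frames
    E <- extinction_at(lib, wl) * dpf
    pinv <- solve(crossprod(E), t(E))
    for (f in map_frames) {
      dA_pix <- (A_list[[f]] - base_pix)[, , sel, drop = FALSE]
      dc_pix <- pinv %*% t(matrix(dA_pix, h * w, length(sel))) / cfg$d
      maps[[as.character(f)]] <- array(t(dc_pix), c(h, w, 2))
    }
  }
  list(curve = curve, maps = maps,
       bands = list(index = sel, wavelength = wl), roi = mask)
}

#' @export
print.oxy_curve <- function(x, ...) {
  cat(sprintf("<oxy_curve> %d frames, proxy '%s', mode '%s' (%s nm)\n",
              nrow(x), attr(x, "proxy"), attr(x, "mode"),
              paste(round(attr(x, "wavelengths"), 1), collapse = ", ")))
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}

#' Plot an oxygenation curve
#'
#' @param x an `oxy_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.oxy_curve <- function(x, ...) {
  graphics::plot(x$time_s, x$proxy, type = "l", xlab = "time [s]",
                 ylab = sprintf("saturation proxy (%s)", attr(x, "proxy")),
                 ...)
  ev <- which(x$event != "")
  if (length(ev)) graphics::abline(v = x$time_s[ev], lty = 3)
  invisible(x)
}
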