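#' Default peak wavelengths of the 16-channel mosaic
#'
#' Sixteen peaks equally distributed over the sensor's active range
#' (470--630 nm).
#'
#' @param n number of channels.
#' @param range active range in nm.
#' @return numeric vector of peak wavelengths, ascending.
#' @export
default_peak_wavelengths <- function(n = 16, range = c(470, 630)) {
  round(seq(range[1], range[2], length.out = n), 1)
}

#' Mosaic layout of the spectral filter array
#'
#' Maps each position of the repeating 4x4 tile to one of the 16 spectral
#' channels. The default places channels row-major in ascending wavelength
#' order; any bijection is valid and real cameras should supply theirs.
#'
#' @param peaks per-channel peak wavelengths (nm), length 16.
#' @param pattern 4x4 integer matrix; `pattern[r, c]` is the channel index at
#'   tile offset (r, c). Must contain each of 1..16 exactly once.
#' @return a `mosaic_layout` object.
#' @export
mosaic_layout <- function(peaks = default_peak_wavelengths(),
                          pattern = matrix(1:16, 4, 4, byrow = TRUE)) {
  if (!is.matrix(pattern) || !all(dim(pattern) == c(4, 4)) ||
      !setequal(as.integer(pattern), 1:16) || anyDuplicated(as.integer(pattern)))
    stop("pattern must be a 4x4 matrix containing each channel 1..16 exactly once",
         call. = FALSE)
  if (!is.numeric(peaks) || length(peaks) != 16 || any(!is.finite(peaks)))
    stop("peaks must be 16 finite wavelengths", call. = FALSE)
  structure(list(pattern = matrix(as.integer(pattern), 4, 4), peaks = peaks),
            class = "mosaic_layout")
}

#' Build a Fabry-Perot-like filter bank
#'
#' Each channel is a primary Gaussian lobe at its peak wavelength plus a
#' scaled second-order lobe at a fixed offset below the primary (the
#' second-order harmonic of the interference cavity), multiplied by the
#' band-pass window that limits the active range, then mixed with its
#' spectral neighbours (crosstalk) and normalized to unit peak. Gaussian
#' lobes stand in for true cavity transmission curves, whose exact shapes
#' are camera-specific.
#'
#' @param peaks 16 peak wavelengths (nm) inside the grid.
#' @param grid wavelength grid (nm).
#' @param fwhm full width at half maximum of the primary lobe (nm).
#' @param second_order_height relative height of the second-order lobe,
#'   in \[0, 1).
#' @param second_order_offset nm below the primary peak at which the
#'   second-order lobe sits.
#' @param crosstalk_strength fraction of each channel's signal mixed in from
#'   spectrally adjacent channels, in \[0, 1).
#' @param bandpass c(low, high) nm; sensitivity outside is zero.
#' @return a `filter_bank`: list with `Q` (16 x grid sensitivity matrix,
#'   unit peak per row), `grid`, `peaks`, and the construction parameters.
#' @export
#' @examples
#' bank <- build_filter_bank()
#' dim(bank$Q)  # 16 channels x 31 grid points
build_filter_bank <- function(peaks = default_peak_wavelengths(),
                              grid = wavelength_grid(),
                              fwhm = 20,
                              second_order_height = 0.25,
                              second_order_offset = 115,
                              crosstalk_strength = 0.04,
                              bandpass = c(455, 645)) {
  validate_grid(grid)
  if (any(peaks < min(grid) | peaks > max(grid)))
    stop("peak wavelengths must lie inside the grid", call. = FALSE)
  check_scalar(fwhm, "fwhm", 0, open_lower = TRUE)
  check_scalar(second_order_height, "second_order_height", 0, 1,
               open_upper = TRUE)
  check_scalar(second_order_offset, "second_order_offset", 0, open_lower = TRUE)
  check_scalar(crosstalk_strength, "crosstalk_strength", 0, 1,
               open_upper = TRUE)
  stopifnot(length(bandpass) == 2, bandpass[1] < bandpass[2])
  n <- length(peaks)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  Q <- t(vapply(peaks, function(p) {
    prim <- exp(-0.5 * ((grid - p) / sigma)^2)
    sec <- second_order_height *
      exp(-0.5 * ((grid - (p - second_order_offset)) / (0.8 * sigma))^2)
    prim + sec
  }, numeric(length(grid))))
  bp <- as.numeric(grid >= bandpass[1] & grid <= bandpass[2])
  Q <- Q * rep(bp, each = n)
  if (crosstalk_strength > 0) {
    ord <- order(peaks)
    W <- matrix(0, n, n)
    for (k in seq_len(n)) {
      pos <- which(ord == k)
      nb <- ord[c(pos - 1, pos + 1)[c(pos - 1, pos + 1) >= 1 &
                                      c(pos - 1, pos + 1) <= n]]
      W[k, nb] <- 1 / length(nb)
    }
    Q <- ((1 - crosstalk_strength) * diag(n) + crosstalk_strength * W) %*% Q
  }
  mx <- apply(Q, 1, max)
  if (any(mx <= 0))
    stop("a channel has zero sensitivity inside the band-pass window",
         call. = FALSE)
  Q <- Q / mx
  structure(list(Q = Q, grid = grid, peaks = peaks, bandpass = bandpass,
                 fwhm = fwhm, second_order_height = second_order_height,
                 second_order_offset = second_order_offset,
                 crosstalk_strength = crosstalk_strength),
            class = "filter_bank")
}

#' Channel responses to reflectance spectra
#'
#' Discrete camera response per channel: `P_i = sum_lambda Q_i(lambda)
#' E(lambda) R(lambda) dlambda`. With `normalize = TRUE` each response is
#' divided by the channel's integrated sensitivity under the illuminant,
#' which is exactly what flat-field correction against a spectrally flat
#' standard produces: a sensitivity-weighted mean reflectance. Training
#' responses for the spectral-correction fit must use the normalized form.
#'
#' @param bank a [build_filter_bank()] result.
#' @param R reflectance: vector on the bank's grid, or a k x grid matrix of
#'   k spectra in rows.
#' @param illuminant relative spectral power, scalar or per-wavelength.
#' @param normalize divide by the integrated sensitivity (default `TRUE`).
#' @return numeric vector of 16 responses (single spectrum) or a k x 16
#'   matrix.
#' @export
channel_responses <- function(bank, R, illuminant = 1, normalize = TRUE) {
  stopifnot(inherits(bank, "filter_bank"))
  ng <- length(bank$grid)
  single <- is.null(dim(R))
  Rm <- if (single) matrix(R, nrow = 1) else as.matrix(R)
  if (ncol(Rm) != ng)
    stop("reflectance must be sampled on the bank's wavelength grid",
         call. = FALSE)
  w <- grid_weights(bank$grid) * rep_len(illuminant, ng)
  P <- Rm %*% t(bank$Q * rep(w, each = nrow(bank$Q)))   # k x 16
  if (normalize) {
    denom <- as.numeric(bank$Q %*% w)
    P <- P / rep(denom, each = nrow(P))
  }
  if (single) drop(P) else P
}

#' Render a mosaic frame
#'
#' Simulates one raw sensor exposure: per-pixel channel response (discrete
#' integral of sensitivity x illuminant x reflectance), electronic gain and
#' exposure scaling, dark level, additive read noise, quantization to the
#' sensor bit depth, and interleaving into the 4x4 mosaic.
#'
#' @param R scene reflectance: a spectrum (vector on the bank's grid) for a
#'   spatially uniform scene, or an `height x width x grid` array.
#' @param bank [build_filter_bank()].
#' @param layout [mosaic_layout()].
#' @param height,width frame dimensions (multiples of 4); required when `R`
#'   is a single spectrum.
#' @param texture optional height x width multiplicative field (spatial
#'   albedo variation), applied to the uniform-scene fast path.
#' @param illuminant relative spectral power, scalar or per-wavelength.
#' @param exposure_ms exposure time in ms.
#' @param gain counts per (ms x response unit).
#' @param bit_depth ADC bit depth; full scale is `2^bit_depth - 1`.
#' @param dark_level dark offset in counts.
#' @param noise_sd read-noise standard deviation in counts.
#' @param seed RNG seed for the noise draw.
#' @param quantize round and clip to the ADC range (`FALSE` returns the
#'   real-valued pre-quantization frame, used to check linearity).
#' @param saturation_ceiling fraction of full scale above which pixels are
#'   reported as saturated (warns when any pixel exceeds it).
#' @return a `mosaic_frame`: numeric matrix with attributes `bit_depth`,
#'   `exposure_ms`, `gain`, `dark_level` and `saturation_fraction`.
#' @export
render_frame <- function(R, bank, layout = mosaic_layout(bank$peaks),
                         height = NULL, width = NULL, texture = NULL,
                         illuminant = 1, exposure_ms = 50, gain = 0.5,
                         bit_depth = 10, dark_level = 12, noise_sd = 2,
                         seed = NULL, quantize = TRUE,
                         saturation_ceiling = 0.66) {
  stopifnot(inherits(bank, "filter_bank"), inherits(layout, "mosaic_layout"))
  ng <- length(bank$grid)
  w <- grid_weights(bank$grid) * rep_len(illuminant, ng)
  pat <- layout$pattern
  if (is.null(dim(R))) {
    if (is.null(height) || is.null(width))
      stop("height and width are required for a uniform scene", call. = FALSE)
    if (height %% 4 != 0 || width %% 4 != 0)
      stop("frame height and width must be multiples of 4", call. = FALSE)
    if (length(R) == 1) R <- rep(R, ng)
    if (length(R) != ng)
      stop("scene spectrum must be sampled on the bank's grid", call. = FALSE)
    p <- as.numeric(bank$Q %*% (R * w))                 # 16 responses
    tile <- matrix(p[pat], 4, 4)
    full <- tile[((seq_len(height) - 1) %% 4) + 1,
                 ((seq_len(width) - 1) %% 4) + 1]
    if (!is.null(texture)) {
      if (!all(dim(texture) == c(height, width)))
        stop("texture dimensions must match the frame", call. = FALSE)
      full <- full * texture
    }
  } else {
    dm <- dim(R)
    if (length(dm) != 3 || dm[3] != ng)
      stop("R must be a height x width x grid array", call. = FALSE)
    height <- dm[1]; width <- dm[2]
    if (height %% 4 != 0 || width %% 4 != 0)
      stop("frame height and width must be multiples of 4", call. = FALSE)
    full <- matrix(0, height, width)
    qe <- bank$Q * rep(w, each = nrow(bank$Q))
    for (r in 1:4) for (cc in 1:4) {
      ch <- pat[r, cc]
      rows <- seq(r, height, by = 4)
      cols <- seq(cc, width, by = 4)
      sub <- R[rows, cols, , drop = FALSE]
      full[rows, cols] <- matrix(sub, length(rows) * length(cols), ng) %*%
        qe[ch, ]
    }
    if (!is.null(texture)) full <- full * texture
  }
  counts <- dark_level + gain * exposure_ms * full
  if (noise_sd > 0)
    counts <- counts + with_seed(seed, matrix(
      stats::rnorm(height * width, 0, noise_sd), height, width))
  full_scale <- 2^bit_depth - 1
  if (quantize) counts <- pmin(pmax(round(counts), 0), full_scale)
  frame <- structure(counts, class = "mosaic_frame",
                     bit_depth = bit_depth, exposure_ms = exposure_ms,
                     gain = gain, dark_level = dark_level)
  sat <- check_saturation(frame, ceiling_fraction = saturation_ceiling)
  attr(frame, "saturation_fraction") <- sat$fraction
  if (sat$fraction > 0)
    warning(sprintf("%.2f%% of pixels exceed %d%% of full scale",
                    100 * sat$fraction, round(100 * saturation_ceiling)),
            call. = FALSE)
  frame
}

#' Render dark and white reference frames
#'
#' The dark frame is an exposure with zero incident light (dark level and
#' read noise only); the white frame images a spectrally flat diffuse
#' reflectance standard. A grey 20% standard is the default so that no
#' channel saturates relative to the brighter skin scene.
#'
#' @param bank,layout sensor description, as for [render_frame()].
#' @param height,width frame dimensions.
#' @param standard_reflectance flat reflectance of the standard (fraction).
#' @param seed RNG seed; dark and white draws are decorrelated internally.
#' @param ... further arguments passed to [render_frame()].
#' @return list with elements `dark`, `white` (both `mosaic_frame`) and
#'   `standard_reflectance`.
#' @export
render_references <- function(bank, layout = mosaic_layout(bank$peaks),
                              height = 64, width = 64,
                              standard_reflectance = 0.20, seed = NULL, ...) {
  check_scalar(standard_reflectance, "standard_reflectance", 0, 1,
               open_lower = TRUE)
  dark <- render_frame(0, bank, layout, height = height, width = width,
                       seed = seed, ...)
  white <- render_frame(rep(standard_reflectance, length(bank$grid)),
                        bank, layout, height = height, width = width,
                        seed = if (is.null(seed)) NULL else seed + 1L, ...)
  list(dark = dark, white = white,
       standard_reflectance = standard_reflectance)
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf(
    "<filter_bank> %d channels, %d grid points (%g-%g nm)\n",
    nrow(x$Q), length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf(
    "  peaks %g-%g nm, fwhm %g nm, 2nd-order height %.2f at -%g nm, crosstalk %.2f\n",
    min(x$peaks), max(x$peaks), x$fwhm, x$second_order_height,
    x$second_order_offset, x$crosstalk_strength))
  invisible(x)
}
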