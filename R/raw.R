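new_spectral_cube <- function(data, band_centers, kind) {
  stopifnot(length(dim(data)) == 3, length(band_centers) == dim(data)[3])
  structure(data, class = "spectral_cube", band_centers = band_centers,
            kind = kind)
}

#' Band-center wavelengths of a cube
#' @param cube a `spectral_cube`.
#' @return numeric vector, nm.
#' @export
band_centers <- function(cube) attr(cube, "band_centers")

#' Flat-field (dark/white) correction
#'
#' Per-pixel illumination correction
#' `I = (I_S - I_D) / (I_W - I_D)` against dark and white reference frames.
#' Pixels where the white reference does not exceed the dark reference are
#' masked (`NA`) and counted. With `absolute = TRUE` (default) the result is
#' multiplied by the reflectance of the grey standard so a perfect white
#' object reads 1.0 and values are absolute reflectance-scale responses;
#' with `absolute = FALSE` the standard itself reads 1.0.
#'
#' Negative corrected values (noise) are kept but counted; relative values
#' above 1.5 are counted as suspect. The counts are attached as the
#' `ff_report` attribute and a warning is raised when more than 1% of
#' pixels are masked.
#'
#' @param sample,dark,white mosaic frames of identical dimensions.
#' @param standard_reflectance reflectance of the grey standard used for the
#'   white reference (default 0.20).
#' @param absolute scale to absolute reflectance (default `TRUE`).
#' @return real-valued `mosaic_frame` with attributes `corrected = TRUE` and
#'   `ff_report` (list: `n_masked`, `masked_fraction`, `n_negative`,
#'   `n_suspect`).
#' @export
flat_field_correct <- function(sample, dark, white,
                               standard_reflectance = 0.20,
                               absolute = TRUE) {
  s <- unclass(sample); d <- unclass(dark); w <- unclass(white)
  if (!all(dim(s) == dim(d)) || !all(dim(s) == dim(w)))
    stop("sample, dark and white frames must have identical dimensions",
         call. = FALSE)
  den <- w - d
  bad <- !(den > 0)
  rel <- (s - d) / den
  rel[bad] <- NA_real_
  report <- list(n_masked = sum(bad),
                 masked_fraction = mean(bad),
                 n_negative = sum(rel < 0, na.rm = TRUE),
                 n_suspect = sum(rel > 1.5, na.rm = TRUE))
  if (report$masked_fraction > 0.01)
    warning(sprintf("%.1f%% of pixels masked (white <= dark)",
                    100 * report$masked_fraction), call. = FALSE)
  out <- if (absolute) rel * standard_reflectance else rel
  structure(out, class = "mosaic_frame",
            bit_depth = attr(sample, "bit_depth"),
            corrected = TRUE, absolute = absolute, ff_report = report)
}

#' Rearrange a mosaic frame into a 16-band cube
#'
#' Pure spatial subsampling: band `b` collects the pixels whose tile
#' position maps to channel `b`, so each band has a quarter of the frame's
#' resolution per axis and no interpolation is performed. A full
#' 1088 x 2048 frame yields 16 bands of 272 x 512.
#'
#' @param frame a mosaic frame (height and width multiples of 4).
#' @param layout [mosaic_layout()].
#' @return a `spectral_cube` of dimensions `(H/4, W/4, 16)` with band
#'   centers taken from the layout's peak wavelengths; `kind` is
#'   `"raw-response"`.
#' @export
demosaic_subsample <- function(frame, layout = mosaic_layout()) {
  stopifnot(inherits(layout, "mosaic_layout"))
  m <- unclass(frame)
  h <- nrow(m); w <- ncol(m)
  if (h %% 4 != 0)
    stop(sprintf("frame height (%d) is not a multiple of 4", h), call. = FALSE)
  if (w %% 4 != 0)
    stop(sprintf("frame width (%d) is not a multiple of 4", w), call. = FALSE)
  cube <- array(NA_real_, c(h / 4, w / 4, 16))
  pat <- layout$pattern
  for (r in 1:4) for (cc in 1:4) {
    cube[, , pat[r, cc]] <- m[seq(r, h, by = 4), seq(cc, w, by = 4)]
  }
  new_spectral_cube(cube, layout$peaks, kind = "raw-response")
}

#' Reassemble a mosaic frame from a 16-band cube
#'
#' Exact inverse of [demosaic_subsample()].
#'
#' @param cube a 16-band `spectral_cube`.
#' @param layout [mosaic_layout()].
#' @return numeric matrix of dimensions `(4 * H, 4 * W)`.
#' @export
remosaic <- function(cube, layout = mosaic_layout()) {
  stopifnot(length(dim(cube)) == 3, dim(cube)[3] == 16)
  h <- dim(cube)[1] * 4; w <- dim(cube)[2] * 4
  m <- matrix(NA_real_, h, w)
  pat <- layout$pattern
  for (r in 1:4) for (cc in 1:4) {
    m[seq(r, h, by = 4), seq(cc, w, by = 4)] <- cube[, , pat[r, cc]]
  }
  m
}

#' Report pixels above the sensor's linearity ceiling
#'
#' The sensor is linear up to a fraction of full scale (66% per the
#' manufacturer's guarantee); exposure should be chosen so no pixel exceeds
#' it. Returns the fraction and coordinates of offending pixels.
#'
#' @param frame a mosaic frame.
#' @param ceiling_fraction linearity ceiling as a fraction of full scale.
#' @param bit_depth ADC bit depth; defaults to the frame's attribute.
#' @return a `saturation_report` list: `fraction`, `n`, `threshold`,
#'   `coords` (matrix of row/col indices).
#' @export
check_saturation <- function(frame, ceiling_fraction = 0.66,
                             bit_depth = NULL) {
  check_scalar(ceiling_fraction, "ceiling_fraction", 0, 1,
               open_lower = TRUE)
  bit_depth <- bit_depth %||% attr(frame, "bit_depth") %||% 10
  m <- unclass(frame)
  threshold <- ceiling_fraction * (2^bit_depth - 1)
  idx <- which(m > threshold, arr.ind = TRUE)
  structure(list(fraction = nrow(idx) / length(m), n = nrow(idx),
                 threshold = threshold, coords = idx),
            class = "saturation_report")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%s), %s\n",
              d[1], d[2], d[3],
              paste0(round(range(band_centers(x)), 1), collapse = "-"),
              attr(x, "kind")))
  invisible(x)
}
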