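#' Construct a wavelength grid
#'
#' The common wavelength axis used by filter sensitivities, chromophore
#' extinction spectra and simulated reflectances. The default covers
#' 400--700 nm in 10 nm steps (31 samples), the sampling used when fitting
#' the spectral-correction model.
#'
#' @param from,to grid limits in nm.
#' @param by step in nm.
#' @return numeric vector of strictly increasing wavelengths (nm).
#' @export
#' @examples
#' length(wavelength_grid())  # 31
wavelength_grid <- function(from = 400, to = 700, by = 10) {
  check_scalar(from, "from", 0, open_lower = TRUE)
  check_scalar(by, "by", 0, open_lower = TRUE)
  check_scalar(to, "to", from, open_lower = TRUE)
  seq(from, to, by = by)
}

validate_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L || anyNA(grid) ||
      any(!is.finite(grid)) || any(diff(grid) <= 0))
    stop("wavelength grid must be a strictly increasing finite numeric vector",
         call. = FALSE)
  invisible(grid)
}

# trapezoidal quadrature weights for integration over a (possibly non-uniform) grid
grid_weights <- function(grid) {
  validate_grid(grid)
  d <- diff(grid)
  c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
}

#' Chromophore extinction library
#'
#' Molar extinction coefficients (per mM per cm) of the tissue chromophores
#' used by the forward model and the delta-concentration estimator. The
#' packaged default table (`hb_extinction_synthetic.csv`) is a synthetic
#' approximation of compiled hemoglobin spectra: it reproduces the standard
#' band structure (oxyhemoglobin double peak near 540/577 nm, deoxyhemoglobin
#' peak near 555 nm, isosbestic behaviour near 500/530 nm, steep
#' oxyhemoglobin fall-off past 590 nm) and can be replaced by any
#' user-supplied table with the same layout.
#'
#' @param table data.frame with a `wavelength_nm` column and one column per
#'   chromophore (at least `O2Hb` and `HHb`), or `NULL` for the packaged
#'   default.
#' @param grid optional wavelength grid (nm) onto which the table is linearly
#'   interpolated; must lie within the table's coverage.
#' @return object of class `chromophore_library` with elements `grid`
#'   (wavelengths, nm) and `extinction` (wavelengths x chromophores matrix).
#' @export
#' @examples
#' lib <- chromophore_library()
#' extinction_at(lib, c(515, 565, 601))
chromophore_library <- function(table = NULL, grid = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "hb_extinction_synthetic.csv",
                        package = "sfaox", mustWork = TRUE)
    table <- utils::read.csv(path)
  }
  if (!is.data.frame(table) || !"wavelength_nm" %in% names(table))
    stop("extinction table must contain a 'wavelength_nm' column", call. = FALSE)
  chroms <- setdiff(names(table), "wavelength_nm")
  if (!all(c("O2Hb", "HHb") %in% chroms))
    stop("extinction table must contain 'O2Hb' and 'HHb' columns", call. = FALSE)
  wl <- table$wavelength_nm
  validate_grid(wl)
  ext <- as.matrix(table[chroms])
  if (any(!is.finite(ext)) || any(ext < 0))
    stop("extinction values must be finite and non-negative", call. = FALSE)
  if (!is.null(grid)) {
    validate_grid(grid)
    if (min(grid) < min(wl) || max(grid) > max(wl))
      stop("requested grid extends beyond the extinction table's coverage",
           call. = FALSE)
    ext <- apply(ext, 2, function(y) stats::approx(wl, y, xout = grid)$y)
    wl <- grid
  }
  structure(list(grid = wl, extinction = ext), class = "chromophore_library")
}

#' Extinction coefficients at arbitrary wavelengths
#'
#' Linear interpolation of the library onto the requested wavelengths.
#'
#' @param lib a [chromophore_library()].
#' @param wavelengths numeric vector, nm.
#' @param chromophores columns to extract (default oxy- and deoxy-hemoglobin).
#' @return matrix `length(wavelengths)` x `length(chromophores)`, in
#'   mM^-1 cm^-1.
#' @export
extinction_at <- function(lib, wavelengths,
                          chromophores = c("O2Hb", "HHb")) {
  stopifnot(inherits(lib, "chromophore_library"))
  if (any(wavelengths < min(lib$grid) | wavelengths > max(lib$grid)))
    stop("wavelength outside the library's coverage", call. = FALSE)
  miss <- setdiff(chromophores, colnames(lib$extinction))
  if (length(miss))
    stop("unknown chromophore(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- vapply(chromophores, function(ch)
    stats::approx(lib$grid, lib$extinction[, ch], xout = wavelengths)$y,
    numeric(length(wavelengths)))
  out <- matrix(out, nrow = length(wavelengths),
                dimnames = list(NULL, chromophores))
  out
}

# melanin absorbance offset: standard power-law shape, scaled so that
# `scale` is the absorbance contributed at 694 nm
melanin_absorbance <- function(grid, scale = 0) {
  if (scale == 0) return(rep(0, length(grid)))
  scale * (grid / 694)^(-3.46)
}
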