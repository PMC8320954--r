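#' Default virtual band centers
#'
#' Centers of the virtual narrow bands produced by the spectral correction:
#' uniformly spaced over the sensor's active range, bracketing the three key
#' oximetry wavelengths (515, 565 and 601 nm).
#'
#' @param m number of virtual bands (default 10).
#' @param range active range in nm.
#' @return numeric vector of `m` wavelengths.
#' @export
default_band_centers <- function(m = 10, range = c(470, 630)) {
  seq(range[1], range[2], length.out = m)
}

# basis factory: returns a function evaluating the m basis functions at
# arbitrary wavelengths (rows = wavelengths, cols = basis functions)
make_basis <- function(type = c("bspline", "gaussian", "box", "pca"),
                       grid, centers, width = NULL, training = NULL) {
  type <- match.arg(type)
  spacing <- if (length(centers) > 1) mean(diff(sort(centers))) else 20
  m <- length(centers)
  if (type == "bspline") {
    # cubic B-splines over the active band: a partition of unity (flat
    # spectra are exact) with good smooth-approximation power; zero outside
    # the band, where the camera carries no information
    rng <- range(centers)
    obj <- splines::bs(seq(rng[1], rng[2], length.out = 50), df = m,
                       degree = 3, intercept = TRUE, Boundary.knots = rng)
    return(function(wl) {
      out <- matrix(0, length(wl), m)
      ok <- wl >= rng[1] & wl <= rng[2]
      if (any(ok)) out[ok, ] <- stats::predict(obj, wl[ok])
      out
    })
  }
  if (type == "gaussian") {
    # wider than the band spacing so flat spectra are representable
    # without comb ripple between the bumps
    sd <- width %||% (0.65 * spacing)
    function(wl) outer(wl, centers, function(l, c) exp(-0.5 * ((l - c) / sd)^2))
  } else if (type == "box") {
    half <- (width %||% spacing) / 2
    function(wl) outer(wl, centers,
                       function(l, c) as.numeric(abs(l - c) <= half))
  } else {
    if (is.null(training))
      stop("PCA basis requires training reflectances", call. = FALSE)
    U <- svd(t(training))$u[, seq_along(centers), drop = FALSE]  # grid x m
    function(wl) apply(U, 2, function(u) stats::approx(grid, u, xout = wl,
                                                       rule = 2)$y)
  }
}

#' Synthetic color-chart-like training patches
#'
#' Smooth reflectance spectra spanning a wide range of spectral shapes, in
#' the spirit of a 24-patch color checker: a greyscale series plus randomly
#' generated smooth spectra (baseline + ramp + one to three Gaussian bumps),
#' clamped to (0, 1). Deterministic for a given seed.
#'
#' @param n number of patches (default 24).
#' @param grid wavelength grid (nm).
#' @param seed RNG seed.
#' @param n_grey number of flat grey patches included first.
#' @return `n` x `length(grid)` matrix of reflectances, patches in rows.
#' @export
synthetic_training_patches <- function(n = 24, grid = wavelength_grid(),
                                       seed = 1, n_grey = 6) {
  validate_grid(grid)
  stopifnot(n >= n_grey, n_grey >= 0)
  span <- diff(range(grid))
  with_seed(seed, {
    grey <- if (n_grey > 0)
      outer(seq(0.05, 0.9, length.out = n_grey), rep(1, length(grid)))
    else NULL
    if (n == n_grey) return(grey)
    rand <- t(replicate(n - n_grey, {
      r <- stats::runif(1, 0.05, 0.55) +
        stats::runif(1, -0.3, 0.3) * (grid - min(grid)) / span
      for (j in seq_len(sample(1:3, 1))) {
        r <- r + stats::runif(1, -0.4, 0.5) *
          exp(-0.5 * ((grid - stats::runif(1, min(grid), max(grid))) /
                        stats::runif(1, 15, 60))^2)
      }
      pmin(pmax(r, 0.02), 0.98)
    }))
    rbind(grey, rand)
  })
}

#' Fit the spectral-correction model
#'
#' Solves for the linear map from raw channel responses to virtual
#' narrow-band reflectance samples. Reflectances are modelled as smooth
#' linear combinations of `m` basis functions, `r ~ B w`, and the joint
#' (optionally ridge-regularized) least-squares problem
#' `min_M sum_p || B M p - r_p ||^2` over the training patches yields the
#' weight map `M`. The applied correction matrix is `M_eff = B(centers) M`,
#' which evaluates the reconstructed spectrum at the virtual band centers,
#' reducing the 16 imperfect channels to `m` (default 10) virtual narrow
#' bands.
#'
#' Training responses must be illumination-corrected (flat-field) channel
#' responses, i.e. sensitivity-weighted mean reflectances as produced by
#' [channel_responses()] with `normalize = TRUE` or by the flat-field stage
#' of the pipeline.
#'
#' @param responses k x 16 matrix of training channel responses.
#' @param reflectances k x grid matrix of the corresponding known
#'   reflectance spectra.
#' @param grid wavelength grid of the reflectances (nm).
#' @param m number of virtual bands.
#' @param centers virtual band centers (nm).
#' @param basis basis family: `"bspline"` (default: cubic B-splines over
#'   the active band), `"gaussian"`, `"box"` or `"pca"`.
#' @param basis_width optional basis width (nm); defaults to 0.65 x band
#'   spacing for the Gaussian basis.
#' @param ridge ridge penalty, as a fraction of the mean diagonal of the
#'   response Gram matrix (scale-free, so duplicating the training set
#'   leaves the fit unchanged).
#' @param bank optional [build_filter_bank()] on the same grid. When given,
#'   a secondary penalty steers the fit -- within the near-null space of
#'   the response data, which leaves reconstruction accuracy essentially
#'   untouched -- toward effective sensitivities `M_eff Q` that resemble
#'   ideal narrow bands at the virtual centers, so the corrected system
#'   also *looks* like the idealized narrow-band camera it emulates.
#' @param target_weight weight of the sensitivity-localization penalty
#'   relative to the per-patch data term; 0 disables it.
#' @return a `correction_model`: list with `M` (m x 16 weight map), `M_eff`
#'   (m x 16 applied correction matrix), `B` (grid x m basis), `centers`,
#'   `grid`, `ridge` and `training_rmse` (per-patch spectral residual).
#' @export
fit_correction <- function(responses, reflectances, grid = wavelength_grid(),
                           m = 10, centers = default_band_centers(m),
                           basis = c("bspline", "gaussian", "box", "pca"),
                           basis_width = NULL, ridge = 1e-6,
                           bank = NULL, target_weight = 0.005) {
  responses <- as.matrix(responses)
  reflectances <- as.matrix(reflectances)
  validate_grid(grid)
  k <- nrow(responses)
  if (nrow(reflectances) != k)
    stop("responses and reflectances must describe the same patches",
         call. = FALSE)
  if (ncol(reflectances) != length(grid))
    stop("reflectances must be sampled on 'grid'", call. = FALSE)
  if (length(centers) != m) m <- length(centers)
  if (k < m)
    stop("need at least as many training patches as virtual bands",
         call. = FALSE)
  P <- t(responses)                                   # nch x k
  nch <- nrow(P)
  if (qr(P)$rank < m)
    stop(paste("training responses are rank deficient: use fewer virtual",
               "bands or more (more diverse) training patches"),
         call. = FALSE)
  bfun <- make_basis(match.arg(basis), grid, centers, width = basis_width,
                     training = reflectances)
  B <- bfun(grid)                                     # grid x m
  Rm <- t(reflectances)                               # grid x k
  Bc <- bfun(centers)                                 # m x m
  G <- crossprod(B)
  # data terms averaged over patches, so duplicating the training set
  # leaves the solution unchanged
  PPk <- tcrossprod(P) / k
  D1 <- crossprod(B, Rm) %*% t(P) / k
  lam <- ridge * mean(diag(PPk))
  if (is.null(bank) || target_weight <= 0) {
    M <- solve(G + 1e-12 * mean(diag(G)) * diag(m), D1) %*%
      solve(PPk + lam * diag(nch))
  } else {
    if (!isTRUE(all.equal(bank$grid, grid)))
      stop("bank and training grid differ", call. = FALSE)
    gw <- grid_weights(grid)
    Qn <- bank$Q * rep(gw, each = nch)
    Qn <- Qn / rowSums(Qn)                            # unit-integral rows
    sp <- if (m > 1) mean(diff(sort(centers))) else 20
    Tg <- t(vapply(centers, function(cc) {
      g <- exp(-0.5 * ((grid - cc) / (sp / 2.355))^2)
      g / sum(g)
    }, numeric(length(grid))))                        # ideal narrow targets
    A <- kronecker(PPk + lam * diag(nch), G) +
      target_weight * kronecker(tcrossprod(Qn), crossprod(Bc)) +
      1e-12 * mean(diag(G)) * diag(m * nch)
    rhs <- as.numeric(D1 + target_weight * crossprod(Bc, Tg) %*% t(Qn))
    M <- matrix(solve(A, rhs), m, nch)
  }
  M_eff <- Bc %*% M
  recon <- B %*% (M %*% P)
  # residual over the active band only: the camera carries no information
  # outside the span of the virtual bands, so out-of-band reflectance is
  # unrecoverable by construction and would swamp the diagnostic
  sp <- if (length(centers) > 1) mean(diff(sort(centers))) else 20
  in_band <- grid >= min(centers) - sp / 2 & grid <= max(centers) + sp / 2
  rmse <- sqrt(colMeans((recon - Rm)[in_band, , drop = FALSE]^2))
  structure(list(M = M, M_eff = M_eff, B = B, centers = centers, grid = grid,
                 basis = match.arg(basis), ridge = ridge,
                 n_channels = nch, training_rmse = rmse),
            class = "correction_model")
}

#' Identity (no-op) correction model
#'
#' Passes the 16 raw channels through unchanged, with band centers at the
#' channel peak wavelengths. Used as the fallback when no fitted correction
#' model is available ("spectrally uncorrected" processing).
#'
#' @param peaks channel peak wavelengths (nm).
#' @return a `correction_model` with `M_eff = I`.
#' @export
identity_correction <- function(peaks = default_peak_wavelengths()) {
  n <- length(peaks)
  structure(list(M = diag(n), M_eff = diag(n), B = NULL, centers = peaks,
                 grid = NULL, basis = "identity", ridge = 0,
                 n_channels = n, training_rmse = NULL),
            class = "correction_model")
}

#' Apply a correction model to a 16-band cube
#'
#' Per-pixel matrix product with the correction matrix, turning raw channel
#' responses into an m-band virtual narrow-band reflectance cube.
#'
#' @param model a `correction_model`.
#' @param cube a `spectral_cube` of kind `"raw-response"` with
#'   `model$n_channels` bands.
#' @return a `spectral_cube` with `length(model$centers)` bands and kind
#'   `"reflectance"`.
#' @export
apply_correction <- function(model, cube) {
  stopifnot(inherits(model, "correction_model"))
  d <- dim(cube)
  if (length(d) != 3 || d[3] != model$n_channels)
    stop(sprintf("cube has %d bands but the model expects %d",
                 d[3], model$n_channels), call. = FALSE)
  vals <- matrix(unclass(cube), d[1] * d[2], d[3]) %*% t(model$M_eff)
  new_spectral_cube(array(vals, c(d[1], d[2], length(model$centers))),
                    model$centers, kind = "reflectance")
}

#' Corrected reflectance samples for response vectors
#'
#' Applies the correction matrix to plain response vectors (one patch per
#' row) instead of an image cube.
#'
#' @param model a `correction_model`.
#' @param responses k x 16 matrix or a 16-vector.
#' @return k x m matrix (or m-vector) of virtual narrow-band reflectances.
#' @export
correct_responses <- function(model, responses) {
  single <- is.null(dim(responses))
  P <- if (single) matrix(responses, nrow = 1) else as.matrix(responses)
  out <- P %*% t(model$M_eff)
  if (single) drop(out) else out
}

#' Reconstruct full spectra from responses
#'
#' Returns the basis-expanded reconstruction `B M p` on the model's grid.
#'
#' @inheritParams correct_responses
#' @return k x grid matrix (or grid-vector) of reconstructed reflectance.
#' @export
reconstruct_spectra <- function(model, responses) {
  if (is.null(model$B))
    stop("identity models carry no reconstruction basis", call. = FALSE)
  single <- is.null(dim(responses))
  P <- if (single) matrix(responses, nrow = 1) else as.matrix(responses)
  out <- t(model$B %*% (model$M %*% t(P)))
  if (single) drop(out) else out
}

#' Effective (corrected) virtual sensitivities
#'
#' The corrected system's virtual sensitivities `M_eff %*% Q`, for
#' inspection of how well the correction suppresses second-order lobes and
#' crosstalk, together with the fraction of absolute sensitivity energy
#' outside a window around each band center (and, for comparison, around
#' each raw channel's peak).
#'
#' @param model a `correction_model`.
#' @param bank the [build_filter_bank()] whose grid matches the model's.
#' @param window half-width of the in-band window (nm); defaults to the
#'   virtual band spacing.
#' @return list: `S` (m x grid corrected sensitivities), `grid`, `centers`,
#'   `oob_corrected`, `oob_raw` (per-band out-of-window energy fractions).
#' @export
effective_sensitivities <- function(model, bank, window = NULL) {
  stopifnot(inherits(model, "correction_model"), inherits(bank, "filter_bank"))
  if (!is.null(model$grid) && !isTRUE(all.equal(model$grid, bank$grid)))
    stop("model and bank wavelength grids differ", call. = FALSE)
  S <- model$M_eff %*% bank$Q
  grid <- bank$grid
  window <- window %||%
    (if (length(model$centers) > 1) mean(diff(sort(model$centers))) else 20)
  oob <- function(row, center) {
    e <- abs(row) * grid_weights(grid)
    1 - sum(e[abs(grid - center) <= window]) / sum(e)
  }
  oob_corrected <- vapply(seq_along(model$centers),
                          function(i) oob(S[i, ], model$centers[i]), 0)
  oob_raw <- vapply(seq_along(bank$peaks),
                    function(i) oob(bank$Q[i, ], bank$peaks[i]), 0)
  list(S = S, grid = grid, centers = model$centers,
       oob_corrected = oob_corrected, oob_raw = oob_raw)
}

#' Serialize a correction model to JSON
#' @param model a `correction_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correction_model <- function(model, path) {
  stopifnot(inherits(model, "correction_model"))
  payload <- list(M = model$M, M_eff = model$M_eff, B = model$B,
                  centers = model$centers, grid = model$grid,
                  basis = model$basis, ridge = model$ridge,
                  n_channels = model$n_channels,
                  training_rmse = model$training_rmse)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a correction model from JSON
#' @param path file written by [write_correction_model()].
#' @return a `correction_model`.
#' @export
read_correction_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(M = as.matrix(x$M), M_eff = as.matrix(x$M_eff),
                 B = if (is.null(x$B)) NULL else as.matrix(x$B),
                 centers = as.numeric(x$centers),
                 grid = if (is.null(x$grid)) NULL else as.numeric(x$grid),
                 basis = x$basis, ridge = x$ridge,
                 n_channels = as.integer(x$n_channels),
                 training_rmse = if (is.null(x$training_rmse)) NULL
                 else as.numeric(x$training_rmse)),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> %d channels -> %d virtual bands (%s basis)\n",
              x$n_channels, length(x$centers), x$basis))
  if (!is.null(x$training_rmse))
    cat(sprintf("  training spectral RMSE: mean %.2e, max %.2e\n",
                mean(x$training_rmse), max(x$training_rmse)))
  invisible(x)
}
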