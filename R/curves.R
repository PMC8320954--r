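#' Feature scaling normalization
#'
#' `X' = (X - min X) / (max X - min X)`, mapping any non-constant curve onto
#' \[0, 1\] with both bounds attained. Used to bring the camera's relative
#' oxygenation proxy and the reference oximeter's absolute readings onto a
#' common amplitude scale before shape comparison.
#'
#' @param x numeric vector (NAs ignored for the range but preserved).
#' @return normalized vector.
#' @export
#' @examples
#' feature_scale(c(2, 4, 6))  # 0 0.5 1
feature_scale <- function(x) {
  stopifnot(is.numeric(x))
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("feature scaling is undefined for a constant curve", call. = FALSE)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Centered moving average
#'
#' Mean over a centered window of odd length; at the boundaries the window
#' shrinks so the output has the same length as the input (needed so the
#' smoothed curve stays alignable sample-for-sample).
#'
#' @param x numeric vector.
#' @param window odd window length, `>= 1` and at most `length(x)`.
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(x, window = 3) {
  stopifnot(is.numeric(x))
  check_scalar(window, "window", 1)
  window <- as.integer(window)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  n <- length(x)
  if (window > n) stop("window exceeds the curve length", call. = FALSE)
  if (window == 1) return(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), 0)
}

find_minimum <- function(value, window = NULL) {
  idx <- if (is.null(window)) seq_along(value)
  else window[1]:window[2]
  mn <- min(value[idx])
  hits <- idx[which(value[idx] == mn)]
  if (length(hits) > 1)
    warning("tied minima; earliest sample used", call. = FALSE)
  hits[1]
}

#' Align two curves at their minima
#'
#' Shifts both time axes so the minimum of each curve (the cuff-release
#' marker in an occlusion recording) sits at `t = 0`, then interpolates the
#' reference onto the test curve's sampling over the overlapping time range.
#' Tied minima are broken to the earliest sample with a warning.
#'
#' @param test,reference curves: data.frames with time and value columns
#'   (or `oxy_curve` / `reference_trace` objects).
#' @param test_window,ref_window optional index ranges `c(first, last)`
#'   restricting the minimum search (e.g. around a marked release).
#' @return an `aligned_pair`: list with `time` (common axis, 0 at the
#'   minima), `test`, `reference` (values on that axis), `shift` (seconds
#'   the reference was moved), `release_index` (index of `t = 0`).
#' @export
align_at_minimum <- function(test, reference, test_window = NULL,
                             ref_window = NULL) {
  a <- as_curve(test)
  b <- as_curve(reference)
  ia <- find_minimum(a$value, test_window)
  ib <- find_minimum(b$value, ref_window)
  ta <- a$time - a$time[ia]
  tb <- b$time - b$time[ib]
  lo <- max(min(ta), min(tb))
  hi <- min(max(ta), max(tb))
  keep <- which(ta >= lo & ta <= hi)
  if (!length(keep)) stop("aligned curves do not overlap", call. = FALSE)
  ref_i <- stats::approx(tb, b$value, xout = ta[keep])$y
  structure(list(time = ta[keep], test = a$value[keep], reference = ref_i,
                 shift = b$time[ib] - a$time[ia],
                 release_index = which(ta[keep] == 0)[1]),
            class = "aligned_pair")
}

#' Curve agreement metrics: RMSE and GFC
#'
#' Root mean square pointwise difference and the goodness-of-fit
#' coefficient, the normalized absolute inner product
#' `|sum(a b)| / (sqrt(sum a^2) sqrt(sum b^2))` (1 for identical shapes,
#' 0 for orthogonal curves). Both are symmetric in the pair. Curves are
#' expected to be feature-scaled onto a common axis, as produced by
#' [align_at_minimum()].
#'
#' @param a an `aligned_pair`, or a numeric vector.
#' @param b numeric vector (when `a` is a vector).
#' @return list with elements `rmse` and `gfc`.
#' @export
#' @examples
#' agreement_metrics(c(1, 0), c(0, 1))$gfc  # 0
agreement_metrics <- function(a, b = NULL) {
  if (inherits(a, "aligned_pair")) {
    b <- a$reference
    a <- a$test
  }
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) stop("no overlapping finite samples", call. = FALSE)
  a <- a[ok]; b <- b[ok]
  list(rmse = sqrt(mean((a - b)^2)),
       gfc = abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2))))
}

#' Fit de-/re-saturation slopes of an occlusion curve
#'
#' Least-squares lines through the desaturation segment (baseline marker to
#' the curve minimum) and the resaturation segment (minimum to the highest
#' point inside a post-release window), plus the time `dt` from release to
#' that post-release maximum.
#'
#' @param curve a curve (data.frame with time and value, or `oxy_curve`).
#' @param baseline_index sample index of the marked baseline end /
#'   occlusion start; must precede the minimum.
#' @param max_window seconds after the minimum within which the
#'   post-release maximum is sought (default 60).
#' @return a `slope_report`: list with `desaturation_slope`,
#'   `resaturation_slope` (units/s), `dt` (s), `min_index`, `max_index`,
#'   and per-segment residual RMSEs.
#' @export
fit_slopes <- function(curve, baseline_index = 1, max_window = 60) {
  cv <- as_curve(curve)
  n <- nrow(cv)
  check_scalar(baseline_index, "baseline_index", 1, n)
  baseline_index <- as.integer(baseline_index)
  imin <- baseline_index - 1L +
    find_minimum(cv$value[baseline_index:n])
  if (imin <= baseline_index)
    stop("baseline marker must precede the curve minimum", call. = FALSE)
  post <- which(cv$time > cv$time[imin] &
                  cv$time <= cv$time[imin] + max_window)
  if (!length(post))
    stop("max_window excludes every post-minimum sample", call. = FALSE)
  imax <- post[which.max(cv$value[post])]
  seg_fit <- function(idx) {
    fit <- stats::lm(value ~ time, data = cv[idx, ])
    list(slope = unname(stats::coef(fit)[2]),
         rmse = sqrt(mean(stats::residuals(fit)^2)))
  }
  de <- seg_fit(baseline_index:imin)
  re <- seg_fit(imin:imax)
  structure(list(desaturation_slope = de$slope,
                 resaturation_slope = re$slope,
                 dt = cv$time[imax] - cv$time[imin],
                 min_index = imin, max_index = imax,
                 desaturation_rmse = de$rmse, resaturation_rmse = re$rmse),
            class = "slope_report")
}

#' @export
print.slope_report <- function(x, ...) {
  cat(sprintf(
    "<slope_report> desat %.4g/s, resat %.4g/s, dt %.1f s\n",
    x$desaturation_slope, x$resaturation_slope, x$dt))
  invisible(x)
}

#' Cohort-level Pearson correlation of slopes
#'
#' Sample correlation between paired de-saturation (and optionally
#' re-saturation) slopes from two measurement systems, one pair per
#' subject/run.
#'
#' @param desat two-column matrix or data.frame of paired desaturation
#'   slopes.
#' @param resat optional two-column matrix of paired resaturation slopes.
#' @return list with `desaturation_r`, `resaturation_r` (or `NULL`), `n`,
#'   and the input pairs (`desat`, `resat`) for scatter plotting.
#' @export
cohort_correlation <- function(desat, resat = NULL) {
  pearson <- function(p, what) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2)
    if (nrow(p) < 3)
      stop("need at least 3 slope pairs", call. = FALSE)
    if (stats::sd(p[, 1]) == 0 || stats::sd(p[, 2]) == 0)
      stop(sprintf("zero variance in %s slopes", what), call. = FALSE)
    stats::cor(p[, 1], p[, 2])
  }
  list(desaturation_r = pearson(desat, "desaturation"),
       resaturation_r = if (is.null(resat)) NULL
       else pearson(resat, "resaturation"),
       n = nrow(as.matrix(desat)), desat = desat, resat = resat)
}

#' Compare a test curve with a reference curve
#'
#' The full shape-comparison recipe: smooth the (faster-sampled) test curve
#' with a centered moving average, align both curves at their minima,
#' interpolate the reference onto the test sampling, feature-scale both over
#' the overlap, and compute RMSE/GFC.
#'
#' @param test,reference curves (see [align_at_minimum()]).
#' @param smooth_window moving-average window for the test curve (default
#'   3; 1 disables smoothing).
#' @param test_window,ref_window optional minimum-search windows.
#' @return list with `pair` (the feature-scaled `aligned_pair`), `rmse`,
#'   `gfc`.
#' @export
compare_curves <- function(test, reference, smooth_window = 3,
                           test_window = NULL, ref_window = NULL) {
  tv <- as_curve(test)
  tv$value <- moving_average(tv$value, smooth_window)
  pair <- align_at_minimum(tv, reference, test_window, ref_window)
  pair$test <- feature_scale(pair$test)
  pair$reference <- feature_scale(pair$reference)
  m <- agreement_metrics(pair)
  list(pair = pair, rmse = m$rmse, gfc = m$gfc)
}
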