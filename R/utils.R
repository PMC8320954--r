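`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded operations are reproducible without perturbing the global
#' random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed single integer seed, or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# scalar validator: finite, within [lower, upper] (open bounds optional)
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_l <- if (open_lower) x > lower else x >= lower
  ok_u <- if (open_upper) x < upper else x <= upper
  if (!ok_l || !ok_u)
    stop(sprintf("'%s' = %g is outside its valid range", name, x),
         call. = FALSE)
  invisible(x)
}

# coerce assorted curve containers to a two-column data.frame(time, value)
as_curve <- function(x, value_col = NULL) {
  if (inherits(x, "oxy_curve")) {
    return(data.frame(time = x$time_s, value = x[[value_col %||% "proxy"]]))
  }
  if (inherits(x, "reference_trace") || inherits(x, "oxy_truth")) {
    return(data.frame(time = x$time_s, value = x$StO2_frac))
  }
  if (is.data.frame(x)) {
    tc <- intersect(c("time", "time_s"), names(x))[1]
    preferred <- intersect(c("proxy", "StO2_frac", "value"), names(x))
    vc <- value_col %||%
      (if (length(preferred)) preferred[1]
       else setdiff(names(x), c(tc, "event"))[1])
    if (is.na(tc) || is.null(vc))
      stop("cannot interpret data.frame as a curve; need time and value columns",
           call. = FALSE)
    return(data.frame(time = x[[tc]], value = x[[vc]]))
  }
  if (is.numeric(x)) return(data.frame(time = seq_along(x) - 1, value = x))
  stop("unsupported curve input", call. = FALSE)
}
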