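## Internal numerical helpers shared across modules.

# stop() with a condition class so callers can distinguish parameter errors,
# fit errors, analysis errors etc. programmatically.
sb_stop <- function(class, msg, ..., data = list()) {
  cond <- structure(
    class = c(class, "salivabench_error", "error", "condition"),
    c(list(message = sprintf(msg, ...), call = sys.call(-1)), data)
  )
  stop(cond)
}

stop_param    <- function(msg, ...) sb_stop("salivabench_parameter_error", msg, ...)
stop_domain   <- function(msg, ...) sb_stop("salivabench_domain_error", msg, ...)
stop_fit      <- function(msg, ..., data = list())
  sb_stop("salivabench_fit_error", msg, ..., data = data)
stop_analysis <- function(msg, ...) sb_stop("salivabench_analysis_error", msg, ...)
stop_io       <- function(msg, ...) sb_stop("salivabench_io_error", msg, ...)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_param("'%s' must be a single number", name)
  if (finite && !is.finite(x)) stop_param("'%s' must be finite", name)
  if (positive && x <= 0) stop_param("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_param("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Log-log linear interpolation with strict in-range queries.
# Returns exact node values at nodes; errors rather than extrapolating.
loglog_interp <- function(x, y, xout, what = "value") {
  if (any(xout < min(x)) || any(xout > max(x)))
    sb_stop("salivabench_extrapolation_error",
            "%s query %g outside data range [%g, %g]; refusing to extrapolate",
            what, xout[which(xout < min(x) | xout > max(x))[1L]], min(x), max(x))
  hit <- match(xout, x)
  out <- exp(stats::approx(log(x), log(y), xout = log(xout), ties = "ordered")$y)
  out[!is.na(hit)] <- y[hit[!is.na(hit)]]
  out
}

# Local weighted polynomial smoother/differentiator.
#
# For each point i, fits a degree-`degree` polynomial in (x - x[i]) to the
# points of a centered window (clamped at the ends of the series; points with
# mask == FALSE are dropped from every window) and returns the fitted value
# and first derivative at x[i]. Handles non-uniform grids.
local_poly_smooth <- function(x, y, span_frac = 0.05, min_pts = 5L,
                              degree = 2L, mask = NULL) {
  n <- length(x)
  if (n < 3L) stop_analysis("need at least 3 points for local smoothing")
  if (is.null(mask)) mask <- rep(TRUE, n)
  w <- max(min_pts, ceiling(span_frac * n))
  w <- min(w, n)
  half <- (w - 1L) %/% 2L
  value <- deriv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    # keep the window width at the ends by extending inward
    if (hi - lo + 1L < w) {
      if (lo == 1L) hi <- min(n, lo + w - 1L) else lo <- max(1L, hi - w + 1L)
    }
    idx <- lo:hi
    idx <- idx[mask[idx]]
    deg <- min(degree, length(idx) - 1L)
    if (deg < 1L) next
    xc <- x[idx] - x[i]
    X <- outer(xc, 0:deg, `^`)
    cf <- tryCatch(qr.coef(qr(X), y[idx]), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    value[i] <- cf[1L]
    deriv[i] <- cf[2L]
  }
  list(value = value, deriv = deriv, window = w)
}

# Longest initial run of values above a fraction of the starting value
# (plateau detection for thinning traces). Returns the index of the last
# plateau point (0 if none).
initial_plateau_end <- function(d, frac = 0.95) {
  below <- which(d < frac * d[1L])
  if (!length(below)) length(d) else below[1L] - 1L
}

# Indices where the diameter locally rises by more than `tol` relative to the
# previous sample inside a thinning window: beads-on-a-string artifacts.
beads_mask <- function(d, tol = 0.05) {
  n <- length(d)
  bad <- rep(FALSE, n)
  if (n >= 2L) bad[-1L] <- diff(d) / d[-n] > tol
  bad
}

geomspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

# Multiplicative lognormal noise with coefficient of variation `cv`
# (mean exactly 1 for every cv).
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

rms <- function(x) sqrt(mean(x^2))
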