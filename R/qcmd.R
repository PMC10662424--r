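## QCM-D adsorption/desorption analysis: phase segmentation, plateau
## estimation, saturation time and desorption extent (the "in vitro
## coating index"). Sign convention: adsorption makes the resonance
## frequency shift negative; summaries report magnitudes |delta f|.

#' QCM-D resonance-frequency trace
#'
#' @param time strictly increasing times, s.
#' @param delta_f resonance-frequency shifts, Hz (negative on
#'   adsorption).
#' @param injection_time s, sample injection marker.
#' @param rinse_time s, buffer-rinse marker (must exceed
#'   `injection_time`; both must lie within the trace span).
#' @return An object of class `qcmd_trace`.
#' @export
qcmd_trace <- function(time, delta_f, injection_time, rinse_time) {
  if (length(time) != length(delta_f) || length(time) < 3L)
    stop_param("time and delta_f must have equal length >= 3")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop_param("time must be finite and strictly increasing")
  if (any(!is.finite(delta_f))) stop_param("delta_f must be finite")
  check_number(injection_time, "injection_time", nonneg = TRUE)
  check_number(rinse_time, "rinse_time", positive = TRUE)
  if (rinse_time <= injection_time)
    stop_param("rinse_time (%g) must exceed injection_time (%g)",
               rinse_time, injection_time)
  if (injection_time < time[1L] || rinse_time > time[length(time)])
    stop_param("injection and rinse markers must lie within the trace span")
  structure(list(time = as.numeric(time), delta_f = as.numeric(delta_f),
                 injection_time = injection_time, rinse_time = rinse_time),
            class = "qcmd_trace")
}

#' @export
print.qcmd_trace <- function(x, ...) {
  cat(sprintf(paste0("<qcmd_trace> %d points over %.0f s (injection %.0f s, ",
                     "rinse %.0f s)\n"),
              length(x$time), diff(range(x$time)), x$injection_time,
              x$rinse_time))
  invisible(x)
}

#' Pre- and post-rinse plateau frequency shifts
#'
#' Plateaus are estimated as medians over trailing 10% windows (robust to
#' drift and spikes): `delta_f_before` over the last 10% of the
#' adsorption phase, `delta_f_after` over the last 10% of the full trace.
#' Magnitudes are returned.
#'
#' @param trace a [qcmd_trace()] with at least 20 samples in each window.
#' @return named numeric vector `c(delta_f_before, delta_f_after)`, Hz.
#' @export
plateau_frequencies <- function(trace) {
  if (!inherits(trace, "qcmd_trace"))
    stop_param("trace must be a qcmd_trace")
  t <- trace$time
  pre <- t >= trace$rinse_time - 0.1 * (trace$rinse_time -
                                          trace$injection_time) &
    t < trace$rinse_time
  post <- t >= t[length(t)] - 0.1 * diff(range(t))
  if (sum(pre) < 20L || sum(post) < 20L)
    stop_analysis("plateau windows hold %d/%d samples; need >= 20 in each",
                  sum(pre), sum(post))
  c(delta_f_before = abs(stats::median(trace$delta_f[pre])),
    delta_f_after = abs(stats::median(trace$delta_f[post])))
}

#' Time to adsorption saturation
#'
#' The saturation time is the first time after injection at which
#' \eqn{|\Delta f|} exceeds `fraction` of the pre-rinse plateau and stays
#' above it until the rinse, reported relative to the injection. The
#' trace is lightly median-smoothed (window `smooth`) before
#' thresholding, since the 2% headroom of the criterion is comparable to
#' raw counter noise. For noiseless exponential adsorption with time
#' constant \eqn{\tau} the result is \eqn{\tau\ln(1/(1-fraction))}
#' (about 3.912 tau at the default 98%).
#'
#' @param trace a [qcmd_trace()].
#' @param fraction saturation criterion (default 0.98).
#' @param smooth running-median window in samples (odd; default 31,
#'   truncated to the adsorption phase length).
#' @return saturation time in s (from injection).
#' @export
saturation_time <- function(trace, fraction = 0.98, smooth = 31L) {
  if (!inherits(trace, "qcmd_trace"))
    stop_param("trace must be a qcmd_trace")
  check_number(fraction, "fraction", positive = TRUE)
  if (fraction >= 1) stop_param("fraction must be < 1")
  before <- plateau_frequencies(trace)[["delta_f_before"]]
  if (before <= 0) stop_analysis("no adsorption signal before the rinse")
  phase <- which(trace$time >= trace$injection_time &
                   trace$time < trace$rinse_time)
  if (length(phase) < 3L) stop_analysis("adsorption phase too short")
  y <- abs(trace$delta_f[phase])
  k <- min(as.integer(smooth), length(y) - (1 - length(y) %% 2L))
  if (k >= 3L) y <- stats::runmed(y, k, endrule = "median")
  thr <- fraction * before
  below <- which(y < thr)
  if (length(below) == length(y) ||
      (length(below) && below[length(below)] == length(y)))
    stop_analysis("no saturation before rinse: |delta f| never sustains %g%% of the plateau",
                  100 * fraction)
  first_sustained <- if (!length(below)) 1L else below[length(below)] + 1L
  trace$time[phase[first_sustained]] - trace$injection_time
}

#' Desorption extent (in vitro coating index)
#'
#' \eqn{100 (|\Delta f|_{before} - |\Delta f|_{after}) /
#' |\Delta f|_{before}}: the percentage of the adsorbed layer removed by
#' rinsing. Higher removal means a poorer coating; the value may be
#' negative if adsorption continued after the rinse (reported, not
#' clamped).
#'
#' @param delta_f_before Hz, pre-rinse plateau magnitude (> 0).
#' @param delta_f_after Hz, post-rinse plateau magnitude.
#' @return percent removal.
#' @export
desorption_extent <- function(delta_f_before, delta_f_after) {
  if (any(!is.finite(delta_f_before)) || any(delta_f_before <= 0))
    stop_domain("delta_f_before must be positive")
  100 * (delta_f_before - delta_f_after) / delta_f_before
}

#' Summarise a QCM-D trace
#'
#' Composes [plateau_frequencies()], [saturation_time()] and
#' [desorption_extent()] into an adsorption summary.
#'
#' @param trace a [qcmd_trace()].
#' @param fraction saturation criterion passed to [saturation_time()].
#' @return An object of class `adsorption_summary` with elements
#'   `t_saturation` (s), `delta_f_before`, `delta_f_after` (Hz,
#'   magnitudes), `removal_percent` and `coating_index_note` (textual
#'   polarity note: the index counts material removed, so larger values
#'   mean a poorer coating).
#' @export
summarize_qcmd <- function(trace, fraction = 0.98) {
  pl <- plateau_frequencies(trace)
  structure(list(t_saturation = saturation_time(trace, fraction),
                 delta_f_before = pl[["delta_f_before"]],
                 delta_f_after = pl[["delta_f_after"]],
                 removal_percent = desorption_extent(pl[["delta_f_before"]],
                                                     pl[["delta_f_after"]]),
                 coating_index_note =
                   "removal percent; higher removal = poorer in vitro coating"),
            class = "adsorption_summary")
}

#' @export
print.adsorption_summary <- function(x, ...) {
  cat(sprintf(paste0("<adsorption_summary> t_saturation = %.1f min, ",
                     "|delta f| before/after rinse = %.1f/%.1f Hz, ",
                     "removal = %.1f%%\n"),
              x$t_saturation / 60, x$delta_f_before, x$delta_f_after,
              x$removal_percent))
  invisible(x)
}
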