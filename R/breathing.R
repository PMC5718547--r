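#' Respiratory surrogate trace
#'
#' A timed surrogate-displacement signal (what an external respiratory
#' monitor records), from which inhalation peaks and retrospective phase
#' values are derived.
#'
#' @param times sample times in seconds, strictly increasing, length >= 2.
#' @param amplitudes surrogate displacement in arbitrary units, finite,
#'   same length as `times`.
#' @return An object of class `breathing_trace`.
#' @export
breathing_trace <- function(times, amplitudes) {
  if (length(times) < 2L || length(times) != length(amplitudes))
    c4_stop("trace needs >= 2 samples with matching times/amplitudes",
            "invalid_argument")
  if (any(diff(times) <= 0))
    c4_stop("trace times must be strictly increasing", "invalid_argument")
  if (!all(is.finite(times)) || !all(is.finite(amplitudes)))
    c4_stop("trace times and amplitudes must be finite", "invalid_argument")
  structure(list(times = as.numeric(times), amplitudes = as.numeric(amplitudes)),
            class = "breathing_trace")
}

#' Set of inhalation-peak times
#'
#' @param peak_times peak times in seconds, strictly increasing. At least
#'   two peaks are needed before phases can be computed.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(peak_times) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 1L || any(diff(peak_times) <= 0) ||
      !all(is.finite(peak_times)))
    c4_stop("peak times must be finite and strictly increasing", "invalid_argument")
  structure(list(peak_times = peak_times), class = "peak_set")
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two minima separating it from higher terrain (or the trace
# boundary) on each side.
peak_prominence <- function(amp, i) {
  left <- if (i == 1L) amp[1L] else {
    higher <- which(amp[seq_len(i - 1L)] > amp[i])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(amp[lo:(i - 1L)])
  }
  right <- if (i == length(amp)) amp[length(amp)] else {
    rest <- amp[(i + 1L):length(amp)]
    higher <- which(rest > amp[i])
    hi <- if (length(higher)) min(higher) - 1L else length(rest)
    min(rest[seq_len(hi)])
  }
  amp[i] - max(left, right)
}

#' Detect inhalation peaks in a breathing trace
#'
#' Finds local maxima of the surrogate amplitude, keeps those whose
#' topographic prominence reaches `min_prominence`, then enforces
#' `min_separation` greedily from the tallest peak down. This emulates
#' the peak detection step of a respiratory monitoring system so that
#' missed or spurious detections can be reproduced downstream with
#' [edit_peaks()].
#'
#' @param trace a [breathing_trace()].
#' @param min_prominence minimum prominence, in amplitude units.
#' @param min_separation minimum time between retained peaks, seconds (> 0).
#' @return A [peak_set()] of the detected peak times, in time order.
#' @export
detect_peaks <- function(trace, min_prominence = 0, min_separation = 1) {
  stopifnot(inherits(trace, "breathing_trace"))
  if (min_separation <= 0)
    c4_stop("'min_separation' must be positive", "invalid_argument")
  amp <- trace$amplitudes
  n <- length(amp)
  cand <- which(diff(c(-Inf, amp)) > 0 & diff(c(amp, -Inf)) <= 0)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[vapply(cand, function(i) peak_prominence(amp, i), numeric(1)) >=
                 min_prominence]
  keep <- logical(length(cand))
  for (i in order(amp[cand], decreasing = TRUE)) {
    ok <- !any(keep & abs(trace$times[cand] - trace$times[cand[i]]) < min_separation)
    keep[i] <- ok
  }
  times <- sort(trace$times[cand[keep]])
  if (length(times) < 2L)
    c4_stop("fewer than 2 peaks detected", "too_few_peaks")
  peak_set(times)
}

#' Insert and/or delete inhalation peaks
#'
#' Reproduces, deterministically, the manual peak-editing step of a phase
#' recalculation review: deletions must match an existing peak within
#' `match_tolerance`, insertions must not duplicate one.
#'
#' @param peaks a [peak_set()].
#' @param insert times (seconds) of peaks to add.
#' @param delete times (seconds) of peaks to remove (nearest match).
#' @param match_tolerance matching window in seconds (default 0.2).
#' @return The edited, re-sorted [peak_set()].
#' @export
edit_peaks <- function(peaks, insert = numeric(), delete = numeric(),
                       match_tolerance = 0.2) {
  stopifnot(inherits(peaks, "peak_set"))
  times <- peaks$peak_times
  for (d in delete) {
    i <- which.min(abs(times - d))
    if (length(i) == 0L || abs(times[i] - d) > match_tolerance)
      c4_stop(sprintf("unmatched deletion: no peak within %g s of t = %g",
                      match_tolerance, d), "unmatched_deletion")
    times <- times[-i]
  }
  for (a in insert) {
    if (length(times) && min(abs(times - a)) <= match_tolerance)
      c4_stop(sprintf("duplicate insertion: existing peak within %g s of t = %g",
                      match_tolerance, a), "duplicate_insertion")
    times <- c(times, a)
  }
  peak_set(sort(times))
}

#' Retrospective phase values from inhalation peaks
#'
#' Phase is 0% at every inhalation peak and advances linearly in time to
#' 100% at the next peak:
#' `phase(t) = 100 * (t - p_i) / (p_{i+1} - p_i)` for `t` in
#' `[p_i, p_{i+1})`. This is the standard retrospective phase-angle
#' surrogate; vendor systems may use proprietary variants.
#'
#' @param peaks a [peak_set()] with at least 2 peaks.
#' @param query_times times (seconds) at which to evaluate the phase.
#' @param outside `"error"` (default) to reject queries outside
#'   `[first peak, last peak)`; `"na"` to return `NA` for them.
#' @return Numeric vector of phases in `[0, 100)` (exactly 0 at peaks).
#' @export
compute_phase <- function(peaks, query_times, outside = c("error", "na")) {
  stopifnot(inherits(peaks, "peak_set"))
  outside <- match.arg(outside)
  p <- peaks$peak_times
  if (length(p) < 2L)
    c4_stop("at least 2 peaks required for phase computation", "too_few_peaks")
  t <- as.numeric(query_times)
  out <- t < p[1L] | t >= p[length(p)]
  if (any(out) && outside == "error")
    c4_stop("phase undefined outside peak span", "phase_undefined")
  i <- findInterval(t, p)
  ph <- rep(NA_real_, length(t))
  ok <- !out
  ph[ok] <- 100 * (t[ok] - p[i[ok]]) / (p[i[ok] + 1L] - p[i[ok]])
  ph
}
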