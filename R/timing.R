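# Deterministic sequence-timing calculator for the segmented, black-blood
# prepared, navigator-gated TPM protocol.  The timing model is a
# reconstruction from the printed protocol parameters: each cardiac phase
# spends one saturation module plus (k-lines + startup echoes) repetition
# times; the navigator runs once per cardiac cycle.  It reproduces the 2D
# protocol's 40 ms phase interval and 21 phases at 60 bpm and is documented
# as a model, not gospel.

#' Sequence timing parameters
#'
#' @param tr repetition time in ms.
#' @param klines_per_segment k-lines acquired per segment and phase.
#' @param startup_echoes startup echoes per phase.
#' @param t_sat duration of the saturation module (pulses + spoilers), ms.
#' @param t_nav navigator duration + evaluation time, ms, once per cycle.
#' @param rr RR interval in ms.
#' @param rr_fraction usable fraction of the RR interval (0-1].
#' @param n_phase_encodes phase-encode lines of the full acquisition.
#' @param n_velocity_encodings velocity encodings (4 for the Hadamard set).
#' @param sense_factor SENSE acceleration factor R.
#' @return object of class `tpm_timing`.  Defaults are the 2D protocol:
#'   TR 7 ms, 3 k-lines + 1 startup echo, 12 ms saturation module,
#'   15.5 + 5 ms navigator, 90% of a 1000 ms RR interval, 168 phase
#'   encodes.
#' @export
sequence_timing <- function(tr = 7, klines_per_segment = 3L,
                            startup_echoes = 1L, t_sat = 12,
                            t_nav = 20.5, rr = 1000, rr_fraction = 0.9,
                            n_phase_encodes = 168L,
                            n_velocity_encodings = 4L, sense_factor = 1L) {
  stopifnot_scalar(tr, "tr", positive = TRUE)
  stopifnot_scalar(rr, "rr", positive = TRUE)
  if (rr_fraction <= 0 || rr_fraction > 1)
    stop("rr_fraction must be in (0, 1]")
  if (t_sat < 0 || t_nav < 0) stop("durations must be non-negative")
  structure(list(tr = tr, klines_per_segment = as.integer(klines_per_segment),
                 startup_echoes = as.integer(startup_echoes), t_sat = t_sat,
                 t_nav = t_nav, rr = rr, rr_fraction = rr_fraction,
                 n_phase_encodes = as.integer(n_phase_encodes),
                 n_velocity_encodings = as.integer(n_velocity_encodings),
                 sense_factor = as.integer(sense_factor)),
            class = "tpm_timing")
}

#' @export
print.tpm_timing <- function(x, ...) {
  pi_ms <- phase_interval(x)
  cat(sprintf("Sequence timing: TR %g ms, %d k-lines + %d startup, sat %g ms\n",
              x$tr, x$klines_per_segment, x$startup_echoes, x$t_sat))
  cat(sprintf("  phase interval %g ms, saturation spacing %g ms, %d phases at %g ms RR\n",
              pi_ms, effective_saturation_interval(pi_ms),
              n_cardiac_phases(x, pi_ms), x$rr))
  invisible(x)
}

#' Temporal spacing of consecutive cardiac phases
#'
#' `t_sat + (klines_per_segment + startup_echoes) * tr`.
#'
#' @param timing a [sequence_timing()].
#' @return phase interval in ms (40 ms for the default 2D protocol).
#' @export
phase_interval <- function(timing) {
  stopifnot(inherits(timing, "tpm_timing"))
  timing$t_sat + (timing$klines_per_segment + timing$startup_echoes) * timing$tr
}

#' Effective spacing between saturation pulses at the same position
#'
#' The black-blood saturation slabs alternate between the two sides of the
#' slice in subsequent cardiac phases, so each position is re-saturated
#' every second phase: twice the phase interval (80 ms for the 2D
#' protocol).
#'
#' @param interval phase interval in ms.
#' @return effective saturation spacing in ms.
#' @export
effective_saturation_interval <- function(interval) {
  stopifnot_scalar(interval, "interval", positive = TRUE)
  2 * interval
}

#' Number of acquirable cardiac phases
#'
#' `floor((rr_fraction * rr - t_nav) / interval)`: the navigator runs once
#' at the start of each cycle, and only the accepted fraction of the RR
#' interval is available.
#'
#' @param timing a [sequence_timing()].
#' @param interval phase interval in ms (default: computed from `timing`).
#' @return integer phase count (21 for the default protocol at 60 bpm).
#' @export
n_cardiac_phases <- function(timing, interval = phase_interval(timing)) {
  stopifnot(inherits(timing, "tpm_timing"))
  stopifnot_scalar(interval, "interval", positive = TRUE)
  window <- timing$rr_fraction * timing$rr - timing$t_nav
  if (window <= 0) stop("no acquisition window left after the navigator")
  as.integer(floor(window / interval))
}

#' Nominal acceleration ratio of two scan durations
#'
#' Reference duration over accelerated duration, rounded half-up to the
#' stated number of decimals (matching how nominal factors are quoted,
#' e.g. 225 s / 117 s = 1.92).
#'
#' @param duration_ref,duration_acc durations in seconds (> 0).
#' @param decimals decimals to round to (default 2).
#' @return unitless ratio.
#' @export
acceleration_ratio <- function(duration_ref, duration_acc, decimals = 2L) {
  stopifnot_scalar(duration_ref, "duration_ref", positive = TRUE)
  stopifnot_scalar(duration_acc, "duration_acc", positive = TRUE)
  round_half_up(duration_ref / duration_acc, decimals)
}

#' Parse a scan duration
#'
#' Accepts `"m:ss"` (minutes and seconds, spaces tolerated) or a bare
#' number of seconds.
#'
#' @param text character scalar, e.g. `"3:45"` or `"57"`.
#' @return duration in seconds.
#' @export
parse_duration <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub(" ", "", text)
  if (grepl("^\\d+:\\d{1,2}(\\.\\d+)?$", s)) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    return(as.numeric(parts[1L]) * 60 + as.numeric(parts[2L]))
  }
  if (grepl("^\\d+(\\.\\d+)?$", s)) return(as.numeric(s))
  stop(sprintf("malformed duration '%s'", text))
}

#' Format seconds as "m:ss"
#'
#' Inverse of [parse_duration()] for whole-second durations.
#'
#' @param seconds duration in seconds.
#' @return character scalar.
#' @export
format_duration <- function(seconds) {
  stopifnot_scalar(seconds, "seconds")
  if (seconds < 0) stop("duration must be non-negative")
  sprintf("%d:%02d", floor(seconds / 60), round(seconds %% 60))
}

#' Timing report for a protocol
#'
#' Collects the derived quantities (phase interval, effective saturation
#' spacing, cardiac phases) and, when nominal durations are supplied,
#' the acceleration ratios relative to the first duration.
#'
#' @param timing a [sequence_timing()].
#' @param durations optional character vector of nominal scan durations
#'   (`"m:ss"`), the first being the reference.
#' @return list suitable for JSON serialisation.
#' @export
timing_report <- function(timing, durations = NULL) {
  pi_ms <- phase_interval(timing)
  out <- list(phase_interval_ms = pi_ms,
              effective_saturation_interval_ms =
                effective_saturation_interval(pi_ms),
              n_cardiac_phases = n_cardiac_phases(timing, pi_ms))
  if (!is.null(durations)) {
    secs <- vapply(durations, parse_duration, numeric(1))
    out$durations_s <- unname(secs)
    out$acceleration_ratios <-
      unname(vapply(secs[-1L], function(d) acceleration_ratio(secs[1L], d),
                    numeric(1)))
  }
  out
}
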