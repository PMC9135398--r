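#' Current stimuli
#'
#' Constructors for the stimulus waveforms used throughout the package. All
#' stimuli are functions of time evaluable at any point of the simulation
#' window; times in ms, currents in pA.
#'
#' @param amplitude_pA step / pulse amplitude (pA).
#' @param onset_ms stimulus onset (ms).
#' @param offset_ms stimulus offset (ms); may be `Inf` for steps.
#' @name stimulus
NULL

new_stimulus <- function(kind, kind_code, ...) {
  s <- c(list(kind = kind, kind_code = as.integer(kind_code)), list(...))
  if (s$onset_ms < 0) stop("stimulus onset must be non-negative")
  structure(s, class = "cc_stimulus")
}

#' @rdname stimulus
#' @export
stim_step <- function(amplitude_pA, onset_ms = 0, offset_ms = Inf) {
  if (is.finite(offset_ms) && offset_ms < onset_ms)
    stop("stimulus offset before onset")
  new_stimulus("step", 0L, amplitude_pA = amplitude_pA,
               onset_ms = onset_ms, offset_ms = offset_ms)
}

#' @rdname stimulus
#' @param width_ms pulse width (ms).
#' @param isi_ms inter-stimulus interval, pause between pulse offset and the
#'   next onset (ms).
#' @param count number of pulses.
#' @export
stim_pulse_train <- function(amplitude_pA, width_ms, isi_ms, count,
                             onset_ms = 0) {
  stopifnot(width_ms > 0, isi_ms >= 0, count >= 1)
  new_stimulus("pulse_train", 1L, amplitude_pA = amplitude_pA,
               onset_ms = onset_ms, width_ms = width_ms, isi_ms = isi_ms,
               count = as.integer(count),
               offset_ms = onset_ms + count * (width_ms + isi_ms))
}

#' @rdname stimulus
#' @param ramp_duration_ms ramp duration (ms).
#' @param height_pA current reached at the end of the ramp (pA).
#' @export
stim_ramp <- function(height_pA, ramp_duration_ms, onset_ms = 0) {
  stopifnot(ramp_duration_ms > 0)
  new_stimulus("ramp", 2L, onset_ms = onset_ms,
               ramp_duration_ms = ramp_duration_ms, height_pA = height_pA,
               offset_ms = onset_ms + ramp_duration_ms)
}

#' @rdname stimulus
#' @param freq_Hz sinusoid frequency (Hz).
#' @param baseline_pA constant offset current added to the sinusoid (pA).
#' @export
stim_sinusoid <- function(amplitude_pA, freq_Hz, onset_ms = 0,
                          offset_ms = Inf, baseline_pA = 0) {
  stopifnot(freq_Hz > 0)
  new_stimulus("sinusoid", 3L, amplitude_pA = amplitude_pA,
               onset_ms = onset_ms, offset_ms = offset_ms,
               freq_Hz = freq_Hz, baseline_pA = baseline_pA)
}

#' @rdname stimulus
#' @param samples_pA vector of current samples held zero-order (pA).
#' @param sample_dt_ms sampling interval of `samples_pA` (ms).
#' @export
stim_samples <- function(samples_pA, sample_dt_ms, onset_ms = 0) {
  stopifnot(sample_dt_ms > 0, length(samples_pA) >= 1)
  new_stimulus("samples", 4L, samples_pA = as.numeric(samples_pA),
               sample_dt_ms = sample_dt_ms, onset_ms = onset_ms,
               offset_ms = onset_ms + length(samples_pA) * sample_dt_ms)
}

#' Evaluate a stimulus at given times
#'
#' @param stim a stimulus created by one of the `stim_*()` constructors.
#' @param t_ms numeric vector of times (ms).
#' @return current in pA at each time.
#' @export
stim_eval <- function(stim, t_ms) {
  stopifnot(inherits(stim, "cc_stimulus"))
  u <- t_ms - stim$onset_ms
  switch(stim$kind,
    step = ifelse(u >= 0 & t_ms < stim$offset_ms, stim$amplitude_pA, 0),
    pulse_train = {
      period <- stim$width_ms + stim$isi_ms
      k <- floor(u / period)
      on <- u >= 0 & k < stim$count & (u - k * period) < stim$width_ms
      ifelse(on, stim$amplitude_pA, 0)
    },
    ramp = ifelse(u >= 0 & t_ms < stim$offset_ms,
                  stim$height_pA * u / stim$ramp_duration_ms, 0),
    sinusoid = ifelse(u >= 0 & t_ms < stim$offset_ms,
                      stim$baseline_pA + stim$amplitude_pA *
                        sin(2 * pi * stim$freq_Hz * u / 1000), 0),
    samples = {
      idx <- floor(u / stim$sample_dt_ms) + 1
      ok <- u >= 0 & idx <= length(stim$samples_pA)
      out <- numeric(length(u))
      out[ok] <- stim$samples_pA[idx[ok]]
      out
    })
}

#' @export
print.cc_stimulus <- function(x, ...) {
  cat("<stimulus:", x$kind, "> onset", x$onset_ms, "ms")
  if (!is.null(x$amplitude_pA)) cat(", amplitude", x$amplitude_pA, "pA")
  if (x$kind == "pulse_train")
    cat(",", x$count, "x", x$width_ms, "ms on /", x$isi_ms, "ms off")
  cat("\n")
  invisible(x)
}
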