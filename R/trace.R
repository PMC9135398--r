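#' Recorded time-series traces
#'
#' A trace is a data frame of uniformly sampled channels with an explicit
#' sampling interval. Channel names carry units (`time_ms`, `V_mV`,
#' `Iext_pA`, `Idyn_pA`, optionally `INa_pA`, `IK_pA`, `IL_pA`, gating states
#' `h`, `n`, and a far-compartment voltage `Vf_mV`).
#'
#' @param data data frame with a `time_ms` column and at least one channel.
#' @param dt_ms sampling interval (ms).
#' @return an object of class `cc_trace` (a data frame).
#' @export
cc_trace <- function(data, dt_ms) {
  stopifnot(is.data.frame(data), "time_ms" %in% names(data), dt_ms > 0)
  n <- vapply(data, length, integer(1))
  if (length(unique(n)) != 1) stop("all channels must have the same length")
  structure(data, dt_ms = dt_ms, class = c("cc_trace", "data.frame"))
}

#' @export
print.cc_trace <- function(x, ...) {
  cat("<trace> ", nrow(x), " samples @ ", attr(x, "dt_ms"), " ms (",
      round(nrow(x) * attr(x, "dt_ms")), " ms), channels: ",
      paste(setdiff(names(x), "time_ms"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sampling interval of a trace
#' @param trace a `cc_trace`.
#' @return interval in ms.
#' @export
trace_dt <- function(trace) attr(trace, "dt_ms")

#' Write / read a trace as CSV
#'
#' Plain CSV with the unit-bearing header, one row per sample.
#'
#' @param trace a `cc_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  if (!"time_ms" %in% names(d)) stop("trace file lacks a time_ms column")
  dt <- stats::median(diff(d$time_ms))
  cc_trace(d, dt)
}

#' Extract a time window from a trace
#' @param trace a `cc_trace`.
#' @param from_ms,to_ms window limits (ms), inclusive.
#' @export
trace_window <- function(trace, from_ms = -Inf, to_ms = Inf) {
  keep <- trace$time_ms >= from_ms & trace$time_ms <= to_ms
  if (!any(keep)) stop("empty trace window")
  cc_trace(as.data.frame(trace)[keep, , drop = FALSE], trace_dt(trace))
}
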