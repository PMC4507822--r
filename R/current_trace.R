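#' Construct a current trace
#'
#' Uniformly sampled membrane current (pA) with acquisition metadata:
#' sampling rate, holding potential, stimulus times, and response polarity.
#' Inward currents (negative deflections, e.g. EPSCs at -70 mV) carry
#' `polarity = "inward"`; outward currents (IPSCs at +10/+20 mV)
#' `polarity = "outward"`. Analysis functions rectify according to this
#' flag so amplitudes are always reported as positive magnitudes.
#'
#' @param samples numeric vector of current samples, pA.
#' @param sampling_rate sampling rate, Hz (> 0).
#' @param holding_potential holding potential, mV.
#' @param stim_times stimulus onset times, s (possibly empty).
#' @param polarity `"inward"` or `"outward"`.
#' @return object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate, holding_potential = NA_real_,
                          stim_times = numeric(0),
                          polarity = c("outward", "inward")) {
  polarity <- match.arg(polarity)
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("trace samples must be finite (no NaN/NA)", call. = FALSE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         holding_potential = holding_potential,
         stim_times = as.numeric(stim_times), polarity = polarity),
    class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> %d samples @ %g kHz (%.2f s), %s, hold %s mV, %d stim\n",
    length(x$samples), x$sampling_rate / 1000, trace_duration(x), x$polarity,
    format(x$holding_potential), length(x$stim_times)))
  invisible(x)
}

#' Duration of a current trace in seconds
#' @param trace a [current_trace()].
#' @return duration, s.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate

#' Signed samples rectified to positive response polarity
#' @keywords internal
rectified <- function(trace) {
  if (trace$polarity == "inward") -trace$samples else trace$samples
}

#' Double-exponential synaptic kernel, normalized to unit peak
#'
#' `k(t) = c * (exp(-t/tau_decay) - exp(-t/tau_rise))` with `c` chosen so
#' that the maximum is 1. The standard phenomenological PSC waveform.
#'
#' @param t time from onset, seconds (vector, >= 0).
#' @param tau_rise rise time constant, ms.
#' @param tau_decay decay time constant, ms (> `tau_rise`).
#' @return kernel values, unit peak.
#' @export
psc_kernel <- function(t, tau_rise, tau_decay) {
  if (tau_rise >= tau_decay)
    stop("rise time constant must be smaller than decay time constant",
         call. = FALSE)
  tr <- tau_rise / 1000; td <- tau_decay / 1000
  t_peak <- tr * td / (td - tr) * log(td / tr)
  peak <- exp(-t_peak / td) - exp(-t_peak / tr)
  out <- (exp(-t / td) - exp(-t / tr)) / peak
  out[t < 0] <- 0
  out
}
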