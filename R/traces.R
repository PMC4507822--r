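#' Measure an evoked synaptic response
#'
#' Analyzes the response following a stimulus: the trace is rectified to
#' positive response polarity and baseline-subtracted (baseline = mean over
#' the pre-stimulus segment, noise SD from its MAD). Within the analysis
#' window the reported peak is the **earliest local maximum** exceeding
#' `3 x noise SD` - not the global maximum - because evoked responses are
#' often polysynaptic with multiple peaks and the shortest-latency
#' (presumably monosynaptic) component is the quantity of interest. Charge
#' is the trapezoidal integral of the baseline-subtracted response over the
#' window (pC), and the decay constant is a single-exponential fit starting
#' at the last suprathreshold peak.
#'
#' @param trace a [current_trace()] with at least one stimulus annotation.
#' @param window analysis window relative to the stimulus, ms
#'   (default `c(1, 100)`).
#' @param stim_index which stimulus to analyze (default 1).
#' @param threshold_sd peak prominence threshold in noise SDs (default 3).
#' @param baseline_ms pre-stimulus baseline length, ms (default 50, clipped
#'   to the available pre-stimulus samples).
#' @return list of class `evoked_measure`: `peak_amplitude` (pA),
#'   `peak_latency` (ms), `charge` (pC), `decay_tau` (ms), `n_peaks`,
#'   `responded` (FALSE for a "no response" trace - distinct from a zero
#'   amplitude).
#' @export
measure_evoked <- function(trace, window = c(1, 100), stim_index = 1L,
                           threshold_sd = 3, baseline_ms = 50) {
  stopifnot(inherits(trace, "current_trace"))
  if (length(trace$stim_times) < stim_index)
    stop("trace has no stimulus annotation at the requested index",
         call. = FALSE)
  fs <- trace$sampling_rate
  t_stim <- trace$stim_times[stim_index]
  x <- rectified(trace)
  i_stim <- floor(t_stim * fs) + 1L
  b0 <- max(1L, i_stim - round(baseline_ms / 1000 * fs))
  base_seg <- x[b0:max(b0, i_stim - 1L)]
  base <- mean(base_seg)
  noise_sd <- stats::mad(base_seg)
  if (noise_sd == 0) noise_sd <- stats::sd(base_seg)
  if (!is.finite(noise_sd)) noise_sd <- 0
  i1 <- i_stim + round(window[1L] / 1000 * fs)
  i2 <- min(length(x), i_stim + round(window[2L] / 1000 * fs))
  if (i2 <= i1) stop("analysis window is empty", call. = FALSE)
  seg <- x[i1:i2] - base
  thr <- threshold_sd * noise_sd
  pk <- find_response_peaks(seg, fs, height = thr, prominence = thr)
  if (!length(pk$idx)) {
    return(structure(list(peak_amplitude = NA_real_, peak_latency = NA_real_,
                          charge = NA_real_, decay_tau = NA_real_,
                          n_peaks = 0L, responded = FALSE),
                     class = "evoked_measure"))
  }
  first_pk <- pk$idx[1L]
  last_pk <- pk$idx[length(pk$idx)]
  charge <- trapz_pC(seg, fs)
  structure(
    list(peak_amplitude = pk$value[1L],
         peak_latency = (i1 - i_stim + first_pk - 1L) / fs * 1000,
         charge = charge,
         decay_tau = fit_decay_tau(pk$smoothed, last_pk, fs),
         n_peaks = length(pk$idx), responded = TRUE),
    class = "evoked_measure")
}

#' Smoothed, prominence-filtered response peaks
#'
#' Boxcar-smooths the segment (width `smooth_ms`), finds interior local
#' maxima, and keeps those whose height exceeds `height` and whose
#' prominence (height above the higher of the two bracketing valleys,
#' valleys taken to the nearest higher sample or segment edge) exceeds
#' `prominence`. Smoothing plus the prominence rule keeps noise bumps on a
#' rising limb from posing as an early component.
#'
#' @param seg baseline-subtracted, rectified segment.
#' @param fs sampling rate, Hz.
#' @param height minimum peak height.
#' @param prominence minimum prominence.
#' @param smooth_ms boxcar width, ms.
#' @param max_scan bound (samples) on the search for each peak's bracketing
#'   valleys; `Inf` scans the whole segment. A finite bound makes
#'   prominence local and keeps long-trace scans linear.
#' @return list: `idx` (peak indices on the original segment grid),
#'   `value` (smoothed heights), `smoothed` (the smoothed segment).
#' @keywords internal
find_response_peaks <- function(seg, fs, height, prominence,
                                smooth_ms = 1, max_scan = Inf) {
  w <- max(1L, round(smooth_ms / 1000 * fs))
  sm <- if (w > 1L) stats::filter(seg, rep(1 / w, w), sides = 2) else seg
  sm[is.na(sm)] <- seg[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  # sentinels let a maximum sitting at the segment boundary count
  cand <- local_maxima(c(-Inf, sm, -Inf)) - 1L
  cand <- cand[cand >= 1L & cand <= n]
  cand <- cand[sm[cand] > height]
  if (!length(cand))
    return(list(idx = integer(0), value = numeric(0), smoothed = sm))
  prom <- vapply(cand, function(i) {
    h <- sm[i]
    l0 <- max(1L, if (is.finite(max_scan)) i - as.integer(max_scan) else 1L)
    r1 <- min(n, if (is.finite(max_scan)) i + as.integer(max_scan) else n)
    lbase <- if (i == 1L) -Inf else {
      left <- sm[seq(l0, i - 1L)]
      higher_l <- which(left >= h)
      min(left[seq(from = if (length(higher_l)) max(higher_l) else 1L,
                   to = length(left))])
    }
    rbase <- if (i == n) -Inf else {
      right <- sm[seq(i + 1L, r1)]
      higher_r <- which(right >= h)
      min(right[seq_len(if (length(higher_r)) min(higher_r)
                        else length(right))])
    }
    base <- max(lbase, rbase)
    if (is.infinite(base)) h else h - base
  }, numeric(1))
  keep <- prom >= prominence
  list(idx = cand[keep], value = sm[cand[keep]], smoothed = sm)
}

#' Interior strict local maxima of a numeric vector
#' @keywords internal
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  # plateau-tolerant: a run of equal values flanked by lower ones counts
  # once, at its first index
  d <- diff(y)
  rising <- c(FALSE, d > 0)
  falling <- c(d < 0, FALSE)
  # carry "last move was up" across flats
  up <- logical(n)
  state <- FALSE
  for (i in seq_len(n)) {
    if (rising[i]) state <- TRUE
    else if (i > 1L && d[i - 1L] < 0) state <- FALSE
    up[i] <- state
  }
  which(up & falling)
}

#' Trapezoidal charge integral: pA sampled at fs integrates to pA*s = pC
#' @keywords internal
trapz_pC <- function(seg, fs) {
  if (length(seg) < 2L) return(0)
  sum((seg[-1L] + seg[-length(seg)]) / 2) / fs
}

#' Paired-pulse ratio
#'
#' Measures the responses to two stimuli separated by `interval` ms and
#' returns `p2 / p1`, the standard presynaptic release-probability proxy.
#' Overlap of the first response into the second window is handled by
#' model-based subtraction:
#'
#' 1. the shared decay constant is fit on the late joint tail (after the
#'    second response's peak, where the superposition of two equal-kinetics
#'    responses is again a single exponential);
#' 2. a double-exponential model of response 1 (free amplitude, onset and
#'    rise; decay pinned from step 1) is fit over the first interval and
#'    its continuation subtracted from the second window;
#' 3. the paired-pulse ratio is the least-squares scale of the corrected
#'    second window on the model waveform - equivalent to measuring `p2`
#'    with the whole response rather than one noisy peak sample.
#'
#' If the model fit does not converge the function falls back to
#' mono-exponential extrapolation-subtraction and a smoothed peak
#' measurement.
#'
#' @param trace a [current_trace()] with two stimulus annotations separated
#'   by `interval` (within one sample).
#' @param interval interpulse interval, ms (conventionally 25, 50 or 100).
#' @param window per-response analysis window, ms (default up to the
#'   interval for the first response).
#' @param threshold_sd peak threshold in noise SDs.
#' @return list of class `ppr_result`: `interval`, `p1`, `p2`, `ratio`
#'   (`NA` when the first response is below noise).
#' @export
paired_pulse_ratio <- function(trace, interval, window = NULL,
                               threshold_sd = 3) {
  stopifnot(inherits(trace, "current_trace"))
  if (length(trace$stim_times) < 2L)
    stop("paired-pulse analysis needs two stimulus annotations", call. = FALSE)
  fs <- trace$sampling_rate
  s1 <- trace$stim_times[1L]; s2 <- trace$stim_times[2L]
  if (abs((s2 - s1) * 1000 - interval) > 1000 / fs + 1e-9)
    stop("stimulus annotations do not match the stated interval", call. = FALSE)
  if (is.null(window)) window <- c(1, interval - 1000 / fs)
  m1 <- measure_evoked(trace, window = window, stim_index = 1L,
                       threshold_sd = threshold_sd)
  if (!m1$responded)
    return(structure(list(interval = interval, p1 = NA_real_, p2 = NA_real_,
                          ratio = NA_real_), class = "ppr_result"))
  x <- rectified(trace)
  n <- length(x)
  i_s1 <- floor(s1 * fs) + 1L
  i_s2 <- floor(s2 * fs) + 1L
  b0 <- max(1L, i_s1 - round(0.050 * fs))
  base_seg <- x[b0:max(b0, i_s1 - 1L)]
  base <- mean(base_seg)
  noise_sd <- stats::mad(base_seg)
  if (noise_sd == 0) noise_sd <- stats::sd(base_seg)
  L <- i_s2 - i_s1
  i2_end <- min(n, i_s2 + L - 1L)
  wsm <- max(1L, round(0.002 * fs))
  boxcar <- function(v) {
    if (wsm == 1L || length(v) < 3L * wsm) return(v)
    sm <- as.numeric(stats::filter(v, rep(1 / wsm, wsm), sides = 2))
    ifelse(is.na(sm), v, sm)
  }
  sig_s <- noise_sd / sqrt(wsm)
  # shared decay constant from the late joint tail: two same-kinetics
  # responses sum to a single exponential after the second peak
  seg2_raw <- x[i_s2:i2_end] - base
  i_pk2 <- i_s2 + which.max(boxcar(seg2_raw)) - 1L
  tail_sm <- boxcar(x[i_pk2:n] - base)
  tau_ms <- fit_decay_tau(tail_sm, 1L, fs, floor = 3 * sig_s)
  i_pk1 <- i_s1 + round((m1$peak_latency / 1000) * fs)
  fit1 <- NULL
  if (!is.na(tau_ms)) {
    t1 <- (seq_len(L) - 1L) / fs
    w_raw <- x[i_s1:(i_s2 - 1L)] - base
    tr0 <- min(2, tau_ms / 4)  # starting rise tau, ms
    t_pk0 <- (tr0 * tau_ms / (tau_ms - tr0)) * log(tau_ms / tr0) / 1000
    o_start <- min(max((i_pk1 - i_s1) / fs - t_pk0, 1 / fs), L / fs)
    fit1 <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        w_raw ~ A * psc_kernel(t1 - o, tr, tau_ms),
        start = list(A = m1$peak_amplitude, o = o_start, tr = tr0),
        lower = c(A = 0, o = 0, tr = 0.05),
        upper = c(A = Inf, o = L / fs, tr = tau_ms * 0.9),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit1)) {
      cf0 <- stats::coef(fit1)
      if (!all(is.finite(cf0)) || cf0[["A"]] <= 0) fit1 <- NULL
    }
  }
  if (!is.null(fit1)) {
    cf <- stats::coef(fit1)
    t_all <- ((i_s2:i2_end) - i_s1) / fs
    resid2 <- x[i_s2:i2_end] - base -
      cf[["A"]] * psc_kernel(t_all - cf[["o"]], cf[["tr"]], tau_ms)
    km <- cf[["A"]] *
      psc_kernel(((i_s2:i2_end) - i_s2) / fs - cf[["o"]], cf[["tr"]], tau_ms)
    ratio <- sum(resid2 * km) / sum(km^2)
    p2 <- ratio * m1$peak_amplitude
  } else {
    # fallback: mono-exponential extrapolation-subtraction, smoothed peak
    fit_seg <- boxcar(x[i_pk1:(i_s2 - 1L)] - base)
    tau_fb <- fit_decay_tau(fit_seg, 1L, fs, floor = 3 * sig_s)
    amp_at_pk <- fit_seg[1L]
    seg2 <- boxcar(seg2_raw)
    if (!is.na(tau_fb) && amp_at_pk > 0) {
      t_ms <- ((i_s2:i2_end) - i_pk1) / fs * 1000
      seg2 <- seg2 - amp_at_pk * exp(-t_ms / tau_fb)
    }
    thr <- threshold_sd * noise_sd
    pk2 <- find_response_peaks(seg2, fs, height = thr, prominence = thr)
    p2 <- if (length(pk2$idx)) pk2$value[1L] else max(seg2)
    ratio <- p2 / m1$peak_amplitude
  }
  structure(list(interval = interval, p1 = m1$peak_amplitude, p2 = p2,
                 ratio = ratio), class = "ppr_result")
}

#' Input-output curve from sweeps at increasing stimulus intensity
#'
#' Averages the earliest-peak amplitude from [measure_evoked()] over the
#' sweeps recorded at each stimulus intensity (responses are conventionally
#' averaged over two to three consecutive trials per intensity).
#' Non-responding sweeps contribute `NA` and are dropped from the mean;
#' intensities with no responding sweep are reported as `NA` (gaps).
#'
#' @param sweeps list of [current_trace()] sweeps.
#' @param intensities stimulus intensity (mA) per sweep, same length.
#' @param ... passed to [measure_evoked()].
#' @return data.frame of class `input_output_curve`: `intensity_mA`,
#'   `mean_peak_pA`, `n_sweeps` (ascending intensity).
#' @export
input_output <- function(sweeps, intensities, ...) {
  stopifnot(length(sweeps) == length(intensities))
  if (!length(sweeps)) {
    out <- data.frame(intensity_mA = numeric(0), mean_peak_pA = numeric(0),
                      n_sweeps = integer(0))
    class(out) <- c("input_output_curve", "data.frame")
    return(out)
  }
  peaks <- vapply(sweeps, function(s) {
    m <- measure_evoked(s, ...)
    if (m$responded) m$peak_amplitude else NA_real_
  }, numeric(1))
  levs <- sort(unique(intensities))
  out <- data.frame(
    intensity_mA = levs,
    mean_peak_pA = vapply(levs, function(l) {
      v <- peaks[intensities == l]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)),
    n_sweeps = vapply(levs, function(l) sum(intensities == l), integer(1)))
  class(out) <- c("input_output_curve", "data.frame")
  out
}

#' Passive membrane properties from a voltage-step trace
#'
#' From the current response to a voltage command step `dV` (the seal-test
#' waveform, stimulus annotation at the step onset):
#'
#' * total resistance `R_total = dV / I_ss` from the steady-state current;
#' * series resistance `Rs = dV / I_0` from the back-extrapolated
#'   instantaneous jump (exponential fit evaluated at the step onset);
#' * input (membrane) resistance `Rm = R_total - Rs`;
#' * `tau` from a single-exponential fit of the decaying transient;
#' * capacitance by charge integration: `Cm = Q / dV * ((Rs+Rm)/Rm)^2`,
#'   where `Q` is the integral of the transient above the steady state.
#'   The quadratic factor undoes the attenuation the series resistance
#'   imposes on the charging transient; the uncorrected estimator `Q/dV`
#'   underestimates `Cm` by `(Rm/(Rs+Rm))^2`. A second estimate from
#'   `tau = Cm * Rs*Rm/(Rs+Rm)` is reported as `capacitance_tau` for
#'   diagnostics.
#'
#' @param trace a [current_trace()] from [gen_rc_step()] or equivalent, with
#'   the step onset annotated as its first stimulus time.
#' @param dV command step, mV (default 10).
#' @param ss_frac final fraction of the step used for the steady state
#'   (default 0.3).
#' @return list of class `passive_props`: `capacitance` (pF),
#'   `input_resistance` (MOhm), `series_resistance` (MOhm), `tau` (ms),
#'   `capacitance_tau` (pF), `converged`.
#' @export
passive_properties <- function(trace, dV = 10, ss_frac = 0.3) {
  stopifnot(inherits(trace, "current_trace"))
  if (!length(trace$stim_times))
    stop("step trace needs its onset annotated as a stimulus time",
         call. = FALSE)
  fs <- trace$sampling_rate
  x <- trace$samples
  i_on <- floor(trace$stim_times[1L] * fs) + 1L
  n <- length(x)
  base <- if (i_on > 1L) mean(x[seq_len(i_on - 1L)]) else 0
  ss_i <- round(n - (n - i_on) * ss_frac)
  I_ss <- mean(x[ss_i:n]) - base
  if (!is.finite(I_ss) || I_ss == 0)
    stop("no steady-state current: is this a step response?", call. = FALSE)
  R_total <- 1000 * dV / I_ss
  # transient: exponential fit of (I - I_ss) from just after onset
  trans <- x[i_on:(ss_i - 1L)] - base - I_ss
  pk <- which.max(abs(trans[seq_len(max(3L, round(length(trans) / 4)))]))
  sgn <- sign(trans[pk])
  tau_ms <- fit_decay_tau(sgn * trans, pk, fs)
  converged <- is.finite(tau_ms)
  # back-extrapolate the fit to the step onset for the instantaneous jump
  I0 <- if (converged) {
    amp_pk <- trans[pk]
    I_ss + amp_pk * exp((pk - 1L) / fs * 1000 / tau_ms)
  } else I_ss + trans[pk]
  Rs <- 1000 * dV / I0
  Rm <- R_total - Rs
  # charge above steady state over the fitted transient (analytic tail
  # beyond the integration window is negligible at >= 5 tau)
  Q_pA_ms <- sum((trans[-1L] + trans[-length(trans)]) / 2) / fs * 1000
  Cm_q <- abs(Q_pA_ms / dV) * ((Rs + Rm) / Rm)^2
  Cm_tau <- if (converged && Rs > 0 && Rm > 0)
    tau_ms * 1000 * (Rs + Rm) / (Rs * Rm) else NA_real_
  structure(
    list(capacitance = Cm_q, input_resistance = Rm, series_resistance = Rs,
         tau = tau_ms, capacitance_tau = Cm_tau, total_resistance = R_total,
         converged = converged),
    class = "passive_props")
}

#' Current density
#'
#' Peak current divided by cell capacitance, pA/pF; normalizes
#' agonist-evoked responses to cell size.
#'
#' @param peak_pA peak current, pA.
#' @param capacitance_pF cell capacitance, pF (> 0).
#' @return current density, pA/pF.
#' @export
current_density <- function(peak_pA, capacitance_pF) {
  if (any(capacitance_pF <= 0))
    stop("capacitance must be positive", call. = FALSE)
  peak_pA / capacitance_pF
}
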