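#' Render a current trace from an event table
#'
#' Deterministic superposition of double-exponential synaptic events plus
#' optional Gaussian noise. Separated from [gen_psc_trace()] so the same
#' ground-truth event table can be re-rendered (e.g. with action-potential-
#' dependent events removed to emulate TTX application).
#'
#' @param events data.frame with columns `time` (s) and `amplitude` (pA,
#'   positive magnitude).
#' @param duration trace duration, s.
#' @param sampling_rate Hz.
#' @param tau_rise,tau_decay kernel time constants, ms (`tau_rise <
#'   tau_decay`).
#' @param noise_sd Gaussian noise SD, pA (0 for noise-free).
#' @param seed seed for the noise (required when `noise_sd > 0`).
#' @param polarity `"outward"` (default) or `"inward"`; inward events are
#'   rendered as negative deflections.
#' @param holding_potential carried into the trace metadata, mV.
#' @return a [current_trace()].
#' @export
render_psc_trace <- function(events, duration, sampling_rate = 5000,
                             tau_rise = 2, tau_decay = 20, noise_sd = 0,
                             seed = NULL, polarity = "outward",
                             holding_potential = NA_real_) {
  n <- round(duration * sampling_rate)
  tt <- (seq_len(n) - 1L) / sampling_rate
  x <- numeric(n)
  kern_len <- min(n, ceiling((tau_decay / 1000 * 8 + tau_rise / 1000 * 2) *
                               sampling_rate))
  kt <- (seq_len(kern_len) - 1L) / sampling_rate
  kern <- psc_kernel(kt, tau_rise, tau_decay)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      i0 <- floor(events$time[i] * sampling_rate) + 1L
      idx <- i0:min(n, i0 + kern_len - 1L)
      x[idx] <- x[idx] + events$amplitude[i] * kern[seq_along(idx)]
    }
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    x <- x + with_rng(seed, stats::rnorm(n, 0, noise_sd))
  }
  if (polarity == "inward") x <- -x
  current_trace(x, sampling_rate, holding_potential = holding_potential,
                polarity = polarity)
}

#' Generate a spontaneous-PSC trace with known ground truth
#'
#' Emulates a voltage-clamp recording of spontaneous postsynaptic currents:
#' Poisson event arrivals at `event_rate`, lognormal amplitudes (median
#' `amp_median`, log-SD `amp_sdlog`), a double-exponential kernel, and
#' Gaussian baseline noise. Each event is flagged action-potential-dependent
#' with probability `ap_dependent_frac`; re-rendering the trace without the
#' flagged events emulates TTX application (which silences the
#' action-potential-dependent component, leaving miniature events).
#'
#' @param duration s.
#' @param event_rate mean event rate, Hz (>= 0).
#' @param amp_median median amplitude, pA.
#' @param amp_sdlog lognormal log-SD of amplitudes (default 0.3, a typical
#'   PSC amplitude spread).
#' @param ap_dependent_frac probability an event is action-potential
#'   dependent (default 0).
#' @param tau_rise,tau_decay kernel time constants, ms.
#' @param noise_sd Gaussian noise SD, pA.
#' @param sampling_rate Hz.
#' @param seed integer seed; determines arrivals, amplitudes, flags, noise.
#' @param polarity,holding_potential trace metadata.
#' @return list with `trace` (a [current_trace()]) and `events` (data.frame
#'   `time`, `amplitude`, `ap_dependent`).
#' @export
gen_psc_trace <- function(duration, event_rate, amp_median = 25,
                          amp_sdlog = 0.3, ap_dependent_frac = 0,
                          tau_rise = 2, tau_decay = 20, noise_sd = 0,
                          sampling_rate = 5000, seed,
                          polarity = "outward",
                          holding_potential = NA_real_) {
  if (tau_rise >= tau_decay)
    stop("rise time constant must be smaller than decay time constant",
         call. = FALSE)
  if (event_rate < 0) stop("event_rate must be >= 0", call. = FALSE)
  seeds <- derive_seeds(seed, 2L)
  events <- with_rng(seeds[1L], {
    n_ev <- stats::rpois(1, event_rate * duration)
    data.frame(
      time = sort(stats::runif(n_ev, 0, duration)),
      amplitude = stats::rlnorm(n_ev, meanlog = log(amp_median),
                                sdlog = amp_sdlog),
      ap_dependent = stats::runif(n_ev) < ap_dependent_frac)
  })
  trace <- render_psc_trace(events, duration, sampling_rate,
                            tau_rise, tau_decay, noise_sd,
                            seed = seeds[2L], polarity = polarity,
                            holding_potential = holding_potential)
  list(trace = trace, events = events)
}

#' Generate a pre/post TTX pair of PSC traces
#'
#' One ground-truth event set is rendered twice: the full set ("pre") and
#' the action-potential-independent subset only ("post TTX"), with
#' independent noise. The generated `ap_dependent` fraction is the ground
#' truth for the percent reduction in event frequency after TTX.
#'
#' @inheritParams gen_psc_trace
#' @return list with `pre`, `post` (each a [current_trace()]), `events`
#'   (full truth table) and `true_reduction_pct`.
#' @export
gen_ttx_pair <- function(duration, event_rate, ap_dependent_frac,
                         amp_median = 25, amp_sdlog = 0.3,
                         tau_rise = 2, tau_decay = 20, noise_sd = 0,
                         sampling_rate = 5000, seed,
                         polarity = "outward") {
  g <- gen_psc_trace(duration, event_rate, amp_median, amp_sdlog,
                     ap_dependent_frac, tau_rise, tau_decay, noise_sd,
                     sampling_rate, seed, polarity)
  post_seed <- derive_seeds(seed, 3L)[3L]
  mini <- g$events[!g$events$ap_dependent, , drop = FALSE]
  post <- render_psc_trace(mini, duration, sampling_rate, tau_rise,
                           tau_decay, noise_sd, seed = post_seed,
                           polarity = polarity)
  true_red <- if (nrow(g$events)) 100 * mean(g$events$ap_dependent) else NA_real_
  list(pre = g$trace, post = post, events = g$events,
       true_reduction_pct = true_red)
}

#' Generate an evoked synaptic sweep
#'
#' Sums one or more double-exponential components at given latencies after a
#' stimulus at `t = 0` (plus optional further stimuli), emulating evoked,
#' possibly polysynaptic, responses with multiple peaks. A pre-stimulus
#' baseline segment is prepended so baseline and noise can be estimated the
#' same way as in recordings.
#'
#' @param components data.frame with columns `latency` (ms after its
#'   stimulus), `amplitude` (pA), `tau_rise`, `tau_decay` (ms), and
#'   optionally `stim` (1-based index into `stim_times`; default 1).
#' @param noise_sd Gaussian noise SD, pA.
#' @param sampling_rate Hz.
#' @param stim_times stimulus times, s (default a single stimulus at 0.1 s
#'   into the sweep).
#' @param duration sweep duration, s.
#' @param seed required when `noise_sd > 0`.
#' @param polarity trace polarity.
#' @return list with `trace` (stimulus-annotated [current_trace()]) and
#'   `truth` (earliest-component latency/amplitude per stimulus).
#' @export
gen_evoked_sweep <- function(components, noise_sd = 0, sampling_rate = 10000,
                             stim_times = 0.1, duration = NULL, seed = NULL,
                             polarity = "outward") {
  stopifnot(is.data.frame(components),
            all(c("latency", "amplitude", "tau_rise", "tau_decay") %in%
                  names(components)))
  if (is.null(components$stim)) components$stim <- 1L
  if (is.null(duration))
    duration <- max(stim_times) + 0.5
  ev <- data.frame(
    time = stim_times[components$stim] + components$latency / 1000,
    amplitude = components$amplitude)
  n <- round(duration * sampling_rate)
  x <- numeric(n)
  for (i in seq_len(nrow(components))) {
    kern_len <- min(n, ceiling((components$tau_decay[i] / 1000 * 8 +
                                  components$tau_rise[i] / 1000 * 2) *
                                 sampling_rate))
    kt <- (seq_len(kern_len) - 1L) / sampling_rate
    kern <- psc_kernel(kt, components$tau_rise[i], components$tau_decay[i])
    i0 <- floor(ev$time[i] * sampling_rate) + 1L
    idx <- i0:min(n, i0 + kern_len - 1L)
    x[idx] <- x[idx] + ev$amplitude[i] * kern[seq_along(idx)]
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    x <- x + with_rng(seed, stats::rnorm(n, 0, noise_sd))
  }
  if (polarity == "inward") x <- -x
  earliest <- do.call(rbind, lapply(split(components, components$stim),
    function(d) d[which.min(d$latency), c("stim", "latency", "amplitude")]))
  list(trace = current_trace(x, sampling_rate, stim_times = stim_times,
                             polarity = polarity),
       truth = earliest)
}

#' Generate the current response to a voltage step (RC circuit)
#'
#' Single-compartment voltage-clamp model: series resistance `Rs` in series
#' with the membrane (`Rm` parallel `Cm`). A command step `dV` produces an
#' instantaneous jump `dV/Rs` relaxing with
#' `tau = Cm * Rs*Rm/(Rs+Rm)` to the steady state `dV/(Rs+Rm)`.
#' This is the standard seal-test waveform from which passive membrane
#' properties are measured.
#'
#' @param Rm membrane resistance, MOhm.
#' @param Cm membrane capacitance, pF.
#' @param Rs series (access) resistance, MOhm.
#' @param dV command step, mV (default 10).
#' @param sampling_rate Hz (default 50 kHz; the transient is ~1 ms).
#' @param baseline_s pre-step baseline, s.
#' @param step_s step duration, s.
#' @param noise_sd Gaussian noise SD, pA.
#' @param seed required when `noise_sd > 0`.
#' @return list with `trace` (a [current_trace()], stimulus annotation at
#'   the step onset) and `truth` (list: `tau_ms`, `I_ss_pA`, `I0_pA`).
#' @export
gen_rc_step <- function(Rm, Cm, Rs, dV = 10, sampling_rate = 50000,
                        baseline_s = 0.02, step_s = 0.08, noise_sd = 0,
                        seed = NULL) {
  stopifnot(Rm > 0, Cm > 0, Rs > 0, dV != 0)
  tau_s <- (Rs * Rm / (Rs + Rm)) * Cm * 1e-6   # MOhm * pF = us
  I_ss <- 1000 * dV / (Rs + Rm)                # mV/MOhm -> nA; *1000 -> pA
  I0 <- 1000 * dV / Rs
  n_base <- round(baseline_s * sampling_rate)
  n_step <- round(step_s * sampling_rate)
  t_step <- (seq_len(n_step) - 1L) / sampling_rate
  x <- c(numeric(n_base), I_ss + (I0 - I_ss) * exp(-t_step / tau_s))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    x <- x + with_rng(seed, stats::rnorm(length(x), 0, noise_sd))
  }
  list(trace = current_trace(x, sampling_rate, stim_times = baseline_s,
                             polarity = "outward"),
       truth = list(tau_ms = tau_s * 1000, I_ss_pA = I_ss, I0_pA = I0))
}
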