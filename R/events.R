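#' Detect spontaneous postsynaptic currents by sliding template fit
#'
#' Clements-Bekkers style detector: a double-exponential template is slid
#' along the (polarity-rectified) trace; at each offset the optimal scale
#' and offset of the template are fit by least squares in closed form. A
#' candidate event requires both (a) a fitted scale above `threshold_sd`
#' times the robust noise SD (MAD of first differences, insensitive to the
#' events themselves) - the amplitude gate - and (b) a detection criterion
#' (fitted scale over its standard error) above `threshold_sd` - the shape
#' gate that rejects drifts scaling unlike the template. Onsets are
#' prominent local maxima of the criterion; candidates closer than
#' `min_iei` are merged. Each event's amplitude is its peak minus the local
#' pre-onset baseline. Rise time (10-90%) and a single-exponential decay
#' constant (fit from peak to 10% of peak, log-linear) are measured per
#' event; a fit without enough clean samples yields `NA`, never an error.
#'
#' A later event inside the fit window biases the template fit at an
#' earlier event's alignment, so after the first pass the detected events
#' are reconstructed from the template, subtracted, and the residual is
#' scanned again (`refine_passes` times); events found only in a residual
#' pass are typically the earlier, smaller member of a close pair.
#'
#' All sliding sums are computed with cumulative sums and an FFT
#' cross-correlation, so each pass is linear in trace length.
#'
#' @param trace a [current_trace()].
#' @param threshold_sd threshold multiplier for both gates (default 3).
#' @param template_rise,template_decay template time constants, ms
#'   (defaults 2 and 20, typical IPSC kinetics at room temperature).
#' @param min_iei minimum interevent interval, ms; closer detections are
#'   merged (default 5).
#' @param refine_passes subtract-and-redetect passes (default 1).
#' @return data.frame with `time` (onset, s), `amplitude` (pA, positive),
#'   `rise_time` (ms), `decay_tau` (ms), `criterion`.
#' @export
detect_events <- function(trace, threshold_sd = 3, template_rise = 2,
                          template_decay = 20, min_iei = 5,
                          refine_passes = 1L) {
  stopifnot(inherits(trace, "current_trace"))
  fs <- trace$sampling_rate
  x <- rectified(trace)
  n <- length(x)
  tpl_len <- ceiling((template_rise * 2 + template_decay * 2.5) / 1000 * fs)
  if (n <= tpl_len + 2L)
    stop("trace shorter than the detection template", call. = FALSE)
  # noise floor from first differences: the MAD of x itself is inflated by
  # the (slow) events, while successive differences are dominated by noise
  noise_sd <- stats::mad(diff(x)) / sqrt(2)
  if (noise_sd == 0 && stats::sd(x) == 0) {  # all-constant trace
    return(empty_events())
  }
  tpl <- psc_kernel((seq_len(tpl_len) - 1L) / fs, template_rise, template_decay)
  det <- cb_pass(x, fs, tpl, noise_sd, threshold_sd, min_iei)
  for (p in seq_len(refine_passes)) {
    if (!nrow(det)) break
    recon <- reconstruct_events(det, n, fs, template_rise, template_decay)
    det2 <- cb_pass(x - recon, fs, tpl, noise_sd, threshold_sd, min_iei)
    if (!nrow(det2)) break
    is_new <- vapply(det2$time, function(t)
      min(abs(det$time - t)) >= min_iei / 1000, logical(1))
    if (!any(is_new)) break
    det <- rbind(det, det2[is_new, , drop = FALSE])
    det <- det[order(det$time), , drop = FALSE]
  }
  rownames(det) <- NULL
  det
}

#' Render detected events back into a trace from the template
#' @keywords internal
reconstruct_events <- function(det, n, fs, template_rise, template_decay) {
  recon <- numeric(n)
  kern_len <- min(n, ceiling((template_decay * 8 + template_rise * 2) /
                               1000 * fs))
  kern <- psc_kernel((seq_len(kern_len) - 1L) / fs, template_rise,
                     template_decay)
  for (i in seq_len(nrow(det))) {
    i0 <- round(det$time[i] * fs) + 1L
    idx <- i0:min(n, i0 + kern_len - 1L)
    recon[idx] <- recon[idx] + det$amplitude[i] * kern[seq_along(idx)]
  }
  recon
}

#' One Clements-Bekkers detection pass over a rectified sample vector
#' @keywords internal
cb_pass <- function(x, fs, tpl, noise_sd, threshold_sd, min_iei) {
  n <- length(x)
  m <- length(tpl)
  sum_t <- sum(tpl); sum_t2 <- sum(tpl^2)
  # sliding sums over every window of length m
  cx <- c(0, cumsum(x)); cx2 <- c(0, cumsum(x^2))
  n_win <- n - m + 1L
  sum_w <- cx[(m + 1L):(n + 1L)] - cx[1L:n_win]
  sum_w2 <- cx2[(m + 1L):(n + 1L)] - cx2[1L:n_win]
  # sliding sum of t*w via FFT cross-correlation, zero-padded to a
  # 2-3-5-smooth length so the transform stays O(n log n)
  N <- stats::nextn(n + m, c(2, 3, 5))
  xp <- c(x, numeric(N - n))
  tp <- c(tpl, numeric(N - m))
  sum_tw <- Re(stats::fft(stats::fft(xp) * Conj(stats::fft(tp)),
                          inverse = TRUE))[seq_len(n_win)] / N
  denom <- sum_t2 - sum_t^2 / m
  scale <- (sum_tw - sum_t * sum_w / m) / denom
  offset <- (sum_w - scale * sum_t) / m
  sse <- sum_w2 + scale^2 * sum_t2 + m * offset^2 -
    2 * (scale * sum_tw + offset * sum_w - scale * offset * sum_t)
  sse <- pmax(sse, 0)
  se <- sqrt(sse / (m - 1)) / sqrt(denom)
  # se = 0 happens on noise-free traces where the template fits exactly:
  # a positive fitted scale there is an unambiguous detection
  crit <- ifelse(se > 0, scale / se, ifelse(scale > 0, Inf, 0))
  amp_floor <- max(threshold_sd * noise_sd, 1e-6)
  above <- scale > amp_floor & crit > threshold_sd
  if (!any(above)) return(empty_events())
  # candidate onsets: prominent local maxima of the criterion, so that one
  # supra-threshold run can yield several events (events closer than a
  # template length) while noise wiggles on a single event's criterion
  # profile (prominence < threshold) are not split off
  finite_crit <- crit
  big <- max(crit[is.finite(crit)], 1) * 2
  finite_crit[is.infinite(crit)] <- big
  pk <- find_response_peaks(finite_crit, fs, height = threshold_sd,
                            prominence = threshold_sd, smooth_ms = 0.6,
                            max_scan = 2L * m)
  onsets <- pk$idx[above[pk$idx]]
  if (!length(onsets)) {  # degenerate profile (e.g. plateau at the edge)
    onsets <- which(above)[which.max(crit[above])]
  }
  # merge onsets closer than min_iei, keeping the stronger criterion
  min_gap <- min_iei / 1000 * fs
  onsets <- onsets[order(onsets)]
  keep <- rep(TRUE, length(onsets))
  last <- 1L
  for (i in seq_along(onsets)[-1L]) {
    if (onsets[i] - onsets[last] < min_gap) {
      if (crit[onsets[i]] > crit[onsets[last]]) {
        keep[last] <- FALSE; last <- i
      } else keep[i] <- FALSE
    } else last <- i
  }
  onsets <- onsets[keep]
  measure_one <- function(i0) {
    win_end <- min(n, i0 + m - 1L)
    base_start <- max(1L, i0 - round(0.005 * fs))
    base <- stats::median(x[base_start:i0])
    seg <- x[i0:win_end] - base
    pk_rel <- which.max(seg)
    amp <- seg[pk_rel]
    # 10-90% rise on the rising limb
    rise <- NA_real_
    r10 <- which(seg[seq_len(pk_rel)] >= 0.1 * amp)[1L]
    r90 <- which(seg[seq_len(pk_rel)] >= 0.9 * amp)[1L]
    if (!is.na(r10) && !is.na(r90) && r90 >= r10)
      rise <- (r90 - r10) / fs * 1000
    decay <- fit_decay_tau(seg, pk_rel, fs)
    c(time = (i0 - 1L) / fs, amplitude = amp, rise_time = rise,
      decay_tau = decay, criterion = crit[i0])
  }
  out <- as.data.frame(t(vapply(onsets, measure_one, numeric(5))))
  out[out$amplitude > 0, , drop = FALSE]
}

empty_events <- function() {
  data.frame(time = numeric(0), amplitude = numeric(0),
             rise_time = numeric(0), decay_tau = numeric(0),
             criterion = numeric(0))
}

#' Log-linear single-exponential decay fit (peak down to a floor)
#'
#' Fits `log(y) ~ t` from the peak until the trace first drops below
#' `floor` (default 10% of the peak). Near-zero noisy samples make the
#' log-linear slope unstable, so callers on noisy data should raise the
#' floor to a few noise SDs.
#' @keywords internal
fit_decay_tau <- function(seg, pk_rel, fs, floor = NULL) {
  tail_seg <- seg[pk_rel:length(seg)]
  if (is.null(floor)) floor <- 0.1 * seg[pk_rel]
  floor <- max(floor, 0.1 * seg[pk_rel])
  below <- which(tail_seg <= floor)[1L]
  end <- if (is.na(below)) length(tail_seg) else below
  if (end < 4L) return(NA_real_)
  y <- tail_seg[seq_len(end)]
  ok <- y > 0
  if (sum(ok) < 4L) return(NA_real_)
  t_ms <- ((seq_len(end) - 1L) / fs * 1000)[ok]
  fit <- stats::lm.fit(cbind(1, t_ms), log(y[ok]))
  slope <- fit$coefficients[2L]
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  unname(-1 / slope)
}

#' Event frequency
#' @param events event table (data.frame) or event count.
#' @param duration recording duration, s (> 0).
#' @return events per second, Hz.
#' @export
event_frequency <- function(events, duration) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / duration
}

#' Amplitude histogram in fixed-width bins
#'
#' Counts events in left-closed, right-open amplitude bins
#' `[first_edge, first_edge + bin_width)`, ... (default 10 pA bins starting
#' at 10 pA, the smallest reported bin). Events below `first_edge` are not
#' binned but their count is reported, so total event count is conserved.
#'
#' @param amplitudes event amplitudes, pA (or an event data.frame with an
#'   `amplitude` column).
#' @param bin_width bin width, pA (default 10).
#' @param first_edge lower edge of the first bin, pA (default 10).
#' @param n_bins number of bins; default spans the data.
#' @return list of class `amplitude_histogram`: `breaks`, `counts`
#'   (named `"[lo,hi)"`), `below_first_edge`, `n_total`.
#' @export
amplitude_histogram <- function(amplitudes, bin_width = 10, first_edge = 10,
                                n_bins = NULL) {
  if (is.data.frame(amplitudes)) amplitudes <- amplitudes$amplitude
  stopifnot(bin_width > 0)
  n_total <- length(amplitudes)
  below <- sum(amplitudes < first_edge)
  if (is.null(n_bins)) {
    hi <- if (any(amplitudes >= first_edge)) max(amplitudes) else first_edge
    n_bins <- max(1L, ceiling((hi - first_edge) / bin_width + 1e-9))
  }
  breaks <- first_edge + bin_width * (0:n_bins)
  idx <- floor((amplitudes - first_edge) / bin_width) + 1L
  idx <- idx[amplitudes >= first_edge & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  names(counts) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1L])
  structure(list(breaks = breaks, counts = counts,
                 below_first_edge = below, n_total = n_total),
            class = "amplitude_histogram")
}

#' Interevent intervals and their empirical CDF
#'
#' @param events event table (with `time` column) or numeric event times, s.
#' @return list of class `iei_distribution`: `ieis` (s) and `ecdf`
#'   (a [stats::ecdf()] function); `NULL` fields when fewer than 2 events.
#' @export
iei_distribution <- function(events) {
  tt <- if (is.data.frame(events)) events$time else as.numeric(events)
  tt <- sort(tt)
  ieis <- diff(tt)
  structure(
    list(ieis = ieis,
         ecdf = if (length(ieis) >= 1L) stats::ecdf(ieis) else NULL),
    class = "iei_distribution")
}

#' Compare two interevent-interval distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the interval samples, plus the
#' direction of the shift: `"left"` when sample `a` has the smaller median
#' (more short intervals, i.e. higher event frequency), `"right"` when
#' larger, `"none"` when equal. A left shift of the cumulative interevent
#' interval distribution is the signature of increased spontaneous event
#' frequency.
#'
#' @param a,b numeric interval samples (s), or `iei_distribution` objects.
#' @return list of class `ecdf_comparison`: `D`, `p_value`, `shift`,
#'   `n_a`, `n_b`.
#' @export
compare_ecdf <- function(a, b) {
  if (inherits(a, "iei_distribution")) a <- a$ieis
  if (inherits(b, "iei_distribution")) b <- b$ieis
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 intervals in each sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b))
  med_a <- stats::median(a); med_b <- stats::median(b)
  shift <- if (med_a < med_b) "left" else if (med_a > med_b) "right" else "none"
  structure(list(D = unname(kt$statistic), p_value = kt$p.value,
                 shift = shift, n_a = length(a), n_b = length(b)),
            class = "ecdf_comparison")
}

#' Percent reduction in event frequency
#'
#' `100 * (freq_pre - freq_post) / freq_pre`; used for the drop in
#' spontaneous IPSC frequency after TTX, whose magnitude estimates the
#' action-potential-dependent fraction of events.
#'
#' @param freq_pre pre-treatment frequency, Hz (> 0).
#' @param freq_post post-treatment frequency, Hz (>= 0).
#' @return percent reduction (negative if frequency increased).
#' @export
percent_reduction <- function(freq_pre, freq_post) {
  if (any(freq_pre <= 0)) stop("freq_pre must be positive", call. = FALSE)
  100 * (freq_pre - freq_post) / freq_pre
}

#' Match detected events to a ground-truth table
#'
#' Greedy nearest-neighbour matching within `tol_ms`: each truth event can
#' absorb at most one detection. Reports precision (matched / detected) and
#' recall (matched / truth).
#'
#' @param detected,truth data.frames with a `time` column (s).
#' @param tol_ms matching tolerance, ms (default 5).
#' @return list: `precision`, `recall`, `n_matched`, `n_detected`,
#'   `n_truth`.
#' @export
benchmark_detection <- function(detected, truth, tol_ms = 5) {
  td <- detected$time; tt <- truth$time
  n_d <- length(td); n_t <- length(tt)
  if (n_d == 0L || n_t == 0L)
    return(list(precision = if (n_d == 0L) NA_real_ else 0,
                recall = if (n_t == 0L) NA_real_ else 0,
                n_matched = 0L, n_detected = n_d, n_truth = n_t))
  tol <- tol_ms / 1000
  used <- rep(FALSE, n_t)
  matched <- 0L
  for (i in order(td)) {
    j <- which(!used & abs(tt - td[i]) <= tol)
    if (length(j)) {
      j <- j[which.min(abs(tt[j] - td[i]))]
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(precision = matched / n_d, recall = matched / n_t,
       n_matched = matched, n_detected = n_d, n_truth = n_t)
}
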