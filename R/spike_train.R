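#' Construct a spike train
#'
#' A spike train is the unit of regularity analysis: an ordered vector of
#' spike times (seconds) within a recording of known duration, tagged with a
#' cell identifier and a group label (e.g. genotype).
#'
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing, all in `[0, duration)`.
#' @param duration recording duration in seconds (> 0).
#' @param cell_id identifier for the cell.
#' @param group group label (e.g. `"WT"`, `"HD"`).
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, duration, cell_id = "cell", group = NA_character_) {
  times <- as.numeric(times)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0)
    stop("duration must be a single positive number", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("spike times must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing (no duplicates)", call. = FALSE)
  if (length(times) && (times[1L] < 0 || times[length(times)] >= duration))
    stop("spike times must lie in [0, duration)", call. = FALSE)
  structure(
    list(times = times, duration = duration,
         cell_id = as.character(cell_id), group = as.character(group)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s): %d spikes over %.1f s (%.2f Hz)\n",
              x$cell_id, x$group, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Generate a renewal-process or bursting spike train
#'
#' Simulates the three firing modes seen in cell-attached recordings of
#' tonically active striatal cholinergic interneurons:
#'
#' * `"regular"` / `"irregular"`: a gamma renewal process. Interspike
#'   intervals are i.i.d. Gamma with shape `k = 1/cv^2` and scale
#'   `1/(rate * k)`, so the ISI mean is `1/rate` and the ISI coefficient of
#'   variation is `cv` (`cv = 0` degenerates to a perfectly periodic train).
#'   The two labels share one mechanism; the label records the intent
#'   (low vs high ISI dispersion) and is carried into ground-truth tables.
#' * `"bursting"`: an alternating renewal process. Burst length (spike
#'   count) is geometric with the given mean, within-burst ISIs are gamma
#'   at `burst_rate` (cv 0.3), and inter-burst pauses are exponential with
#'   the given mean, mimicking phasic burst-and-pause firing.
#'
#' The first spike is placed at `phase * first_isi` so that periodic trains
#' are not phase-locked across cells; `phase` defaults to a seed-driven
#' uniform draw.
#'
#' @param pattern one of `"regular"`, `"irregular"`, `"bursting"`.
#' @param rate target mean firing rate, Hz (> 0). For bursting trains this
#'   is the within-burst rate; overall rate also depends on pauses.
#' @param cv target ISI coefficient of variation (>= 0); ignored for
#'   `"bursting"`.
#' @param duration recording duration, s (> 0).
#' @param seed integer seed; fully determines the train.
#' @param burst_params list with `burst_rate` (Hz), `mean_burst_len`
#'   (spikes), `mean_pause` (s); only used for `pattern = "bursting"`.
#'   `mean_pause = NULL` (default) derives the pause from `rate` so the
#'   overall firing rate matches the target:
#'   `pause = len/rate - (len - 1)/burst_rate`.
#' @param phase optional fraction in `[0, 1)` of the first ISI at which the
#'   first spike is placed; `NULL` (default) draws it uniformly.
#' @param cell_id,group passed to [spike_train()].
#' @return a [spike_train()].
#' @examples
#' tr <- gen_spike_train("regular", rate = 1, cv = 0, duration = 10,
#'                       seed = 1, phase = 0.5)
#' tr$times  # 0.5, 1.5, ..., 9.5
#' @export
gen_spike_train <- function(pattern = c("regular", "irregular", "bursting"),
                            rate, cv = NULL, duration, seed,
                            burst_params = list(burst_rate = 10,
                                                mean_burst_len = 5,
                                                mean_pause = NULL),
                            phase = NULL,
                            cell_id = "cell", group = NA_character_) {
  pattern <- match.arg(pattern)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (pattern != "bursting") {
    if (is.null(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  }
  times <- with_rng(seed, {
    ph <- if (is.null(phase)) stats::runif(1) else phase
    if (pattern == "bursting") {
      bp <- burst_params
      if (is.null(bp$mean_pause)) {
        # choose the pause so the overall rate hits the target:
        # one cycle = (len - 1)/burst_rate spiking + pause, len spikes
        bp$mean_pause <- max(bp$mean_burst_len / rate -
                               (bp$mean_burst_len - 1) / bp$burst_rate,
                             0.05)
      }
      # within-burst ISIs are dispersed (cv 0.4) and each burst gets its own
      # rate multiplier, so the intra-burst rhythm is not a periodicity the
      # autocorrelogram should lock onto
      k_wb <- 1 / 0.4^2
      ts <- numeric(0)
      t <- stats::rexp(1, 1 / bp$mean_pause) * ph
      while (t < duration) {
        n_burst <- 1L + stats::rgeom(1, 1 / bp$mean_burst_len)
        burst_rate_i <- bp$burst_rate * stats::rlnorm(1, 0, 0.25)
        isis <- stats::rgamma(n_burst - 1L, shape = k_wb,
                              scale = 1 / (burst_rate_i * k_wb))
        burst_ts <- t + cumsum(c(0, isis))
        ts <- c(ts, burst_ts)
        t <- burst_ts[length(burst_ts)] + stats::rexp(1, 1 / bp$mean_pause)
      }
      ts[ts < duration]
    } else {
      mean_isi <- 1 / rate
      n_max <- ceiling(duration * rate * 1.5 + 10 * sqrt(duration * rate) + 20)
      isis <- if (cv == 0) rep(mean_isi, n_max) else {
        k <- 1 / cv^2
        stats::rgamma(n_max, shape = k, scale = 1 / (rate * k))
      }
      ts <- cumsum(isis) - isis[1L] * (1 - ph)
      while (ts[length(ts)] < duration) {  # top up in the rare short case
        extra <- if (cv == 0) rep(mean_isi, n_max) else {
          k <- 1 / cv^2
          stats::rgamma(n_max, shape = k, scale = 1 / (rate * k))
        }
        ts <- c(ts, ts[length(ts)] + cumsum(extra))
      }
      ts[ts >= 0 & ts < duration]
    }
  })
  times <- sort(unique(times))
  spike_train(times, duration, cell_id = cell_id, group = group)
}
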