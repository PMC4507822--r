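#' Read and write spike-time tables
#'
#' Spike tables are UTF-8 CSVs with a mandatory header
#' `cell_id,group,time_s`; times are seconds and must be strictly
#' increasing within each cell. Units are carried in the column names.
#'
#' @param trains list of [spike_train()] objects (for writing).
#' @param path file path.
#' @param duration recording duration, s, applied to all cells on reading
#'   (a `# duration_s=` comment written by [write_spike_csv()] is honoured).
#' @return `write_spike_csv` returns `path` invisibly; `read_spike_csv`
#'   returns a named list of [spike_train()] objects.
#' @export
write_spike_csv <- function(trains, path) {
  rows <- lapply(trains, function(tr)
    if (length(tr$times))
      data.frame(cell_id = tr$cell_id, group = tr$group, time_s = tr$times)
    else NULL)
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(cell_id = character(0), group = character(0),
                     time_s = numeric(0))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  durs <- vapply(trains, `[[`, numeric(1), "duration")
  writeLines(sprintf("# duration_s=%s",
                     paste(format(durs, digits = 17), collapse = ",")), con)
  writeLines(sprintf("# cells=%s",
                     paste(vapply(trains, `[[`, character(1), "cell_id"),
                           collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path, duration = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || !grepl("^cell_id,group,time_s", body[1L]))
    stop("spike CSV must have header cell_id,group,time_s: ", path,
         call. = FALSE)
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  durs <- NULL; ids <- NULL
  dl <- grep("^# duration_s=", meta, value = TRUE)
  il <- grep("^# cells=", meta, value = TRUE)
  if (length(dl)) durs <- as.numeric(strsplit(sub("^# duration_s=", "", dl[1L]),
                                              ",")[[1L]])
  if (length(il)) ids <- strsplit(sub("^# cells=", "", il[1L]), ",")[[1L]]
  if (is.null(ids)) ids <- unique(df$cell_id)
  if (is.null(durs)) {
    if (is.null(duration))
      stop("no duration metadata in file; pass duration=", call. = FALSE)
    durs <- rep(duration, length(ids))
  }
  out <- list()
  for (i in seq_along(ids)) {
    sub <- df[df$cell_id == ids[i], , drop = FALSE]
    tt <- sub$time_s
    if (is.unsorted(tt, strictly = TRUE))
      stop(sprintf("spike times for cell %s are not strictly increasing (%s)",
                   ids[i], path), call. = FALSE)
    grp <- if (nrow(sub)) sub$group[1L] else NA_character_
    out[[ids[i]]] <- spike_train(tt, durs[i], cell_id = ids[i], group = grp)
  }
  out
}

#' Read and write detected-event tables
#'
#' CSV with header `cell_id,time_s,amplitude_pA` (extra columns such as
#' `rise_time_ms`, `decay_tau_ms` are preserved).
#'
#' @param events data.frame with at least `time` (s) and `amplitude` (pA).
#' @param path file path.
#' @param cell_id identifier written alongside each event.
#' @return the path (write) or a data.frame (read).
#' @export
write_event_csv <- function(events, path, cell_id = "cell") {
  df <- data.frame(cell_id = cell_id, time_s = events$time,
                   amplitude_pA = events$amplitude)
  if (!is.null(events$rise_time)) df$rise_time_ms <- events$rise_time
  if (!is.null(events$decay_tau)) df$decay_tau_ms <- events$decay_tau
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_s", "amplitude_pA")
  if (!all(need %in% names(df)))
    stop("event CSV must have columns ", paste(need, collapse = ","),
         ": ", path, call. = FALSE)
  out <- data.frame(cell_id = df$cell_id, time = df$time_s,
                    amplitude = df$amplitude_pA)
  if (!is.null(df$rise_time_ms)) out$rise_time <- df$rise_time_ms
  if (!is.null(df$decay_tau_ms)) out$decay_tau <- df$decay_tau_ms
  out
}

#' Read and write per-slice stereology tables
#'
#' CSV with header `slice_index,area_mm2,raw_count,mean_diameter_um`.
#'
#' @param slices data.frame as produced by [gen_sections()].
#' @param path file path.
#' @return the path (write) or the slice data.frame (read).
#' @export
write_stereology_csv <- function(slices, path) {
  utils::write.csv(
    slices[, c("slice_index", "area_mm2", "raw_count", "mean_diameter_um")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stereology_csv
#' @export
read_stereology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice_index", "area_mm2", "raw_count", "mean_diameter_um")
  if (!all(need %in% names(df)))
    stop("stereology CSV must have columns ", paste(need, collapse = ","),
         ": ", path, call. = FALSE)
  if (any(df$area_mm2 < 0)) stop("negative slice area: ", path, call. = FALSE)
  df
}

#' Read and write current traces as annotated CSV
#'
#' The trace container is a CSV with a commented metadata header:
#' ```
#' # lciphys-trace v1
#' # fs_hz=5000
#' # holding_mV=-70
#' # polarity=outward
#' # stim_times_s=0.1,0.125
#' current_pA
#' ...
#' ```
#' A file without `fs_hz` is rejected (samples are meaningless without the
#' sampling rate).
#'
#' @param trace a [current_trace()].
#' @param path file path.
#' @return the path (write) or a [current_trace()] (read).
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# lciphys-trace v1",
               sprintf("# fs_hz=%s", format(trace$sampling_rate, digits = 17)),
               sprintf("# holding_mV=%s",
                       format(trace$holding_potential, digits = 17)),
               sprintf("# polarity=%s", trace$polarity),
               sprintf("# stim_times_s=%s",
                       paste(format(trace$stim_times, digits = 17),
                             collapse = ","))), con)
  writeLines("current_pA", con)
  writeLines(format(trace$samples, digits = 17, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    l <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (!length(l)) return(NULL)
    sub(paste0("^# ", key, "="), "", l[1L])
  }
  fs <- get_meta("fs_hz")
  if (is.null(fs))
    stop("trace container missing fs_hz metadata: ", path, call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1L] != "current_pA")
    stop("trace container must have a current_pA column: ", path,
         call. = FALSE)
  hv <- get_meta("holding_mV")
  st <- get_meta("stim_times_s")
  current_trace(
    as.numeric(body[-1L]), as.numeric(fs),
    holding_potential = if (is.null(hv) || hv == "NA") NA_real_
                        else as.numeric(hv),
    stim_times = if (is.null(st) || st == "") numeric(0)
                 else as.numeric(strsplit(st, ",")[[1L]]),
    polarity = get_meta("polarity") %||% "outward")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a study configuration file
#'
#' Loads a cohort/study configuration from YAML (or JSON) into the nested
#' list [gen_cohort()] consumes. Only fields present in the file override
#' the package defaults; see [default_cohort_config()] for the full schema.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a named list suitable for `gen_cohort(config = ...)`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
}

#' Write a study bundle to disk
#'
#' Writes the spike table, per-group trace containers, stereology tables
#' and a JSON manifest of all ground truth under `dir`.
#'
#' @param bundle a `study_bundle` from [gen_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spike_csv(bundle$spikes, file.path(dir, "spikes.csv"))
  utils::write.csv(bundle$cells, file.path(dir, "cells_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  for (g in names(bundle$ttx)) {
    write_trace_csv(bundle$ttx[[g]]$pre,
                    file.path(dir, sprintf("psc_pre_%s.csv", g)))
    write_trace_csv(bundle$ttx[[g]]$post,
                    file.path(dir, sprintf("psc_post_%s.csv", g)))
    write_trace_csv(bundle$rc[[g]]$trace,
                    file.path(dir, sprintf("rc_step_%s.csv", g)))
    write_stereology_csv(bundle$stereology[[g]],
                         file.path(dir, sprintf("stereology_%s.csv", g)))
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full study pipeline on a cohort
#'
#' Executes every analysis stage on a (typically generated) study bundle
#' and assembles the study report:
#'
#' 1. **spikes**: per-cell ISI statistics, autocorrelogram classification,
#'    CV dichotomy; per-group class proportions with a Fisher exact test on
#'    each 2x2 classification table; the frequency-CV regression per group.
#' 2. **events**: PSC detection on the pre/post-TTX traces, frequencies,
#'    amplitude histograms, interevent-interval comparison across groups,
#'    TTX percent reduction.
#' 3. **traces**: passive membrane properties from each group's RC step.
#' 4. **stereology**: Cavalieri volume, Abercrombie-corrected count and
#'    density per group.
#'
#' The report is a plain list (serializable with
#' [write_study_report()]); identical bundle and parameters give an
#' identical report.
#'
#' @param bundle a `study_bundle` from [gen_cohort()] (or assembled from
#'   files with the read functions).
#' @param cv_cutoff CV dichotomy cutoff (default 0.2).
#' @param detect_args list of arguments for [detect_events()].
#' @return list of class `study_report`.
#' @export
run_study <- function(bundle, cv_cutoff = 0.2, detect_args = list()) {
  stopifnot(inherits(bundle, "study_bundle") || is.list(bundle))
  groups <- unique(vapply(bundle$spikes, `[[`, character(1), "group"))
  if (!length(groups)) groups <- names(bundle$ttx)

  per_cell <- do.call(rbind, lapply(bundle$spikes, function(tr) {
    st <- compute_isis(tr)
    cl <- classify_train(tr)
    data.frame(cell_id = tr$cell_id, group = tr$group, n_spikes = st$n_spikes,
               rate = st$rate, cv = st$cv,
               regularity_class = cl$regularity_class,
               first_peak_coefficient = cl$first_peak_coefficient,
               n_peaks = cl$n_peaks,
               cv_class = cv_class(st$cv, cv_cutoff))
  }))
  if (!is.null(per_cell)) rownames(per_cell) <- NULL

  proportions <- NULL; fisher_cv <- NULL; fisher_high <- NULL
  regressions <- list()
  if (!is.null(per_cell) && length(groups) == 2L) {
    g1 <- per_cell[per_cell$group == groups[1L], ]
    g2 <- per_cell[per_cell$group == groups[2L], ]
    tab_cv <- rbind(
      c(sum(g1$cv_class == "low_cv", na.rm = TRUE),
        sum(g1$cv_class == "high_cv", na.rm = TRUE)),
      c(sum(g2$cv_class == "low_cv", na.rm = TRUE),
        sum(g2$cv_class == "high_cv", na.rm = TRUE)))
    tab_high <- rbind(
      c(sum(g1$regularity_class == "high"),
        sum(g1$regularity_class != "high")),
      c(sum(g2$regularity_class == "high"),
        sum(g2$regularity_class != "high")))
    fisher_cv <- fisher_exact(tab_cv)
    fisher_high <- fisher_exact(tab_high)
    proportions <- data.frame(
      group = groups,
      n = c(nrow(g1), nrow(g2)),
      low_cv = tab_cv[, 1L], high_autocorr = tab_high[, 1L])
    for (g in groups) {
      sub <- per_cell[per_cell$group == g & is.finite(per_cell$cv), ]
      regressions[[g]] <- if (nrow(sub) >= 3L)
        frequency_cv_relationship(sub$rate, sub$cv) else NULL
    }
  }

  events <- list()
  for (g in names(bundle$ttx)) {
    pair <- bundle$ttx[[g]]
    dur <- trace_duration(pair$pre)
    det_pre <- do.call(detect_events, c(list(pair$pre), detect_args))
    det_post <- do.call(detect_events, c(list(pair$post), detect_args))
    f_pre <- event_frequency(det_pre, dur)
    f_post <- event_frequency(det_post, trace_duration(pair$post))
    events[[g]] <- list(
      frequency_pre = f_pre, frequency_post = f_post,
      reduction_pct = if (f_pre > 0) percent_reduction(f_pre, f_post)
                      else NA_real_,
      amplitude_histogram = amplitude_histogram(det_pre),
      iei = iei_distribution(det_pre),
      mean_amplitude = if (nrow(det_pre)) mean(det_pre$amplitude) else NA_real_,
      n_events = nrow(det_pre))
  }
  iei_comparison <- if (length(events) == 2L &&
                        length(events[[1L]]$iei$ieis) >= 2L &&
                        length(events[[2L]]$iei$ieis) >= 2L)
    compare_ecdf(events[[1L]]$iei, events[[2L]]$iei) else NULL

  passive <- lapply(bundle$rc, function(r) passive_properties(r$trace))
  stereo <- lapply(bundle$stereology, function(s)
    corrected_density(s, thickness_um = attr(s, "truth")$thickness_um %||% 30))

  structure(
    list(per_cell = per_cell, proportions = proportions,
         fisher_cv = fisher_cv, fisher_high_autocorr = fisher_high,
         frequency_cv = regressions, events = events,
         iei_comparison = iei_comparison, passive = passive,
         stereology = stereo,
         provenance = list(
           schema_version = "1",
           seed = bundle$manifest$seed %||% NA,
           cv_cutoff = cv_cutoff,
           detect_args = detect_args,
           iei_test = "two-sample Kolmogorov-Smirnov",
           package_version = as.character(utils::packageVersion("lciphys")))),
    class = "study_report")
}

#' Serialize a study report to JSON (plus per-cell CSV)
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$per_cell))
    utils::write.csv(report$per_cell, file.path(dir, "per_cell.csv"),
                     row.names = FALSE, quote = FALSE)
  ser <- rapply(unclass(report), function(x) {
    if (inherits(x, "ecdf")) NULL else x
  }, how = "replace", classes = "function")
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(dir)
}
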