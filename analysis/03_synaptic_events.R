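#!/usr/bin/env Rscript
# Stage 3: spontaneous synaptic-current analysis.
#
# Detects PSCs on each group's pre- and post-TTX traces, then compares
# groups on event frequency, the 10 pA amplitude-bin histogram, the
# cumulative interevent-interval distribution (two-sample KS), and the
# percent reduction in frequency after TTX (the action-potential-dependent
# share of events).

suppressPackageStartupMessages(library(lciphys))

groups <- c("WT", "HD")
stats_rows <- list()
iei_samples <- list()

for (g in groups) {
  pre <- read_trace_csv(sprintf("results/cohort/psc_pre_%s.csv", g))
  post <- read_trace_csv(sprintf("results/cohort/psc_post_%s.csv", g))
  dur <- trace_duration(pre)
  d_pre <- detect_events(pre)
  d_post <- detect_events(post)
  f_pre <- event_frequency(d_pre, dur)
  f_post <- event_frequency(d_post, trace_duration(post))
  red <- percent_reduction(f_pre, f_post)
  h <- amplitude_histogram(d_pre)
  iei_samples[[g]] <- iei_distribution(d_pre)
  write_event_csv(d_pre, sprintf("results/events_pre_%s.csv", g),
                  cell_id = g)
  stats_rows[[g]] <- data.frame(
    group = g, frequency_pre_hz = f_pre, frequency_post_hz = f_post,
    ttx_reduction_pct = red, mean_amplitude_pA = mean(d_pre$amplitude),
    n_events = nrow(d_pre))
  cat(sprintf("%s: %.2f Hz pre, %.2f Hz post TTX (%.0f%% reduction), %d events\n",
              g, f_pre, f_post, red, nrow(d_pre)))
  cat("  amplitude bins:", paste(sprintf("%s %d", names(h$counts)[1:4],
                                         h$counts[1:4]), collapse = ", "),
      "...\n")
}

cmp <- compare_ecdf(iei_samples[[2]], iei_samples[[1]])
cat(sprintf(
  "interevent intervals %s vs %s: KS D = %.3f, p = %s, %s shift in %s\n",
  groups[2], groups[1], cmp$D, format_pvalue(cmp$p_value), cmp$shift,
  groups[2]))

out <- do.call(rbind, stats_rows)
out$iei_ks_D <- cmp$D
out$iei_ks_p <- cmp$p_value
write.csv(out, "results/event_stats.csv", row.names = FALSE)
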