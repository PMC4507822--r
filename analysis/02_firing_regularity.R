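#!/usr/bin/env Rscript
# Stage 2: firing-pattern analysis of the cohort's spike trains.
#
# Per cell: ISI statistics (rate, CV), the binned spike-train
# autocorrelogram, the first-lag-period coefficient, and the three-way
# high/low/none regularity class. Per group: class proportions with Fisher
# exact tests (high-autocorrelation share and the CV < 0.2 share), the mean
# first-peak coefficient compared across groups, and the frequency-CV
# regression within each group.

suppressPackageStartupMessages(library(lciphys))

trains <- read_spike_csv("results/cohort/spikes.csv")
dir.create("results", showWarnings = FALSE)

per_cell <- do.call(rbind, lapply(trains, function(tr) {
  st <- compute_isis(tr)
  cl <- classify_train(tr)
  data.frame(cell_id = tr$cell_id, group = tr$group, rate = st$rate,
             cv = st$cv, regularity_class = cl$regularity_class,
             first_peak_coefficient = cl$first_peak_coefficient,
             n_peaks = cl$n_peaks, cv_class = cv_class(st$cv))
}))
rownames(per_cell) <- NULL
write.csv(per_cell, "results/regularity_per_cell.csv", row.names = FALSE)

groups <- unique(per_cell$group)
g1 <- per_cell[per_cell$group == groups[1], ]
g2 <- per_cell[per_cell$group == groups[2], ]

tab_high <- rbind(c(sum(g1$regularity_class == "high"),
                    sum(g1$regularity_class != "high")),
                  c(sum(g2$regularity_class == "high"),
                    sum(g2$regularity_class != "high")))
f_high <- fisher_exact(tab_high)
cat(sprintf("high autocorrelation: %s %d/%d (%.1f%%) vs %s %d/%d (%.1f%%), Fisher p = %s\n",
            groups[1], tab_high[1, 1], nrow(g1), 100 * tab_high[1, 1] / nrow(g1),
            groups[2], tab_high[2, 1], nrow(g2), 100 * tab_high[2, 1] / nrow(g2),
            format_pvalue(f_high$p_value)))

tab_cv <- rbind(c(sum(g1$cv_class == "low_cv", na.rm = TRUE),
                  sum(g1$cv_class == "high_cv", na.rm = TRUE)),
                c(sum(g2$cv_class == "low_cv", na.rm = TRUE),
                  sum(g2$cv_class == "high_cv", na.rm = TRUE)))
f_cv <- fisher_exact(tab_cv)
cat(sprintf("CV < 0.2: %s %d/%d vs %s %d/%d, Fisher p = %s\n",
            groups[1], tab_cv[1, 1], nrow(g1),
            groups[2], tab_cv[2, 1], nrow(g2), format_pvalue(f_cv$p_value)))

# firing rates should be similar; the first-peak coefficient should differ
rate_cmp <- compare_two_samples(g1$rate, g2$rate, "mann_whitney")
fpc1 <- g1$first_peak_coefficient[g1$regularity_class != "none"]
fpc2 <- g2$first_peak_coefficient[g2$regularity_class != "none"]
fpc_cmp <- compare_two_samples(fpc1, fpc2, "mann_whitney")
cat(sprintf("firing rate: %.2f vs %.2f Hz (p = %s); first-peak coefficient: %.2f vs %.2f (p = %s)\n",
            mean(g1$rate), mean(g2$rate), format_pvalue(rate_cmp$p_value),
            mean(fpc1, na.rm = TRUE), mean(fpc2, na.rm = TRUE),
            format_pvalue(fpc_cmp$p_value)))

for (g in groups) {
  sub <- per_cell[per_cell$group == g & is.finite(per_cell$cv), ]
  reg <- frequency_cv_relationship(sub$rate, sub$cv)
  cat(sprintf("%s frequency-CV: r = %.2f, r^2 = %.2f, p = %s (n = %d)\n",
              g, reg$pearson_r, reg$r_squared, format_pvalue(reg$p_value),
              reg$n))
}

summary_tab <- data.frame(
  group = groups, n = c(nrow(g1), nrow(g2)),
  high_autocorr = tab_high[, 1], low_cv = tab_cv[, 1],
  fisher_p_high = f_high$p_value, fisher_p_cv = f_cv$p_value)
write.csv(summary_tab, "results/regularity_groups.csv", row.names = FALSE)
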