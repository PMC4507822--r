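test_that("ISI statistics follow their definitions", {
  st <- compute_isis(spike_train(c(0, 1, 2, 3), 4))
  expect_equal(st$isis, c(1, 1, 1))
  expect_equal(st$cv, 0)
  expect_equal(st$rate, 1)
  # single spike: rate defined, CV not
  one <- compute_isis(spike_train(1.5, 10))
  expect_length(one$isis, 0)
  expect_true(is.na(one$cv))
  expect_equal(one$rate, 0.1)
  # sample SD (n-1): times 0,1,3 -> isis 1,2 -> sd sqrt(0.5)
  st2 <- compute_isis(spike_train(c(0, 1, 3), 4))
  expect_equal(st2$sd_isi, stats::sd(c(1, 2)))
  expect_equal(st2$cv, stats::sd(c(1, 2)) / 1.5)
})

test_that("gamma k = 4 train recovers cv 0.5 through compute_isis", {
  tr <- gen_spike_train("irregular", rate = 1, cv = 0.5, duration = 2100,
                        seed = 7)
  expect_gte(length(compute_isis(tr)$isis), 2000 * 0.9)
  expect_lt(abs(compute_isis(tr)$cv - 0.5), 0.05)
})

test_that("periodic trains produce lag-period peaks in the autocorrelogram", {
  tr <- gen_spike_train("regular", rate = 1, cv = 0, duration = 300,
                        seed = 1, phase = 0.25)
  ac <- autocorrelogram(tr, bin_width = 0.1, max_lag = 3)
  peaks <- detect_ac_peaks(ac)
  expect_gte(nrow(peaks), 3)
  expect_gt(peaks$coefficient[1], 0.2)
  # peak lags within one bin of integer multiples of the 1 s period
  k <- round(peaks$lag)
  expect_true(all(abs(peaks$lag - k) <= 0.1 + 1e-9))
})

test_that("autocorrelogram matches the brute-force shift-and-correlate oracle", {
  seeds <- 1:25
  max_diff <- 0
  for (s in seeds) {
    rate <- with_rng(s, stats::runif(1, 0.5, 4))
    cv <- with_rng(s + 1000, stats::runif(1, 0.05, 1.2))
    tr <- gen_spike_train("irregular", rate = rate, cv = cv,
                          duration = 50, seed = s)
    if (length(tr$times) < 5) next
    ac <- autocorrelogram(tr, bin_width = 0.1, max_lag = 2)
    ora <- oracle_autocorrelogram(tr$times, tr$duration, 0.1, 2)
    ora[is.na(ora)] <- 0
    max_diff <- max(max_diff, max(abs(ac$coefficients - ora)))
  }
  expect_lt(max_diff, 1e-9)
})

test_that("Poisson-train autocorrelogram coefficients sit in the noise band", {
  inside <- vapply(1:20, function(s) {
    tr <- gen_spike_train("irregular", rate = 1, cv = 1, duration = 500,
                          seed = s)
    ac <- autocorrelogram(tr, bin_width = 0.2, max_lag = 5)
    all(abs(ac$coefficients) < 2 / sqrt(ac$n_bins) * 2)
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("peak detection finds strict local maxima above the floor", {
  mk_ac <- function(coefs) structure(
    list(lags = seq_along(coefs) * 0.1, coefficients = coefs,
         bin_width = 0.1, n_bins = 1000, analyzable = TRUE),
    class = "autocorrelogram")
  expect_equal(nrow(detect_ac_peaks(mk_ac(rep(0, 10)))), 0)
  bump <- c(0.1, 0.3, 0.5, 0.3, 0.1, 0, 0, 0, 0, 0)
  pk <- detect_ac_peaks(mk_ac(bump))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$lag, 0.3)
  expect_equal(pk$coefficient, 0.5)
  # floor excludes small peaks
  small <- c(0, 0.05, 0, 0, 0.3, 0, 0, 0, 0, 0)
  expect_equal(nrow(detect_ac_peaks(mk_ac(small), floor = 0.08)), 1)
})

test_that("regularity classes follow the coefficient and peak-count rules", {
  pk <- function(coefs, lags = seq_along(coefs))
    data.frame(lag = lags, coefficient = coefs)
  # first peak > 0.2 with >= 3 peaks -> high
  expect_equal(classify_regularity(pk(c(0.25, 0.2, 0.15, 0.1)))$regularity_class,
               "high")
  # first peak < 0.2, few peaks -> low
  expect_equal(classify_regularity(pk(c(0.10, 0.09)))$regularity_class, "low")
  # no peaks -> none
  expect_equal(classify_regularity(pk(numeric(0)))$regularity_class, "none")
  # boundary: first peak exactly 0.2 is not high (strict inequality)
  expect_equal(classify_regularity(pk(c(0.2, 0.3, 0.25)))$regularity_class,
               "low")
  # > 0.2 but only 2 peaks -> low (no repeating lag structure)
  expect_equal(classify_regularity(pk(c(0.5, 0.4)))$regularity_class, "low")
})

test_that("CV dichotomy uses a strict 0.2 cutoff", {
  expect_equal(cv_class(0.15), "low_cv")
  expect_equal(cv_class(0.2), "high_cv")
  expect_equal(cv_class(0), "low_cv")
  expect_true(is.na(cv_class(NA_real_)))
})

test_that("classification is invariant to time translation and bin phase", {
  tr <- gen_spike_train("regular", rate = 1.5, cv = 0.04, duration = 290,
                        seed = 9)
  base_class <- classify_train(tr)$regularity_class
  # shift all spikes by a constant (refit inside a shorter duration)
  shifted <- spike_train(tr$times[tr$times < 280] + 7, 290)
  expect_equal(classify_train(shifted)$regularity_class, base_class)
  # a sub-bin offset must not flip the class either
  nudged <- spike_train(tr$times + 0.011, 290.1)
  expect_equal(classify_train(nudged)$regularity_class, base_class)
})

test_that("first-peak coefficient falls as periodic trains are jittered", {
  mean_fpc <- vapply(c(0, 0.1, 0.25, 0.5), function(jit) {
    mean(vapply(1:20, function(s) {
      tr <- gen_spike_train("regular", rate = 1, cv = jit,
                            duration = 300, seed = s)
      cl <- classify_train(tr)
      if (is.na(cl$first_peak_coefficient)) 0 else cl$first_peak_coefficient
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fpc) < 0))
})

test_that("frequency-CV regression matches its closed-form cases", {
  # collinear points: r^2 = 1
  res <- frequency_cv_relationship(c(1, 2, 3, 4), c(0.8, 0.6, 0.4, 0.2))
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, -0.2)
  expect_equal(res$pearson_r, -1)
  # constant cv: slope 0, r 0
  flat <- frequency_cv_relationship(c(1, 2, 3, 4), rep(0.3, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$pearson_r, 0)
  # zero variance in rate: flagged degenerate
  deg <- frequency_cv_relationship(rep(2, 5), c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$slope))
  expect_error(frequency_cv_relationship(c(1, 2), c(0.1, 0.2)), "3")
})

test_that("a coupled rate-CV population yields a detected negative correlation", {
  # cv = 0.45 - 0.08 rate + N(0, 0.03) over 33 cells: the Pearson r must be
  # negative with p < 0.05 in >= 90% of 100 seeds
  hits <- vapply(1:100, function(s) {
    dat <- with_rng(s, {
      rate <- stats::runif(33, 0.3, 3.9)
      cv <- 0.45 - 0.08 * rate + stats::rnorm(33, 0, 0.03)
      list(rate = rate, cv = cv)
    })
    res <- frequency_cv_relationship(dat$rate, dat$cv)
    res$pearson_r < 0 && res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("unanalyzable trains are classified none", {
  sparse <- spike_train(c(10, 150), 300)
  cl <- classify_train(sparse)
  expect_equal(cl$regularity_class, "none")
})

test_that("cohort classes are recovered by the classification pipeline", {
  # regular cells (cv ~ 0.1) should classify high, bursting cells low or
  # none, in >= 90% of cells across a few cohorts
  hits_reg <- c(); hits_burst <- c()
  for (s in 1:3) {
    bun <- gen_cohort(seed = 100 + s)
    cls <- vapply(bun$spikes, function(tr)
      classify_train(tr)$regularity_class, character(1))
    truth <- bun$cells$true_class[match(names(cls), bun$cells$cell_id)]
    hits_reg <- c(hits_reg, cls[truth == "regular"] == "high")
    hits_burst <- c(hits_burst,
                    cls[truth == "bursting"] %in% c("low", "none"))
  }
  expect_gte(mean(hits_reg), 0.9)
  expect_gte(mean(hits_burst), 0.9)
})
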