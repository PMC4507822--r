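test_that("degenerate gamma (cv = 0) gives a periodic train", {
  tr <- gen_spike_train("regular", rate = 1, cv = 0, duration = 10,
                        seed = 1, phase = 0.5)
  expect_equal(tr$times, seq(0.5, 9.5, by = 1))
  expect_equal(diff(tr$times), rep(1, 9))
})

test_that("gamma renewal trains reproduce the analytic ISI CV 1/sqrt(k)", {
  # exponential ISIs: cv 1
  tr <- gen_spike_train("irregular", rate = 1, cv = 1, duration = 2000,
                        seed = 7)
  expect_lt(abs(compute_isis(tr)$cv - 1), 0.05)
  # k = 4 -> cv 0.5
  tr4 <- gen_spike_train("irregular", rate = 1, cv = 0.5, duration = 2000,
                         seed = 7)
  expect_lt(abs(compute_isis(tr4)$cv - 0.5), 0.05)
})

test_that("generated rate matches the target rate at long duration", {
  tr <- gen_spike_train("regular", rate = 2, cv = 0.1, duration = 2000,
                        seed = 7)
  expect_lt(abs(compute_isis(tr)$rate - 2) / 2, 0.05)
})

test_that("gamma-renewal CV recovery holds across the dispersion grid", {
  # k in {1, 4, 16, 100} <-> cv in {1, 0.5, 0.25, 0.1}; >= 95% of seeds
  # within 0.05 of the analytic value at >= 2000 ISIs
  for (k in c(1, 4, 16, 100)) {
    cv_target <- 1 / sqrt(k)
    hits <- vapply(1:20, function(s) {
      tr <- gen_spike_train("irregular", rate = 1, cv = cv_target,
                            duration = 2100, seed = s)
      abs(compute_isis(tr)$cv - cv_target) < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("spike generators are pure functions of their seed", {
  a <- gen_spike_train("bursting", rate = 10, duration = 60, seed = 42)
  b <- gen_spike_train("bursting", rate = 10, duration = 60, seed = 42)
  c <- gen_spike_train("bursting", rate = 10, duration = 60, seed = 43)
  expect_identical(a$times, b$times)
  expect_false(identical(a$times, c$times))
})

test_that("invalid spike-train inputs are rejected", {
  expect_error(gen_spike_train("regular", rate = -1, cv = 0.1, duration = 10,
                               seed = 1), "rate")
  expect_error(gen_spike_train("regular", rate = 1, cv = 0.1, duration = 0,
                               seed = 1), "duration")
  expect_error(gen_spike_train("regular", rate = 1, cv = -0.5, duration = 10,
                               seed = 1), "cv")
  expect_error(spike_train(c(2, 1), 10), "increasing")
  expect_error(spike_train(c(1, 1), 10), "increasing")
  expect_error(spike_train(c(1, 11), 10), "duration")
})

test_that("bursting trains alternate bursts and pauses", {
  tr <- gen_spike_train("bursting", rate = 10, duration = 300, seed = 5,
                        burst_params = list(burst_rate = 10,
                                            mean_burst_len = 5,
                                            mean_pause = 1))
  isis <- diff(tr$times)
  # the ISI mix is bimodal: short within-burst intervals around 100 ms and
  # long pauses; the CV of such a mixture is well above 1
  expect_gt(compute_isis(tr)$cv, 1)
  expect_gt(sum(isis > 0.5), 10)     # pauses present
  expect_gt(sum(isis < 0.2), 100)    # within-burst intervals present
})

test_that("cohort generator reproduces class mixes and is deterministic", {
  cfg <- default_cohort_config()
  bun <- gen_cohort(seed = 21)
  expect_s3_class(bun, "study_bundle")
  expect_equal(nrow(bun$cells), 33 + 39)
  expect_setequal(unique(bun$cells$group), c("WT", "HD"))
  # the WT-like mix draws the regular class with its configured probability
  # over 33 cells: the count should sit inside a generous binomial band
  p_reg <- cfg$groups[[1]]$class_mix$regular
  n_reg <- sum(bun$cells$true_class == "regular" & bun$cells$group == "WT")
  expect_gte(n_reg, qbinom(0.005, 33, p_reg))
  expect_lte(n_reg, qbinom(0.995, 33, p_reg))
  # determinism: identical seed, identical spike tables
  bun2 <- gen_cohort(seed = 21)
  expect_identical(lapply(bun$spikes, `[[`, "times"),
                   lapply(bun2$spikes, `[[`, "times"))
})

test_that("empty cohort yields an empty but valid bundle", {
  cfg <- default_cohort_config()
  cfg$groups[[1]]$n_cells <- 0
  cfg$groups[[2]]$n_cells <- 0
  bun <- gen_cohort(cfg, seed = 3)
  expect_length(bun$spikes, 0)
  expect_equal(nrow(bun$cells), 0)
  expect_equal(bun$manifest$seed, 3)
})
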