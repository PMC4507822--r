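test_that("a single evoked component is measured at its amplitude and latency", {
  s <- gen_evoked_sweep(data.frame(latency = 3, amplitude = 100,
                                   tau_rise = 0.5, tau_decay = 8))
  m <- measure_evoked(s$trace)
  expect_true(m$responded)
  expect_lt(abs(m$peak_amplitude - 100), 1)
  # reported latency is the peak time; with these fast kinetics the kernel
  # peaks ~1.5 ms after onset, within 2 ms of the component latency
  expect_lt(abs(m$peak_latency - 3), 2)
})

test_that("the earliest peak is reported even when a later one is larger", {
  s <- gen_evoked_sweep(data.frame(latency = c(3, 12),
                                   amplitude = c(60, 120),
                                   tau_rise = 1, tau_decay = 8))
  m <- measure_evoked(s$trace)
  expect_equal(m$n_peaks, 2)
  expect_lt(abs(m$peak_amplitude - 60), 2)   # earliest, not the 120 pA one
  expect_lt(m$peak_latency, 10)
})

test_that("a rectangular pulse integrates to its analytic charge", {
  fs <- 10000
  x <- c(rep(0, 1000), rep(100, round(0.1 * fs)), rep(0, 500))
  tr <- current_trace(x, fs, stim_times = 0.1)
  m <- measure_evoked(tr, window = c(0, 120))
  expect_lt(abs(m$charge - 10) / 10, 0.01)   # 100 pA x 100 ms = 10 pC
})

test_that("charge is additive over summed sweeps", {
  a <- gen_evoked_sweep(data.frame(latency = 4, amplitude = 80,
                                   tau_rise = 1, tau_decay = 10))
  b <- gen_evoked_sweep(data.frame(latency = 9, amplitude = 40,
                                   tau_rise = 1, tau_decay = 10))
  ab <- current_trace(a$trace$samples + b$trace$samples,
                      a$trace$sampling_rate, stim_times = 0.1)
  ca <- measure_evoked(a$trace, window = c(1, 200))$charge
  cb <- measure_evoked(b$trace, window = c(1, 200))$charge
  cab <- measure_evoked(ab, window = c(1, 200))$charge
  expect_lt(abs(cab - (ca + cb)) / (ca + cb), 0.01)
})

test_that("evoked measurement is invariant to a baseline offset", {
  s <- gen_evoked_sweep(data.frame(latency = 3, amplitude = 90,
                                   tau_rise = 1, tau_decay = 10))
  shifted <- current_trace(s$trace$samples + 37, s$trace$sampling_rate,
                           stim_times = s$trace$stim_times)
  m0 <- measure_evoked(s$trace)
  m1 <- measure_evoked(shifted)
  expect_equal(m1$peak_amplitude, m0$peak_amplitude, tolerance = 1e-6)
  expect_equal(m1$charge, m0$charge, tolerance = 1e-6)
})

test_that("a subthreshold sweep is reported as no response, not zero", {
  quiet <- gen_evoked_sweep(data.frame(latency = 3, amplitude = 2,
                                       tau_rise = 1, tau_decay = 10),
                            noise_sd = 5, seed = 2)
  m <- measure_evoked(quiet$trace)
  expect_false(m$responded)
  expect_true(is.na(m$peak_amplitude))
})

test_that("paired-pulse ratio is exact for identical non-overlapping responses", {
  s <- make_ppr_sweep(1.0, 100, tau_decay = 10)
  p <- paired_pulse_ratio(s$trace, 100)
  expect_lt(abs(p$ratio - 1), 0.005)
})

test_that("overlap subtraction recovers the constructed ratio at 25 ms", {
  s <- make_ppr_sweep(1.2, 25, tau_decay = 40)
  p <- paired_pulse_ratio(s$trace, 25)
  expect_lt(abs(p$ratio - 1.2) / 1.2, 0.02)
})

test_that("PPR recovery holds over intervals and ratios at SNR 10", {
  worst <- 0
  for (iv in c(25, 50, 100)) for (r in c(0.8, 1.0, 1.2)) {
    errs <- vapply(1:5, function(s)
      abs(paired_pulse_ratio(make_ppr_sweep(r, iv, noise_sd = 10,
                                            seed = s)$trace, iv)$ratio - r),
      numeric(1))
    worst <- max(worst, max(errs))
  }
  expect_lt(worst, 0.05)
})

test_that("input-output curves average sweeps per intensity", {
  sw <- gen_evoked_sweep(data.frame(latency = 3, amplitude = 100,
                                    tau_rise = 1, tau_decay = 10))
  io <- input_output(list(sw$trace, sw$trace), c(0.05, 0.05))
  expect_equal(nrow(io), 1)
  expect_lt(abs(io$mean_peak_pA - 100), 1)
  expect_equal(io$n_sweeps, 2)
  # monotone construction gives a nondecreasing curve
  amps <- c(20, 50, 90, 130, 160)
  sweeps <- lapply(amps, function(a)
    gen_evoked_sweep(data.frame(latency = 3, amplitude = a,
                                tau_rise = 1, tau_decay = 10))$trace)
  io2 <- input_output(sweeps, seq(0.02, 0.10, 0.02))
  expect_true(all(diff(io2$mean_peak_pA) >= 0))
  # empty input
  io0 <- input_output(list(), numeric(0))
  expect_equal(nrow(io0), 0)
})

test_that("passive properties are recovered from a clean RC step", {
  rc <- gen_rc_step(Rm = 200, Cm = 90, Rs = 10)
  pp <- passive_properties(rc$trace)
  expect_lt(abs(pp$input_resistance - 200) / 200, 0.05)
  expect_lt(abs(pp$capacitance - 90) / 90, 0.05)
  expect_lt(abs(pp$series_resistance - 10) / 10, 0.05)
  expect_lt(abs(pp$tau - rc$truth$tau_ms) / rc$truth$tau_ms, 0.05)
})

test_that("passive-property recovery holds across the Rm x Cm grid", {
  for (Rm in c(100, 200, 400)) for (Cm in c(60, 90, 120)) {
    rc <- gen_rc_step(Rm = Rm, Cm = Cm, Rs = 10)
    pp <- passive_properties(rc$trace)
    expect_lt(abs(pp$input_resistance - Rm) / Rm, 0.05)
    expect_lt(abs(pp$capacitance - Cm) / Cm, 0.05)
  }
})

test_that("doubling Cm doubles the fitted tau", {
  t1 <- passive_properties(gen_rc_step(200, 60, 10)$trace)$tau
  t2 <- passive_properties(gen_rc_step(200, 120, 10)$trace)$tau
  expect_lt(abs(t2 / t1 - 2), 0.05)
})

test_that("steady-state current approaches dV/Rm as Rs vanishes", {
  rc <- gen_rc_step(Rm = 200, Cm = 90, Rs = 0.05)
  x <- rc$trace$samples
  expect_lt(abs(x[length(x)] - 1000 * 10 / 200.05), 0.2)
})

test_that("current density is peak over capacitance", {
  expect_equal(current_density(900, 90), 10)
  expect_equal(current_density(0, 50), 0)
  expect_equal(current_density(3 * 900, 3 * 90), current_density(900, 90))
  expect_error(current_density(100, 0), "positive")
})
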