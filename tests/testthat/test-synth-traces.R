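test_that("zero event rate and zero noise give a flat trace and empty truth", {
  g <- gen_psc_trace(duration = 10, event_rate = 0, noise_sd = 0, seed = 1)
  expect_equal(g$trace$samples, rep(0, 50000))
  expect_equal(nrow(g$events), 0)
})

test_that("the synaptic kernel is normalized to unit peak", {
  t <- seq(0, 0.5, by = 1e-5)
  for (taus in list(c(2, 20), c(0.5, 8), c(5, 100))) {
    k <- psc_kernel(t, taus[1], taus[2])
    expect_lt(abs(max(k) - 1), 1e-6)
    expect_equal(k[1], 0)
  }
  expect_error(psc_kernel(t, 20, 2), "rise")
})

test_that("a single rendered event peaks at its amplitude", {
  tr <- render_psc_trace(data.frame(time = 1, amplitude = 50), duration = 3)
  expect_lt(abs(max(tr$samples) - 50) / 50, 0.01)
})

test_that("trace minus noise equals the analytic event superposition", {
  g <- gen_psc_trace(duration = 20, event_rate = 1.5, noise_sd = 4, seed = 12)
  clean <- render_psc_trace(g$events, duration = 20)
  # re-rendering the truth table with the derived noise seed reproduces the
  # trace exactly, so trace = superposition + that Gaussian noise
  again <- render_psc_trace(g$events, 20, noise_sd = 4,
                            seed = derive_seeds(12, 2)[2])
  expect_identical(g$trace$samples, again$samples)
  noise <- g$trace$samples - clean$samples
  expect_lt(abs(stats::sd(noise) - 4), 0.3)
})

test_that("generated event counts follow Poisson statistics", {
  g <- gen_psc_trace(duration = 60, event_rate = 2, amp_median = 25,
                     noise_sd = 5, seed = 3)
  expect_gte(nrow(g$events), qpois(0.005, 120))
  expect_lte(nrow(g$events), qpois(0.995, 120))
})

test_that("evoked sweep components sum and the truth records the earliest", {
  one <- gen_evoked_sweep(data.frame(latency = 5, amplitude = 80,
                                     tau_rise = 1, tau_decay = 10))
  expect_lt(abs(max(one$trace$samples) - 80) / 80, 0.01)
  expect_equal(one$truth$amplitude, 80)
  # two components with decay much shorter than their separation give two
  # distinct local maxima in the summed trace
  two <- gen_evoked_sweep(data.frame(latency = c(3, 12),
                                     amplitude = c(60, 120),
                                     tau_rise = 1, tau_decay = 3))
  x <- two$trace$samples
  n <- length(x)
  is_max <- x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
    x[2:(n - 1)] > 10
  expect_equal(sum(is_max), 2)
  expect_equal(two$truth$amplitude, 60)  # earliest component recorded
})

test_that("paired-stimulus sweeps carry the constructed PPR ground truth", {
  s <- make_ppr_sweep(1.2, 25)
  expect_equal(s$truth$amplitude[1], 100)
  expect_equal(length(s$trace$stim_times), 2)
  expect_equal(diff(s$trace$stim_times), 0.025)
})

test_that("RC step response matches the closed-form circuit values", {
  rc <- gen_rc_step(Rm = 200, Cm = 90, Rs = 10, dV = 10)
  expect_equal(rc$truth$I_ss_pA, 1000 * 10 / 210)      # ~47.6 pA
  expect_equal(rc$truth$I0_pA, 1000)                   # 10 mV / 10 MOhm
  expect_equal(rc$truth$tau_ms, (10 * 200 / 210) * 90 / 1000)  # ~0.857 ms
  x <- rc$trace$samples
  i_on <- round(0.02 * rc$trace$sampling_rate) + 1L
  expect_lt(abs(x[i_on] - 1000) / 1000, 0.01)          # instantaneous jump
  expect_lt(abs(x[length(x)] - 1000 * 10 / 210), 0.5)  # steady state
})

test_that("trace generators are pure functions of their seed", {
  a <- gen_psc_trace(10, 2, noise_sd = 5, seed = 8)
  b <- gen_psc_trace(10, 2, noise_sd = 5, seed = 8)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$events, b$events)
})

test_that("invalid kernel and noise arguments are rejected", {
  expect_error(gen_psc_trace(10, 2, tau_rise = 30, tau_decay = 20, seed = 1),
               "rise")
  expect_error(render_psc_trace(data.frame(time = 1, amplitude = 5),
                                duration = 5, noise_sd = 3), "seed")
})
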