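test_that("flat and constant traces yield zero events", {
  flat <- current_trace(rep(0, 30000), 5000)
  expect_equal(nrow(detect_events(flat)), 0)
  const <- current_trace(rep(-12.5, 30000), 5000, polarity = "inward")
  expect_equal(nrow(detect_events(const)), 0)
})

test_that("noise-free well-separated events are recovered exactly", {
  truth <- data.frame(time = seq(1, 55, 6)[1:10], amplitude = 50)
  tr <- render_psc_trace(truth, duration = 60)
  det <- detect_events(tr)
  expect_equal(nrow(det), 10)
  expect_true(all(abs(det$amplitude - 50) < 1))
  expect_true(all(abs(det$time - truth$time) < 0.002))
})

test_that("detector reaches precision and recall 0.9 at SNR 5", {
  g <- gen_psc_trace(60, 2, amp_median = 25, noise_sd = 5, seed = 3)
  b <- benchmark_detection(detect_events(g$trace), g$events)
  expect_gte(b$precision, 0.9)
  expect_gte(b$recall, 0.9)
})

test_that("detector is equivariant to polarity", {
  g <- gen_psc_trace(30, 2, amp_median = 30, noise_sd = 4, seed = 6)
  flipped <- current_trace(-g$trace$samples, g$trace$sampling_rate,
                           polarity = "inward")
  expect_equal(detect_events(g$trace), detect_events(flipped))
})

test_that("NaN samples are rejected at construction", {
  expect_error(current_trace(c(1, NaN, 3), 1000), "finite")
  expect_error(current_trace(c(1, NA, 3), 1000), "finite")
})

test_that("event frequency is count over duration", {
  expect_equal(event_frequency(30, 60), 0.5)
  expect_equal(event_frequency(data.frame(time = numeric(0)), 60), 0)
  expect_error(event_frequency(5, 0), "duration")
  # Poisson 2 Hz over 300 s: estimate within 3 SE of the rate
  g <- gen_psc_trace(300, 2, noise_sd = 0, seed = 4)
  f <- event_frequency(g$events, 300)
  se <- sqrt(2 / 300)
  expect_lt(abs(f - 2), 3 * se)
})

test_that("amplitude histogram uses left-closed right-open 10 pA bins", {
  h <- amplitude_histogram(c(12, 15, 25))
  expect_equal(unname(h$counts[1:2]), c(2, 1))
  expect_equal(names(h$counts)[1], "[10,20)")
  # boundary value 20 falls in [20,30)
  h20 <- amplitude_histogram(20)
  expect_equal(unname(h20$counts), c(0, 1))
  # events below the first edge are excluded but conserved
  h5 <- amplitude_histogram(c(5, 15))
  expect_equal(h5$below_first_edge, 1)
  expect_equal(sum(h5$counts) + h5$below_first_edge, h5$n_total)
  # empty input: all-zero histogram
  he <- amplitude_histogram(numeric(0))
  expect_true(all(he$counts == 0))
  expect_equal(he$n_total, 0)
})

test_that("histogram plus below-threshold count conserves the event total", {
  g <- gen_psc_trace(60, 3, amp_median = 18, amp_sdlog = 0.5, noise_sd = 0,
                     seed = 9)
  h <- amplitude_histogram(g$events)
  expect_equal(sum(h$counts) + h$below_first_edge, nrow(g$events))
})

test_that("interevent-interval ECDF behaves as a distribution function", {
  d <- iei_distribution(c(0.5, 1.0, 2.0, 4.0))
  expect_equal(d$ieis, c(0.5, 1.0, 2.0))
  expect_equal(d$ecdf(max(d$ieis)), 1)
  expect_equal(d$ecdf(0), 0)
  expect_true(all(diff(d$ecdf(seq(0, 3, 0.1))) >= 0))
})

test_that("KS comparison of IEI samples detects a frequency shift", {
  # identical samples: D = 0
  x <- c(0.2, 0.5, 0.9, 1.4)
  same <- compare_ecdf(x, x)
  expect_equal(same$D, 0)
  # exponential rate 2 vs rate 1: faster group shifted left, p < 0.001
  a <- with_rng(9, stats::rexp(500, 2))
  b <- with_rng(10, stats::rexp(500, 1))
  cmp <- compare_ecdf(a, b)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$shift, "left")
  expect_error(compare_ecdf(0.1, x), "2 intervals")
})

test_that("KS p-values are not anti-conservative under the null", {
  rejections <- vapply(1:200, function(s) {
    ab <- with_rng(s, list(a = stats::rexp(60, 1), b = stats::rexp(60, 1)))
    compare_ecdf(ab$a, ab$b)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.075)
})

test_that("percent reduction is the standard normalized difference", {
  expect_equal(percent_reduction(2, 1), 50)
  expect_equal(percent_reduction(3, 3), 0)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("TTX pair recovers the action-potential-dependent fraction", {
  tx <- gen_ttx_pair(300, 2, ap_dependent_frac = 0.6, noise_sd = 5, seed = 3)
  d_pre <- detect_events(tx$pre)
  d_post <- detect_events(tx$post)
  red <- percent_reduction(event_frequency(d_pre, 300),
                           event_frequency(d_post, 300))
  expect_lt(abs(red - 60), 5)
})

test_that("detected frequency tracks truth when precision and recall are high", {
  g <- gen_psc_trace(60, 2, amp_median = 25, noise_sd = 5, seed = 5)
  det <- detect_events(g$trace)
  b <- benchmark_detection(det, g$events)
  if (b$precision >= 0.9 && b$recall >= 0.9) {
    f_true <- event_frequency(g$events, 60)
    f_det <- event_frequency(det, 60)
    expect_lt(abs(f_det - f_true) / f_true, 0.10)
  } else {
    fail("benchmark conditions not met at these settings")
  }
})
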