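test_that("cross-correlation of a series with itself is 1 at lag 0", {
  a <- withr::with_seed(1, cumsum(rnorm(2000)))
  cc <- cross_correlate(a, a, max_lag = 0.3)
  expect_equal(cc$cc[1], 1, tolerance = 1e-3)  # n vs n-1 variance divisor
  expect_equal(cc$lags[1], 0)
})

test_that("independent white noise shows no correlation at any lag", {
  withr::local_seed(2)
  a <- rnorm(1e4); b <- rnorm(1e4)
  cc <- cross_correlate(a, b, max_lag = 1)
  expect_true(all(abs(cc$cc) < 0.05))
})

test_that("cross-correlation matches a direct oracle and time-reversal duality", {
  withr::local_seed(3)
  a <- as.numeric(stats::filter(rnorm(3000), 0.9, method = "recursive"))
  b <- -a + rnorm(3000, sd = 0.3)
  cc_ab <- cross_correlate(a, b, max_lag = 0.3)
  # direct definition, computed independently
  k <- 5
  n <- length(a)
  oracle <- mean((a[1:(n - k)] - mean(a)) * (b[(1 + k):n] - mean(b))) /
    (sd(a) * sd(b))
  expect_equal(cc_ab$cc[k + 1], oracle)
  # CC_ab at lag k equals CC_ba evaluated on the time-reversed series
  cc_rev <- cross_correlate(rev(b), rev(a), max_lag = 0.3)
  expect_equal(cc_ab$cc, cc_rev$cc, tolerance = 1e-12)
})

test_that("anti-phase telegraph pair decays with time constant 1/(2k)", {
  rate <- 5
  a <- make_telegraph(rate, 0.01, 2e5, seed = 4)
  b <- -a
  cc <- fit_cc_exponential(cross_correlate(a, b, max_lag = 0.5,
                                           frame_interval = 0.01))
  expect_lt(abs(cc$tau - 1 / (2 * rate)) / (1 / (2 * rate)), 0.1)
})

test_that("exponential fit is exact on noiseless data and robust to noise", {
  lags <- (0:50) * 0.03
  mk <- function(y) structure(list(lags = lags, cc = y,
                                   frame_interval = 0.03, n_molecules = 1L,
                                   tau = NA_real_, amplitude = NA_real_),
                              class = "cc_result")
  fit <- fit_cc_exponential(mk(0.8 * exp(-lags / 0.04)))
  expect_equal(fit$tau, 0.04, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.8, tolerance = 1e-6)
  noisy <- 0.8 * exp(-lags / 0.04) + withr::with_seed(5, rnorm(51, sd = 0.01))
  fit2 <- fit_cc_exponential(mk(noisy))
  expect_lt(abs(fit2$tau - 0.04) / 0.04, 0.1)
  expect_error(fit_cc_exponential(mk(rep(0, 51))), "flat")
})

test_that("molecule averaging is the equal-weight mean of per-molecule CC", {
  withr::local_seed(6)
  ccs <- lapply(1:3, function(i) cross_correlate(rnorm(500), rnorm(500),
                                                 max_lag = 0.3))
  avg <- average_cc(ccs)
  expect_equal(avg$cc, rowMeans(vapply(ccs, `[[`, numeric(11), "cc")))
  expect_equal(avg$n_molecules, 3L)
})

test_that("binding events are segmented at the threshold with exact dwells", {
  don <- rep(0, 500); don[c(101:200, 301:350)] <- 250
  tr <- intensity_trace(list(donor = don, acceptor1 = don))
  ev <- detect_binding_events(tr, threshold = 100)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$dwell, c(100, 50) * 0.03)
  expect_equal(ev$start_frame, c(101, 301))
  # auto threshold on noisy plateaus recovers every event within one frame
  withr::local_seed(7)
  noisy <- intensity_trace(list(donor = don + rnorm(500, sd = 40),
                                acceptor1 = don + rnorm(500, sd = 40)))
  ev2 <- detect_binding_events(noisy, threshold = "auto")
  expect_equal(nrow(ev2), 2)
  expect_true(all(abs(ev2$start_frame - ev$start_frame) <= 1))
  expect_true(all(abs(ev2$dwell - ev$dwell) <= 0.03))
  # all-dark trace yields an empty table
  dark <- intensity_trace(list(donor = rnorm(200, sd = 10),
                               acceptor1 = rnorm(200, sd = 10)))
  expect_equal(nrow(detect_binding_events(dark, threshold = 100)), 0)
})

test_that("dwell lifetime MLE handles censoring and matches the sample mean", {
  expect_warning(fit <- fit_dwell_exponential(c(1, 3, 5)), "fewer than 10")
  expect_equal(fit$mean, 3.0)
  expect_equal(fit$se, 3.0 / sqrt(3))
  # censored dwells add time but not events
  expect_warning(fitc <- fit_dwell_exponential(c(2, 4), censored = c(FALSE, TRUE)))
  expect_equal(fitc$mean, 6.0)
  expect_error(fit_dwell_exponential(c(1, 2), censored = c(TRUE, TRUE)),
               "unidentifiable")
  draws <- withr::with_seed(8, rexp(1000, rate = 1 / 3.5))
  expect_lt(abs(fit_dwell_exponential(draws)$mean - 3.5) / 3.5, 0.1)
})

test_that("the dwell estimator is unbiased over replicates", {
  withr::local_seed(9)
  est <- replicate(100, fit_dwell_exponential(rexp(100, rate = 0.5))$mean)
  se_mean <- 2 / sqrt(100 * 100)
  expect_lt(abs(mean(est) - 2), 2 * se_mean + 1e-9)
})
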