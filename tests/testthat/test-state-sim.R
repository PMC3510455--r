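test_that("a silent chain yields one full-length dwell", {
  m <- state_model(rate_matrix = matrix(0, 3, 3))
  d <- simulate_ctmc(m, 100, seed = 1)
  expect_equal(nrow(d), 1)
  expect_equal(d$length, 100)
  expect_true(d$censored)
})

test_that("dwell times are exponential with the configured mean", {
  m <- state_model(state_names = c("A", "B"), fret_means = c(0.1, 0.9),
                   rate_matrix = matrix(c(0, 1, 1, 0), 2, 2))
  d <- simulate_ctmc(m, 1e4, seed = 2)
  unc <- d$length[!d$censored]
  expect_gt(length(unc), 5e3)
  expect_lt(abs(mean(unc) - 1) , 0.05)
  ks <- suppressWarnings(stats::ks.test(unc, "pexp", rate = 1 / mean(unc)))
  expect_gt(ks$p.value, 0.01)
})

test_that("branching fractions follow the rate ratios", {
  m <- state_model()  # NH exits: 1.1 to HS2, 0.9 to HS1
  d <- simulate_ctmc(m, 5e3, seed = 3)
  st <- as.integer(d$state)
  from_nh <- which(st[-length(st)] == 1)
  to <- st[from_nh + 1]
  frac_hs2 <- mean(to == 2)
  expect_gt(length(to), 1000)
  expect_lt(abs(frac_hs2 - 0.55), 0.04)
})

test_that("noiseless emission reproduces plateau values exactly", {
  m <- state_model(state_names = c("lo", "hi"), fret_means = c(0.1, 0.9),
                   emission_sd = 1e-12,
                   rate_matrix = matrix(c(0, 1, 1, 0), 2, 2))
  # frame-aligned dwells, 10 frames each
  dw <- data.frame(state = factor(c("lo", "hi", "lo"),
                                  levels = c("lo", "hi")),
                   start = c(0, 0.3, 0.6), length = rep(0.3, 3),
                   censored = c(FALSE, FALSE, TRUE))
  tr <- emit_fret(dw, m, frame_interval = 0.030)
  expect_equal(tr$efficiencies$e1,
               rep(c(0.1, 0.9, 0.1), each = 10), tolerance = 1e-9)
})

test_that("single-state emission has the configured noise scale", {
  m <- state_model(state_names = "S", fret_means = 0.5, emission_sd = 0.05,
                   rate_matrix = matrix(0, 1, 1))
  d <- simulate_ctmc(m, 300, seed = 4)
  tr <- emit_fret(d, m, seed = 4)
  expect_equal(length(tr$efficiencies$e1), 10000)
  expect_lt(abs(sd(tr$efficiencies$e1) - 0.05) / 0.05, 0.05)
  expect_lt(abs(mean(tr$efficiencies$e1) - 0.5), 0.01)
})

test_that("zero-noise emission inverts to the dwell sequence", {
  m <- state_model(state_names = c("lo", "hi"), fret_means = c(0.1, 0.9),
                   emission_sd = 1e-12,
                   rate_matrix = matrix(c(0, 0.5, 0.5, 0), 2, 2))
  withr::local_seed(5)
  # frame-aligned dwells of >= 2 frames
  n_dw <- 30
  lens <- sample(2:20, n_dw, replace = TRUE) * 0.030
  states <- rep(c("lo", "hi"), length.out = n_dw)
  dw <- data.frame(state = factor(states, levels = c("lo", "hi")),
                   start = cumsum(c(0, lens[-n_dw])), length = lens,
                   censored = FALSE)
  tr <- emit_fret(dw, m)
  r <- rle(round(tr$efficiencies$e1, 3))
  expect_equal(length(r$lengths), n_dw)
  expect_equal(r$lengths * 0.030, lens)
  expect_equal(ifelse(r$values == 0.1, "lo", "hi"), states)
})

test_that("docking series has exponential bound dwells on the frame grid", {
  tr <- simulate_docking_series(on_rate = 1, mean_dwell = 3.5,
                                duration = 3e3, seed = 6)
  ev <- tr$metadata$events
  expect_gt(nrow(ev), 300)
  dwells <- (ev$end_frame - ev$start_frame + 1) * tr$frame_interval
  fit <- fit_dwell_exponential(dwells)
  expect_lt(abs(fit$mean - 3.5) / 3.5, 0.1)
  expect_true(all(ev$start_frame == floor(ev$start_frame)))
  # dark when the docking rate vanishes
  dark <- simulate_docking_series(on_rate = 0, mean_dwell = 3.5,
                                  duration = 10, noise_sd = 0, seed = 7)
  expect_true(all(dark$channels$donor == 0))
})
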