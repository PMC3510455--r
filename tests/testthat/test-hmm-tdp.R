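test_that("a separable two-level trace is fitted and idealized exactly", {
  withr::local_seed(1)
  truth <- rep(rep(c(1L, 2L), 10), each = 25)
  e <- c(0.1, 0.9)[truth] + rnorm(length(truth), sd = 1e-4)
  tr <- fret_trace(list(e1 = e))
  fit <- fit_hmm(list(tr), n_states = 2)
  expect_equal(fit$means, c(0.1, 0.9), tolerance = 1e-3)
  idl <- idealize(fit, tr)
  expect_equal(idl$states, truth)
  expect_equal(nrow(idl$segments), 20)
})

test_that("a one-state model reduces to the trace mean", {
  withr::local_seed(2)
  tr <- fret_trace(list(e1 = rnorm(300, 0.4, 0.05)))
  fit <- fit_hmm(list(tr), n_states = 1)
  expect_equal(fit$means, mean(tr$efficiencies$e1), tolerance = 1e-6)
  idl <- idealize(fit, tr)
  expect_equal(nrow(idl$segments), 1)
})

test_that("EM log-likelihood is non-decreasing", {
  withr::local_seed(3)
  sim <- simulate_recognition_traces(state_model(), 10, 500, seed = 3)
  fit <- fit_hmm(sim$traces, 3)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_gt(fit$n_iter, 1)
})

test_that("generator round-trip recovers means and the state path", {
  sim <- simulate_recognition_traces(state_model(), 30, 1000, seed = 4)
  fit <- fit_hmm(sim$traces, 3)
  expect_equal(fit$means, c(0.1, 0.5, 0.9), tolerance = 0.03)
  # frame-wise accuracy against the generating dwell sequence
  acc <- vapply(seq_along(sim$traces), function(i) {
    idl <- idealize(fit, sim$traces[[i]])
    dw <- sim$dwells[[i]]
    nf <- length(idl$states)
    frame_t <- (seq_len(nf) - 0.5) * 0.030
    truth <- as.integer(dw$state)[findInterval(frame_t, dw$start)]
    mean(idl$states == truth)
  }, numeric(1))
  expect_gt(mean(acc), 0.95)
})

test_that("the TDP bookkeeping is exact", {
  idl <- make_idealization(rep(rep(c(1L, 2L), 5), each = 10), c(0.1, 0.9))
  tdp <- build_tdp(idl, bins = 10)
  expect_equal(tdp$n_transitions, 9)
  expect_equal(sum(tdp$counts), 9)
  expect_equal(sort(tdp$counts[tdp$counts > 0]), c(4, 5))
  expect_true(all(diag(tdp$counts) == 0))
  # a single-dwell trace yields an empty TDP with a warning
  expect_warning(empty <- build_tdp(make_idealization(rep(1L, 50),
                                                      c(0.1, 0.9))),
                 "no transitions")
  expect_equal(empty$n_transitions, 0)
  # segment-mean axes need the source traces
  expect_error(build_tdp(idl, axis = "segment"), "original traces")
})

test_that("transition rates are counts over occupancy time", {
  # 100 s in state 1 split into 50 dwells, each exiting to state 2
  states <- rep(rep(c(1L, 2L), 50), times = rep(c(66, 33), 50))
  idl <- make_idealization(states, c(0.1, 0.9), frame_interval = 0.030)
  st <- transition_stats(idl, state_names = c("NH", "HS2"))
  expect_equal(st$counts["NH", "HS2"], 50)
  expect_equal(st$occupancy_time[["NH"]], 50 * 66 * 0.030)
  expect_equal(st$rates["NH", "HS2"], 50 / (50 * 66 * 0.030))
  expect_error(transition_stats(list()), "no idealizations")
})

test_that("unvisited states report absent rates, not zero", {
  idl <- make_idealization(rep(c(1L, 2L), each = 50), c(0.1, 0.5, 0.9))
  st <- transition_stats(idl, state_names = c("NH", "HS2", "HS1"))
  expect_true(all(is.na(st$rates["HS1", ])))
  expect_equal(st$counts["HS1", "NH"], 0)
})

test_that("recognition efficiency is the NH-exit branching fraction", {
  counts <- matrix(0, 3, 3, dimnames = rep(list(c("NH", "HS2", "HS1")), 2))
  counts["NH", "HS2"] <- 77; counts["NH", "HS1"] <- 23
  expect_equal(recognition_efficiency(counts), 0.77)
  counts["NH", "HS2"] <- 23
  expect_equal(recognition_efficiency(counts), 0.5)
  # invariant under scaling all counts
  expect_equal(recognition_efficiency(counts * 13),
               recognition_efficiency(counts))
  counts["NH", ] <- 0
  expect_error(recognition_efficiency(counts), "no exits")
})

test_that("short-dwell filtering merges one-frame segments", {
  states <- c(rep(1L, 20), 2L, rep(3L, 20), rep(1L, 20))
  idl_raw <- make_idealization(states, c(0.1, 0.5, 0.9))
  expect_equal(nrow(idl_raw$segments), 4)
  filtered <- rle(slidefret:::filter_short_dwells(states, 2))
  expect_equal(filtered$values, c(1L, 3L, 1L))
})
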