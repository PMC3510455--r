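test_that("zero corrections are the identity and apply linearly", {
  tr <- intensity_trace(list(donor = c(550, 300), acceptor1 = c(250, 400)))
  id <- correction_set(leakage_donor_a1 = 0, leakage_a1_a2 = 0)
  expect_equal(apply_corrections(tr, id)$channels, tr$channels)
  # applying zero corrections twice equals once
  expect_equal(apply_corrections(apply_corrections(tr, id), id)$channels,
               tr$channels)
  bg <- correction_set(background = c(donor = 50, acceptor1 = 50),
                       leakage_donor_a1 = 0, leakage_a1_a2 = 0)
  out <- apply_corrections(tr, bg)
  expect_equal(out$channels$donor[1], 500)
  expect_equal(out$channels$acceptor1[1], 200)
})

test_that("leakage is subtracted from the background-corrected donor", {
  tr <- intensity_trace(list(donor = 500, acceptor1 = 60))
  corr <- correction_set(leakage_donor_a1 = 0.1, leakage_a1_a2 = 0)
  out <- apply_corrections(tr, corr)
  expect_equal(out$channels$acceptor1, 60 - 0.1 * 500)
  expect_error(apply_corrections(
    intensity_trace(list(donor = 1:3)), corr), "acceptor1")
})

test_that("gamma is the ratio of intensity changes across the bleach step", {
  expect_equal(as.numeric(estimate_gamma(
    make_gamma_step_trace(2, a2_level = 30))), 2.0)
  expect_equal(as.numeric(estimate_gamma(
    make_gamma_step_trace(1, a2_level = 60))), 1.0)
  g <- estimate_gamma(make_gamma_step_trace(1.4, noise_sd = 5, seed = 2))
  expect_lt(abs(g - 1.4) / 1.4, 0.1)
  expect_equal(attr(g, "step_frame"), 100)
})

test_that("gamma estimation is invariant to intensity scaling", {
  tr <- make_gamma_step_trace(1.4, noise_sd = 0)
  tr3 <- intensity_trace(lapply(tr$channels, `*`, 3))
  expect_equal(as.numeric(estimate_gamma(tr3)),
               as.numeric(estimate_gamma(tr)))
  flat <- intensity_trace(list(donor = rep(250, 100),
                               acceptor1 = rep(200, 100),
                               acceptor2 = rep(60, 100) +
                                 withr::with_seed(4, rnorm(100))))
  expect_error(estimate_gamma(flat), "no acceptor-2 photobleach")
})

test_that("FRET efficiencies partition intensity per acceptor", {
  e <- fret_efficiencies(intensity_trace(list(donor = 0, acceptor1 = 500)))
  expect_equal(e$efficiencies$e1, 1)
  e3 <- fret_efficiencies(intensity_trace(
    list(donor = c(100, 250), acceptor1 = c(100, 200),
         acceptor2 = c(100, 50))))
  expect_equal(e3$efficiencies$e1, c(1 / 3, 0.4))
  expect_equal(e3$efficiencies$e2, c(1 / 3, 0.1))
  expect_warning(
    bad <- fret_efficiencies(intensity_trace(
      list(donor = c(250, 0), acceptor1 = c(250, 0)))),
    "non-positive")
  expect_equal(bad$efficiencies$e1, c(0.5, NA))
})

test_that("noiseless simulated traces round-trip through the efficiency formula", {
  geom <- filament_geometry(99, 39)
  cfg <- slide_sim_config(n_frames = 200)
  tr <- simulate_slide(cfg, geom, noise = FALSE, seed = 3)[[1]]
  e <- fret_efficiencies(tr)$efficiencies$e1
  # I_A = 500 * Ebar and I_D = 500 * (1 - Ebar), so E recomputes exactly
  expect_equal(e, tr$channels$acceptor1 / 500, tolerance = 1e-12)
})

test_that("Pearson correlation handles the exact limits", {
  e1 <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(pearson_correlation(e1, e1), 1.0)
  expect_equal(pearson_correlation(e1, 1 - e1), -1.0)
  expect_error(pearson_correlation(e1, rep(0.5, 4)), "zero variance")
  expect_error(pearson_correlation(e1[1:2], e1[1:2]))
})
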