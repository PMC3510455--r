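geom_std <- filament_geometry(99, 39)

test_that("zero diffusion yields a constant trajectory and a static trace", {
  cfg <- slide_sim_config(d_um2 = 0, n_frames = 50)
  pos <- simulate_trajectory(cfg, geom_std, n_steps = 200, seed = 1)
  expect_true(all(pos == pos[1]))
  tr <- simulate_slide(cfg, geom_std, noise = FALSE, seed = 1)[[1]]
  expect_equal(diff(range(tr$channels$acceptor1)), 0)
  e_static <- fret_from_distance(20, fret_coupling(56))  # starts at acceptor
  expect_equal(tr$channels$acceptor1[1], 500 * e_static)
})

test_that("reflecting boundaries confine the walk", {
  cfg <- slide_sim_config(d_bp2 = 5000, n_frames = 10)
  pos <- simulate_trajectory(cfg, geom_std, n_steps = 2e5,
                             boundary = c(0, 10), x0 = 5, seed = 2)
  expect_gte(min(pos), 0)
  expect_lte(max(pos), 10)
})

test_that("unbounded walk reproduces the diffusion law (time-averaged MSD)", {
  d_bp2 <- 7700
  cfg <- slide_sim_config(d_bp2 = d_bp2, n_frames = 10)
  tau_micro <- cfg$step_size^2 / (2 * d_bp2)
  lags <- seq(10, 100, by = 10)
  msd <- matrix(0, nrow = 20, ncol = length(lags))
  withr::with_seed(3, {
    for (w in seq_len(20)) {
      pos <- simulate_trajectory(cfg, geom_std, n_steps = 2e4,
                                 boundary = c(-Inf, Inf), x0 = 0)
      msd[w, ] <- vapply(lags, function(k) mean(diff(pos, lag = k)^2),
                         numeric(1))
    }
  })
  slope <- coef(lm(colMeans(msd) ~ 0 + I(lags * tau_micro)))[[1]]
  expect_lt(abs(slope - 2 * d_bp2) / (2 * d_bp2), 0.05)
})

test_that("noiseless channel sums equal the photon budget exactly", {
  cfg <- slide_sim_config(n_frames = 200)
  tr <- simulate_slide(cfg, geom_std, noise = FALSE, seed = 4)[[1]]
  expect_equal(tr$channels$donor + tr$channels$acceptor1,
               rep(500, 200))
  geom3 <- filament_geometry(99, 39, acceptor_positions = c(0, 33))
  tr3 <- simulate_three_color(cfg, geom3, noise = FALSE, seed = 4)[[1]]
  expect_equal(Reduce(`+`, tr3$channels), rep(500, 200))
})

test_that("channel noise has the configured scale", {
  cfg <- slide_sim_config(d_um2 = 0, n_frames = 1e4, noise_sd = 40)
  tr <- simulate_slide(cfg, geom_std, seed = 5)[[1]]
  resid <- tr$channels$donor + tr$channels$acceptor1 - 500
  # sum of two independent Gaussians: SD sqrt(2) * 40
  expect_lt(abs(sd(resid) - sqrt(2) * 40) / (sqrt(2) * 40), 0.05)
})

test_that("rendering a trajectory matches the closed-form static case", {
  cfg <- slide_sim_config(d_um2 = 0, n_frames = 20)
  pos <- rep(12, 20)
  tr <- render_intensities(pos, geom_std, fret_coupling(56), cfg,
                           noise = FALSE)
  e <- fret_from_distance(register_to_distance(12, 0, geom_std),
                          fret_coupling(56))
  expect_equal(tr$channels$acceptor1, rep(500 * e, 20))
})

test_that("a long bounded walk occupies the domain uniformly", {
  cfg <- slide_sim_config(d_bp2 = 5000, n_frames = 10)
  pos <- simulate_trajectory(cfg, geom_std, n_steps = 2e6,
                             boundary = c(0, 20), x0 = 10, seed = 6)
  h <- hist(pos, breaks = seq(0, 20, by = 4), plot = FALSE)
  expect_true(all(abs(h$counts / length(pos) - 0.2) < 0.05))
})

test_that("mean FRET decreases with filament length (junction acceptor)", {
  mean_e <- vapply(c(21, 39, 99), function(L) {
    tr <- simulate_slide(slide_sim_config(n_frames = 2000),
                         filament_geometry(L, 39), noise = FALSE,
                         seed = 7)[[1]]
    mean(tr$channels$acceptor1) / 500
  }, numeric(1))
  expect_true(all(diff(mean_e) < 0))
})

test_that("three-color limits behave geometrically", {
  geom3 <- filament_geometry(99, 39, acceptor_positions = c(0, 33))
  # pinned at acceptor 1 (D = 0 starts at the first acceptor position)
  cfg0 <- slide_sim_config(d_um2 = 0, n_frames = 100)
  tr <- simulate_three_color(cfg0, geom3, noise = FALSE, seed = 8)[[1]]
  e <- fret_efficiencies(tr)
  expect_true(all(e$efficiencies$e1 > 0.9))
  expect_true(all(e$efficiencies$e2 < 0.01))
  expect_equal(diff(range(e$efficiencies$e1)), 0)  # static
  expect_error(simulate_three_color(cfg0,
    filament_geometry(99, 39, acceptor_positions = c(10, 10))), "coincide")
})

test_that("identical seeds reproduce identical traces", {
  cfg <- slide_sim_config(n_frames = 100)
  t1 <- simulate_slide(cfg, geom_std, n_molecules = 2, seed = 9)
  t2 <- simulate_slide(cfg, geom_std, n_molecules = 2, seed = 9)
  expect_identical(t1[[2]]$channels, t2[[2]]$channels)
  t3 <- simulate_slide(cfg, geom_std, n_molecules = 2, seed = 10)
  expect_false(identical(t1[[1]]$channels, t3[[1]]$channels))
})
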