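test_that("register-to-distance follows the lateral-offset Pythagorean form", {
  geom0 <- filament_geometry(99, 39, lateral_offset = 0)
  expect_equal(register_to_distance(10, 0, geom0), 51.0)
  geom30 <- filament_geometry(99, 39, lateral_offset = 30)
  expect_equal(register_to_distance(8, 0, geom30), sqrt(900 + 1664.64))
  # zero axial separation returns the lateral offset itself
  expect_equal(register_to_distance(5, 5, geom30), 30)
  expect_equal(register_to_distance(0, 0, geom0), 0)
})

test_that("register-to-distance is symmetric and bounded below by the offset", {
  geom <- filament_geometry(99, 39, lateral_offset = 20)
  withr::with_seed(1, {
    x <- runif(50, 0, 99); x0 <- runif(50, 0, 99)
  })
  expect_equal(register_to_distance(x, x0, geom),
               register_to_distance(x0, x, geom))
  expect_true(all(register_to_distance(x, x0, geom) >= 20))
})

test_that("Foerster relation hits its defining points and is monotone", {
  cp <- fret_coupling(56)
  expect_equal(fret_from_distance(56, cp), 0.5)
  expect_equal(fret_from_distance(0, cp), 1.0)
  expect_equal(fret_from_distance(112, cp), 1 / 65)
  d <- seq(0, 200, by = 0.5)
  expect_true(all(diff(fret_from_distance(d, cp)) < 0))
  expect_error(fret_from_distance(-1, cp), "negative")
})

test_that("efficiency along the register is unimodal with its peak at the acceptor", {
  geom <- filament_geometry(99, 39, lateral_offset = 20)
  cp <- fret_coupling(56)
  x <- seq(0, 90, by = 0.5)
  e <- fret_from_distance(register_to_distance(x, 30, geom), cp)
  peak <- which.max(e)
  expect_equal(x[peak], 30)
  expect_true(all(diff(e[seq_len(peak)]) > 0))
  expect_true(all(diff(e[peak:length(e)]) < 0))
})

test_that("diffusion unit conversion matches direct arithmetic and round-trips", {
  expect_equal(diffusion_um2_to_bp2(0), 0)
  expect_equal(diffusion_um2_to_bp2(0.9e-3, rise_nm = 0.34), 900 / 0.34^2)
  # the stretched-register rise gives a different bp^2/s figure: convention
  # sensitivity is real and must be explicit
  expect_equal(diffusion_um2_to_bp2(0.9e-3, rise_nm = 0.51), 900 / 0.51^2)
  d <- c(1e-5, 0.9e-3, 2)
  expect_equal(diffusion_bp2_to_um2(diffusion_um2_to_bp2(d, 0.42), 0.42), d)
})

test_that("stretched span recovers the filament register rise", {
  expect_equal(stretched_span(11), 11 * 3.4 * 1.5)
  expect_equal(stretched_span(0), 0)
  expect_equal(stretched_span(1), 5.1)
})

test_that("geometry constructor enforces its invariants", {
  expect_error(filament_geometry(0, 39))
  expect_error(filament_geometry(99, 39, rise_per_nt = -1))
  expect_error(filament_geometry(99, 39, acceptor_positions = 120),
               "within")
  expect_error(fret_coupling(0))
})

test_that("FRET clipping policies apply the documented bounds", {
  e <- c(-0.5, -0.1, 0.5, 1.1, 1.5)
  expect_equal(clip_fret(e, "storage"), c(-0.2, -0.1, 0.5, 1.1, 1.2))
  expect_equal(clip_fret(e, "unit"), c(0, 0, 0.5, 1, 1))
})
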