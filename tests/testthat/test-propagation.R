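test_that("a single element reproduces the point-source formula", {
  geom <- array_geometry(matrix(c(0, 0, 0), 1), areas = 0.0225)
  d <- 7; f <- 20
  H <- build_propagator(geom, matrix(c(0, 0, d), 1), water, f)
  k <- 2 * pi * f / 1.5                 # rad/mm at c = 1.5 mm/us
  expect_equal(Mod(H$matrix[1, 1]), 1000 * 1.5 * k * 0.0225 / (2 * pi * d),
               tolerance = 1e-12)
  expect_equal(Arg(H$matrix[1, 1]), Arg(1i * exp(-1i * k * d)),
               tolerance = 1e-12)
})

test_that("operator matches an independently coded double-loop summation", {
  geom <- build_ring_geometry(small_spec(n = 16))
  pts <- as.matrix(expand.grid(x = seq(-0.4, 0.4, length.out = 5),
                               y = seq(-0.4, 0.4, length.out = 5)))
  pts <- cbind(pts, z = 7)
  H <- build_propagator(geom, pts, water, 20)$matrix
  expect_rel_equal(H, naive_H(geom, pts, water, 20), 1e-12)
})

test_that("mirror-symmetric field points see equal magnitudes from a symmetric excitation", {
  geom <- dense_cap(pitch = 0.25)       # full lattice: symmetric in x
  pts <- rbind(c(0.37, 0.11, 7), c(-0.37, 0.11, 7))
  H <- build_propagator(geom, pts, water, 5)$matrix
  P <- H %*% rep(1 + 0i, nrow(geom$positions))
  expect_equal(Mod(P[1]), Mod(P[2]), tolerance = 1e-10)
})

test_that("coincident element and field point is a reported singularity", {
  geom <- array_geometry(matrix(c(0, 0, 0), 1), areas = 1)
  expect_error(build_propagator(geom, matrix(c(0, 0, 0), 1), water, 20),
               "singular distance")
})

test_that("field evaluation is linear and vanishes for zero drive", {
  geom <- build_ring_geometry(small_spec(n = 32))
  grid <- field_grid("lateral", extent = c(0.4, 0.4), spacing = 0.05)
  u1 <- conjugate_phase_excitation(geom, c(0, 0, 7), water, 20)
  set.seed(42)
  u2 <- complex(real = stats::rnorm(32), imaginary = stats::rnorm(32))
  f1 <- evaluate_field(geom, u1, grid, water, 20)$pressure
  f2 <- evaluate_field(geom, u2, grid, water, 20)$pressure
  f12 <- evaluate_field(geom, 2 * u1 + (0.3 - 1i) * u2, grid, water, 20)$pressure
  expect_rel_equal(f12, 2 * f1 + (0.3 - 1i) * f2, 1e-12)
  f0 <- evaluate_field(geom, rep(0 + 0i, 32), grid, water, 20)$pressure
  expect_true(all(f0 == 0))
  expect_error(evaluate_field(geom, rep(1 + 0i, 31), grid, water, 20),
               "does not match element count")
})

test_that("a lone element decays exactly as 1/distance", {
  geom <- array_geometry(matrix(c(0, 0, 0), 1), areas = 1)
  d <- seq(5, 50, by = 5)
  H <- build_propagator(geom, cbind(0, 0, d), water, 20)$matrix
  pd <- Mod(H[, 1]) * d
  expect_lt(diff(range(pd)) / mean(pd), 1e-9)
})

test_that("reciprocity: swapping element and field point transposes H up to areas", {
  a <- c(0.3, -0.2, 0.1); b <- c(-0.5, 0.4, 6)
  g1 <- array_geometry(matrix(a, 1), areas = 0.04)
  g2 <- array_geometry(matrix(b, 1), areas = 0.09)
  H12 <- build_propagator(g1, matrix(b, 1), water, 12)$matrix[1, 1]
  H21 <- build_propagator(g2, matrix(a, 1), water, 12)$matrix[1, 1]
  expect_equal(H12 / 0.04, H21 / 0.09, tolerance = 1e-12)
})

test_that("focal pressure of a dense annular cap matches the closed-form focused-radiator solution", {
  # O'Neil's solution at the geometric focus of a concave bowl: |p| = rho c u k h
  # with h the bowl depth; an annulus is the difference of two caps.
  geom <- dense_cap(pitch = 0.02)
  f <- 5
  exc <- conjugate_phase_excitation(geom, c(0, 0, 12), water, f)
  H <- build_propagator(geom, matrix(c(0, 0, 12), 1), water, f)
  P <- Mod(H$matrix %*% exc)
  k <- 2 * pi * f / 1.5
  h_out <- 12 - sqrt(144 - 5.5^2)
  h_in <- 12 - sqrt(144 - 4.5^2)
  oneil <- 1000 * 1.5 * k * (h_out - h_in)
  expect_lt(abs(P - oneil) / oneil, 0.02)
})

test_that("attenuated operator applies the medium power law along each path", {
  med <- medium(attenuation_a0 = 0.5, attenuation_gamma = 1.2)
  geom <- array_geometry(matrix(c(0, 0, 0), 1), areas = 1)
  d <- 8
  H0 <- build_propagator(geom, matrix(c(0, 0, d), 1), med, 10)$matrix[1, 1]
  Ha <- build_propagator(geom, matrix(c(0, 0, d), 1), med, 10,
                         attenuate = TRUE)$matrix[1, 1]
  db <- 0.5 * 10^1.2 * (d / 10)          # dB over d mm
  expect_equal(Mod(Ha) / Mod(H0), 10^(-db / 20), tolerance = 1e-12)
})

test_that("beam widths recover a synthetic Gaussian's FWHM", {
  grid <- field_grid("lateral", extent = c(2, 2), spacing = 0.01)
  sigma <- 0.21
  pts <- grid_points(grid)
  amp <- exp(-(pts[, 1]^2 + pts[, 2]^2) / (4 * sigma^2))  # intensity ~ exp(-r^2/2sigma^2)
  fld <- structure(list(grid = grid,
                        pressure = matrix(complex(modulus = amp, argument = 0),
                                          grid$dim[1], grid$dim[2]),
                        frequency = 20, medium = water),
                   class = "pressure_field")
  w <- measure_beam_widths(fld)
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  expect_equal(unname(w$widths["x"]), fwhm, tolerance = grid$spacing / fwhm)
  expect_equal(unname(w$widths["y"]), fwhm, tolerance = grid$spacing / fwhm)
  # scale invariance
  fld2 <- fld; fld2$pressure <- fld$pressure * 17.3
  expect_identical(measure_beam_widths(fld2)$widths, w$widths)
})

test_that("peak on the grid border is rejected, censored widths are flagged", {
  grid <- field_grid("lateral", extent = c(1, 1), spacing = 0.1)
  pts <- grid_points(grid)
  ramp <- matrix(pts[, 1] + 2, grid$dim[1], grid$dim[2])
  fld <- structure(list(grid = grid, pressure = ramp + 0i,
                        frequency = 5, medium = water),
                   class = "pressure_field")
  expect_error(measure_beam_widths(fld), "focus outside grid")
  # near-flat field: interior peak but no -3 dB crossing inside the grid
  bump <- 1 + 0.01 * exp(-(pts[, 1]^2 + pts[, 2]^2))
  flat <- structure(list(grid = grid,
                         pressure = matrix(bump + 0i, grid$dim[1], grid$dim[2]),
                         frequency = 5, medium = water),
                    class = "pressure_field")
  w <- measure_beam_widths(flat)
  expect_true(all(w$censored))
})

test_that("halving the frequency doubles the focal width of a fixed geometry", {
  spec <- ring_array_spec()
  w10 <- single_focus_field(spec, frequency = 10, extent = c(0.6, 0.6),
                            spacing = 0.005)$widths$widths["x"]
  w5 <- single_focus_field(spec, frequency = 5, extent = c(1.2, 1.2),
                           spacing = 0.005)$widths$widths["x"]
  expect_equal(unname(w5 / w10), 2, tolerance = 0.1)
})
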