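# band-limited random field: pass white noise once through the zero-distance
# angular-spectrum filter (keeps only propagating components)
band_limited <- function(n, pitch, f, seed = 1) {
  set.seed(seed)
  x <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  angular_spectrum_propagate(x, pitch, 0, water, f)
}

test_that("zero-distance propagation is the identity on the propagating band", {
  x <- band_limited(64, 0.1, 5)
  y <- angular_spectrum_propagate(x, 0.1, 0, water, 5)
  expect_rel_equal(y, x, 1e-12)
})

test_that("propagation is unitary on the propagating band (round trip + Parseval)", {
  x <- band_limited(64, 0.1, 5)
  y <- angular_spectrum_propagate(x, 0.1, 7, water, 5)
  back <- angular_spectrum_propagate(y, 0.1, -7, water, 5)
  expect_rel_equal(back, x, 1e-10)
  expect_lt(abs(sum(Mod(y)^2) - sum(Mod(x)^2)) / sum(Mod(x)^2), 1e-9)
})

test_that("undersampled planes trigger a warning", {
  x <- matrix(1 + 0i, 16, 16)
  expect_warning(angular_spectrum_propagate(x, 0.2, 1, water, 20),
                 "undersampled")
})

test_that("a point-like source propagates like direct Rayleigh-Sommerfeld summation", {
  # compact Gaussian source (band-limited, so the sampled field represents it
  # faithfully) propagated 7 mm; oracle = brute-force summation of the exact
  # Rayleigh kernel over every source pixel
  n <- 256; pitch <- 0.05; f <- 5; z <- 7
  k <- wavenumber(f, water)
  ax <- pixel_axis_for_test(n, pitch)
  src <- outer(exp(-ax^2 / (2 * 0.2^2)), exp(-ax^2 / (2 * 0.2^2)))
  V <- angular_spectrum_propagate(src + 0i, pitch, z, water, f)
  ic <- which.min(abs(ax))
  win <- which(abs(ax) <= 1.2)
  xx <- rep(ax, times = n); yy <- rep(ax, each = n); ss <- as.vector(src)
  direct <- vapply(ax[win], function(x0) {
    d <- sqrt((x0 - xx)^2 + yy^2 + z^2)
    sum(ss * pitch^2 * (1i * k / (2 * pi)) * (z / d) *
          (1 + 1 / (1i * k * d)) * exp(-1i * k * d) / d)
  }, complex(1))
  expect_lt(max(Mod(V[win, ic] - direct)) / max(Mod(direct)), 0.02)
})

test_that("single-transform aperture relation has the documented inverse pair", {
  tp <- render_pattern(pattern_recipe("letters", text = "O", size_px = 64))
  A <- image_to_aperture(tp, water, 20)
  I_rec <- aperture_to_image(A, water, 20, depth = tp$depth)
  expect_rel_equal(Re(I_rec), tp$amplitude, 1e-10)
  expect_lt(max(abs(Im(I_rec))), 1e-10)
  # delta image -> constant-magnitude aperture
  delta <- render_pattern(pattern_recipe("points", size_px = 32))
  Ad <- image_to_aperture(delta, water, 20)
  expect_lt(diff(range(Mod(Ad))) / mean(Mod(Ad)), 1e-10)
})

test_that("shifting the image applies the transform phase ramp to the aperture", {
  n <- 32
  set.seed(3)
  img <- matrix(runif(n * n), n, n)
  p <- 5
  shifted <- img[c((n - p + 1):n, 1:(n - p)), ]   # circular shift along x
  A0 <- stats::fft(img, inverse = TRUE)
  A1 <- stats::fft(shifted, inverse = TRUE)
  ramp <- exp(2i * pi * p * (seq_len(n) - 1) / n)
  expect_rel_equal(A1, A0 * matrix(ramp, n, n), 1e-10)
})

test_that("a single-point target yields the analytic focusing lens", {
  pt <- c(0.7, -0.35)
  tg <- render_pattern(pattern_recipe("points", size_px = 64,
                                      pixel_pitch = 0.07,
                                      points = matrix(pt, ncol = 2)), depth = 7)
  gs <- suppressWarnings(gsw_synthesize(tg, water, 20, max_iter = 30))
  k <- wavenumber(20, water)
  ax <- pixel_axis_for_test(64, 0.07)
  # lens centered on the rendered pixel (the target point is quantized)
  ix <- which.min(abs(ax - pt[1])); iy <- which.min(abs(ax - pt[2]))
  lens <- k * sqrt(outer((ax - ax[ix])^2, (ax - ax[iy])^2, "+") + 7^2)
  # phase agreement up to a global constant: circular correlation near 1
  cc <- Mod(mean(exp(1i * (gs$hologram$phase - lens))))
  expect_gt(cc, 0.9)
  # achieved peak lands on the requested point
  pk <- which(Mod(gs$achieved_field$pressure) ==
                max(Mod(gs$achieved_field$pressure)), arr.ind = TRUE)[1, ]
  expect_lt(abs(ax[pk[1]] - pt[1]), 0.07 + 1e-9)
  expect_lt(abs(ax[pk[2]] - pt[2]), 0.07 + 1e-9)
})

test_that("reported uniformity history is non-decreasing and the hologram is phase-only", {
  tg <- render_pattern(pattern_recipe("points", size_px = 64, pixel_pitch = 0.05,
                                      points = rbind(c(-0.5, 0), c(0.5, 0),
                                                     c(0, 0.5))))
  gs <- suppressWarnings(gsw_synthesize(tg, water, 20, max_iter = 40))
  expect_identical(length(gs$uniformity_history), gs$iterations_run)
  expect_true(all(diff(gs$uniformity_history) >= -1e-6))
  expect_gt(utils::tail(gs$uniformity_history, 1), 0.9)
  expect_true(is.numeric(gs$hologram$phase))
  expect_true(all(gs$hologram$phase > -pi - 1e-12 &
                    gs$hologram$phase <= pi + 1e-12))
  expect_true(gs$efficiency >= 0 && gs$efficiency <= 1)
  expect_error(gsw_synthesize(target_pattern(diag(2), pixel_pitch = 0.05),
                              water, 20, support_threshold = 2),
               "empty support")
})

test_that("two-point patterns stop being resolved below about a wavelength", {
  # two equal in-phase foci: above ~1 wavelength separation the field shows a
  # dip between them; below ~lambda/2 they merge into one blob whose center
  # exceeds the prescribed focal pressures
  lam <- wavelength_mm(20, water)        # 0.075 mm
  geom <- build_ring_geometry(ring_array_spec())
  mid_ratio <- function(sep) {
    fs <- focus_set(rbind(c(-sep / 2, 0, 7), c(sep / 2, 0, 7)))
    H <- build_propagator(geom, fs$points, water, 20)
    sol <- solve_min_norm(H, fs)
    grid <- field_grid("lateral", extent = c(0.4, 0.1), spacing = 0.005)
    fld <- evaluate_field(geom, sol$excitation, grid, water, 20)
    ax <- grid$axis1; iy <- which.min(abs(grid$axis2))
    prof <- Mod(fld$pressure[, iy])
    i1 <- which.min(abs(ax + sep / 2)); i2 <- which.min(abs(ax - sep / 2))
    prof[which.min(abs(ax))] / min(prof[i1], prof[i2])
  }
  expect_lt(mid_ratio(2 * lam), 0.8)     # resolved
  expect_lt(mid_ratio(lam), 0.8)         # still resolved at one wavelength
  expect_gt(mid_ratio(lam / 2), 1)       # merged below the band limit
})

test_that("hologram sampling compensates the cap sag and flags stray elements", {
  f <- 20; k <- wavenumber(f, water)
  holo <- structure(list(phase = matrix(0, 128, 128),
                         source_pixel_pitch = 0.07, plane_z = 0),
                    class = "hologram")
  geom <- build_ring_geometry(ring_array_spec(outer_diameter = 7,
                                              inner_diameter = 5,
                                              n_elements = 64))
  exc <- sample_hologram_to_elements(holo, geom, water, f)
  # constant-phase hologram: excitation phase is pure sag compensation
  expected <- Arg(exp(-1i * k * geom$positions[, 3]))
  expect_equal(Arg(exc), expected, tolerance = 1e-10)
  # flat-cap limit: sag ~ 0, phases equal the hologram samples
  flat <- build_ring_geometry(ring_array_spec(curvature_radius = 1e6,
                                              outer_diameter = 7,
                                              inner_diameter = 5,
                                              n_elements = 64))
  exc_flat <- sample_hologram_to_elements(holo, flat, water, f)
  expect_lt(max(abs(Arg(exc_flat))), 1e-3)
  # elements outside the hologram extent are listed
  big <- build_ring_geometry(ring_array_spec(n_elements = 64))  # OD 11 > 8.96
  expect_error(sample_hologram_to_elements(holo, big, water, f),
               "outside the hologram extent")
})

test_that("end-to-end hologram -> elements -> field focuses at the requested point", {
  pt <- c(0.5, -0.3, 7)
  tg <- render_pattern(pattern_recipe("points", size_px = 128,
                                      pixel_pitch = 0.07,
                                      points = matrix(pt[1:2], ncol = 2)))
  geom <- build_ring_geometry(ring_array_spec(outer_diameter = 7,
                                              inner_diameter = 5,
                                              n_elements = 256))
  res <- suppressWarnings(
    pattern_pipeline(tg, frequency = 20, path = "elements", geometry = geom,
                     max_iter = 20))
  fld <- res$achieved
  pk <- which(Mod(fld$pressure) == max(Mod(fld$pressure)), arr.ind = TRUE)[1, ]
  expect_lt(abs(fld$grid$axis1[pk[1]] - pt[1]), 0.07 + 1e-9)
  expect_lt(abs(fld$grid$axis2[pk[2]] - pt[2]), 0.07 + 1e-9)
  expect_identical(res$path, "elements")
})

test_that("pattern quality metrics behave on degenerate inputs", {
  tg <- render_pattern(pattern_recipe("disks", size_px = 64, pixel_pitch = 0.05,
                                      centers = rbind(c(-0.5, 0), c(0.5, 0)),
                                      radii = 0.25))
  q1 <- pattern_quality(tg$amplitude, tg)
  expect_equal(q1$correlation, 1, tolerance = 1e-12)
  expect_equal(q1$uniformity, 1, tolerance = 1e-12)
  q0 <- pattern_quality(matrix(1, 64, 64), tg)
  expect_equal(q0$correlation, 0)
  # mismatched physical extents are rejected
  fld <- field_from_pixels_for_test(matrix(1 + 0i, 32, 32), 0.2, 7, 20, water)
  expect_error(pattern_quality(fld, tg), "extent mismatch")
})

test_that("weighted GSW reproduces a three-disk pattern (regression)", {
  tg <- render_pattern(pattern_recipe("disks", size_px = 128,
                                      pixel_pitch = 0.035,
                                      centers = rbind(c(-1, 0), c(1, 0),
                                                      c(0, 1)), radii = 0.3))
  gs <- gsw_synthesize(tg, water, 20)
  q <- pattern_quality(gs$achieved_field, tg)
  expect_gte(q$correlation, 0.7)
})
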