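# Shared small fixtures; everything is generated in code.

water <- medium()

# small ring for fast propagation tests
small_spec <- function(n = 64, seed = 0)
  ring_array_spec(n_elements = n, pitch = 0.15, sparsify_seed = seed)

# dense (non-sparse) annular cap with surface-patch areas, for quantitative
# comparisons against closed-form radiator solutions
dense_cap <- function(pitch = 0.02) {
  probe <- ring_array_spec(pitch = pitch, n_elements = 1)
  n_cand <- nrow(build_candidate_grid(probe))
  build_ring_geometry(ring_array_spec(pitch = pitch, n_elements = n_cand),
                      area_mode = "lattice")
}

# independent brute-force Rayleigh-Sommerfeld operator: explicit double loop
naive_H <- function(geometry, points, med, frequency) {
  k <- 2 * pi * frequency / (med$sound_speed / 1000)
  pref <- 1i * med$density * (med$sound_speed / 1000) * k / (2 * pi)
  M <- nrow(points); N <- nrow(geometry$positions)
  H <- matrix(0 + 0i, M, N)
  for (m in seq_len(M)) for (n in seq_len(N)) {
    d <- sqrt(sum((points[m, ] - geometry$positions[n, ])^2))
    H[m, n] <- pref * geometry$areas[n] * exp(-1i * k * d) / d
  }
  H
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}

# pixel-center axis of an n-pixel plane (re-derived here, kept independent of
# package internals)
pixel_axis_for_test <- function(n, pitch) (seq_len(n) - (n + 1) / 2) * pitch

# minimal pressure_field wrapper for metric tests
field_from_pixels_for_test <- function(P, pitch, depth, frequency, med) {
  d <- dim(P)
  grid <- structure(list(plane = "lateral", extent = d * pitch,
                         spacing = pitch, depth = depth, offset = 0,
                         axis1 = pixel_axis_for_test(d[1], pitch),
                         axis2 = pixel_axis_for_test(d[2], pitch), dim = d),
                    class = "field_grid")
  structure(list(grid = grid, pressure = P, frequency = frequency,
                 medium = med), class = "pressure_field")
}
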