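#' Target stimulation pattern
#'
#' A normalized 2-D amplitude image to be projected acoustically onto the
#' retinal plane. The default pixel pitch of 0.035 mm makes a 256 x 256
#' pattern span 8.96 x 8.96 mm at the default 7 mm depth.
#'
#' @param amplitude non-negative 2-D matrix; rescaled to max 1.
#' @param pixel_pitch pixel size in mm.
#' @param depth target plane depth in mm.
#' @return An object of class `target_pattern`.
#' @export
target_pattern <- function(amplitude, pixel_pitch = 0.035, depth = 7) {
  amplitude <- as.matrix(amplitude)
  stopifnot(all(is.finite(amplitude)), all(amplitude >= 0),
            pixel_pitch > 0, depth > 0)
  mx <- max(amplitude)
  if (mx == 0) stop("target pattern is identically zero")
  structure(list(amplitude = amplitude / mx, pixel_pitch = pixel_pitch,
                 depth = depth, pixels = dim(amplitude)),
            class = "target_pattern")
}

#' @export
print.target_pattern <- function(x, ...) {
  cat(sprintf("<target_pattern> %d x %d px, pitch %g mm (%.4g x %.4g mm), depth %g mm\n",
              x$pixels[1], x$pixels[2], x$pixel_pitch,
              x$pixels[1] * x$pixel_pitch, x$pixels[2] * x$pixel_pitch,
              x$depth))
  invisible(x)
}

# Circular shifts that move the zero-frequency bin to/from the array center.
fftshift2 <- function(m) {
  d <- dim(m)
  m[c(seq(floor(d[1] / 2) + 1L, d[1]), seq_len(floor(d[1] / 2))),
    c(seq(floor(d[2] / 2) + 1L, d[2]), seq_len(floor(d[2] / 2)))]
}
ifftshift2 <- function(m) {
  d <- dim(m)
  m[c(seq(ceiling(d[1] / 2) + 1L, d[1]), seq_len(ceiling(d[1] / 2))),
    c(seq(ceiling(d[2] / 2) + 1L, d[2]), seq_len(ceiling(d[2] / 2)))]
}

# DFT sample frequencies (cycles per unit length) in fft bin order.
fft_freqs <- function(n, pitch) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * pitch)
}

#' Angular-spectrum propagation of a sampled field
#'
#' Propagates a complex field sampled on a square-pixel plane by a distance
#' `dz` (either sign): the 2-D spatial-frequency transform is multiplied by
#' the exact homogeneous-medium transfer function
#' \eqn{\exp(-j\, dz \sqrt{k^2 - k_x^2 - k_y^2})} on the propagating band
#' (the sign matches the package-wide \eqn{e^{j(\omega t - kd)}} phase
#' convention, so +dz propagation accrues the same negative phase as the
#' Rayleigh-Sommerfeld operator), while evanescent components
#' (\eqn{k_x^2 + k_y^2 > k^2}) are zeroed.
#'
#' @param field complex 2-D matrix.
#' @param pitch pixel pitch in mm (square pixels; sampling coarser than
#'   \eqn{\lambda/2} triggers a warning).
#' @param dz propagation distance in mm.
#' @param medium a [medium()].
#' @param frequency MHz.
#' @return complex matrix of the field at z + dz.
#' @export
angular_spectrum_propagate <- function(field, pitch, dz,
                                       medium = ringfus::medium(), frequency) {
  field <- as.matrix(field)
  stopifnot(is.numeric(pitch), length(pitch) == 1L, pitch > 0)
  lam <- wavelength_mm(frequency, medium)
  if (pitch > lam / 2 + 1e-12)
    warning(sprintf("pixel pitch %g mm exceeds lambda/2 = %g mm; the angular spectrum is undersampled",
                    pitch, lam / 2))
  k <- 2 * pi / lam
  d <- dim(field)
  kx <- 2 * pi * fft_freqs(d[1], pitch)
  ky <- 2 * pi * fft_freqs(d[2], pitch)
  kz2 <- outer(kx^2, ky^2, "+")
  prop <- kz2 <= k^2
  kz <- sqrt(pmax(k^2 - kz2, 0))
  transfer <- ifelse(prop, exp(-1i * dz * kz), 0 + 0i)
  stats::fft(stats::fft(field) * transfer, inverse = TRUE) / prod(d)
}

#' Aperture function from a target image (single-transform initializer)
#'
#' Computes the complex aperture whose far-field (Fraunhofer) pattern is the
#' target image, via a centered unnormalized inverse 2-D DFT scaled by
#' \eqn{1/(\lambda z)}. This is the one-shot Fourier-holography relation; the
#' angular-spectrum propagator is the authoritative forward model at finite
#' depth, and this transform serves as an initializer / diagnostic.
#'
#' @param target a [target_pattern()] (or bare matrix).
#' @inheritParams angular_spectrum_propagate
#' @return complex matrix, the aperture before any phase-only constraint.
#' @seealso [aperture_to_image()] for the exact inverse.
#' @export
image_to_aperture <- function(target, medium = ringfus::medium(), frequency) {
  I <- if (inherits(target, "target_pattern")) target$amplitude else as.matrix(target)
  z <- if (inherits(target, "target_pattern")) target$depth else 7
  lam <- wavelength_mm(frequency, medium)
  fftshift2(stats::fft(ifftshift2(I), inverse = TRUE)) / (lam * z)
}

#' @rdname image_to_aperture
#' @param aperture complex matrix as returned by [image_to_aperture()].
#' @param depth target plane depth in mm.
#' @export
aperture_to_image <- function(aperture, medium = ringfus::medium(), frequency,
                              depth = 7) {
  lam <- wavelength_mm(frequency, medium)
  fftshift2(stats::fft(ifftshift2(aperture))) * (lam * depth) / length(aperture)
}

# Pixel-center axis of an n-pixel plane with pitch p, centered on the origin.
pixel_axis <- function(n, pitch) (seq_len(n) - (n + 1) / 2) * pitch

# pressure_field wrapper around a pixel-sampled lateral complex field.
field_from_pixels <- function(P, pitch, depth, frequency, medium,
                              excitation_ref = "hologram") {
  d <- dim(P)
  grid <- structure(list(plane = "lateral", extent = d * pitch,
                         spacing = pitch, depth = depth, offset = 0,
                         axis1 = pixel_axis(d[1], pitch),
                         axis2 = pixel_axis(d[2], pitch), dim = d),
                    class = "field_grid")
  structure(list(grid = grid, pressure = P, frequency = frequency,
                 medium = medium, excitation_ref = excitation_ref),
            class = "pressure_field")
}

#' Weighted Gerchberg-Saxton pattern synthesis
#'
#' Retrieves a phase-only source-plane hologram whose propagated field
#' reproduces a target amplitude image at depth `z`, by alternating
#' angular-spectrum propagation between the source plane (z = 0) and the
#' target plane:
#' \enumerate{
#'   \item propagate the phase-only source to the target plane;
#'   \item on target-support pixels replace the amplitude by the weighted
#'     target \eqn{w I} and update the weights by the equalizing rule
#'     \eqn{w_s \leftarrow w_s \langle|V|\rangle_{supp} / |V_s|} (clamped);
#'     off-support pixels in the padding border keep their computed values
#'     (amplitude freedom);
#'   \item back-propagate to the source plane;
#'   \item restore unit amplitude on the source aperture (phase-only
#'     constraint), zero outside.
#' }
#' Support pixels are those with \eqn{I \ge} `support_threshold` times the
#' image maximum. Uniformity is \eqn{1 - (\max - \min)/(\max + \min)} of
#' \eqn{|V|} over the support. The loop runs the standard weighted update
#' and returns the final iterate; it stops early only when the support
#' uniformity reaches `1 - tol` (converged). Because the raw per-iteration
#' uniformity oscillates (the amplitude replacement can transiently worsen
#' the support spread before the weights absorb it), `uniformity_history`
#' reports the running-best uniformity — a monotone convergence monitor —
#' while the raw trace is kept in `uniformity_trace`.
#'
#' @param target a [target_pattern()].
#' @inheritParams angular_spectrum_propagate
#' @param max_iter maximum GSW iterations.
#' @param tol convergence margin: iteration stops once the support
#'   uniformity reaches `1 - tol`.
#' @param support_threshold support definition, fraction of the image max.
#' @param pad_factor zero-padding factor of the transform plane (suppresses
#'   wrap-around).
#' @param seed seed of the random initial-phase perturbation.
#' @param init_perturb half-range (rad) of the uniform initial perturbation
#'   added to the focusing phase toward the pattern centroid.
#' @param weight_clamp allowed weight range.
#' @return An object of class `gsw_result`: `hologram` (class `hologram`:
#'   phase matrix in (-pi, pi], pixel pitch, plane z = 0), `achieved_field`
#'   (a `pressure_field` on the target plane), `weights`, `iterations_run`,
#'   `uniformity_history` (running-best uniformity after each iteration),
#'   `uniformity_trace` (raw per-iteration values), `efficiency` (fraction
#'   of propagated energy on the support).
#' @export
gsw_synthesize <- function(target, medium = ringfus::medium(), frequency = 20,
                           max_iter = 50, tol = 1e-4, support_threshold = 0.1,
                           pad_factor = 2, seed = 1, init_perturb = 0.5,
                           weight_clamp = c(1e-3, 1e3)) {
  stopifnot(inherits(target, "target_pattern"), max_iter >= 1)
  I <- target$amplitude
  d <- dim(I)
  np <- pad_factor * d
  pitch <- target$pixel_pitch
  z <- target$depth
  sup_small <- I >= support_threshold * max(I)
  if (!any(sup_small)) stop("empty support: no pixel reaches support_threshold")

  # embed target (and masks) centered in the padded plane
  off <- floor((np - d) / 2)
  idx1 <- off[1] + seq_len(d[1]); idx2 <- off[2] + seq_len(d[2])
  I_pad <- matrix(0, np[1], np[2]); I_pad[idx1, idx2] <- I
  sup <- matrix(FALSE, np[1], np[2]); sup[idx1, idx2] <- sup_small
  src <- matrix(FALSE, np[1], np[2]); src[idx1, idx2] <- TRUE
  block <- matrix(FALSE, np[1], np[2]); block[idx1, idx2] <- TRUE

  # initial phase: focusing lens toward the pattern centroid + perturbation
  ax1 <- pixel_axis(np[1], pitch); ax2 <- pixel_axis(np[2], pitch)
  w_img <- sum(I)
  cx <- sum(pixel_axis(d[1], pitch) * rowSums(I)) / w_img
  cy <- sum(pixel_axis(d[2], pitch) * colSums(I)) / w_img
  k <- wavenumber(frequency, medium)
  dist <- sqrt(outer((ax1 - cx)^2, (ax2 - cy)^2, "+") + z^2)
  phase <- k * dist +
    with_seed(seed, matrix(stats::runif(prod(np), -init_perturb, init_perturb),
                           np[1], np[2]))

  propagate_src <- function(ph) {
    A <- matrix(0 + 0i, np[1], np[2])
    A[src] <- exp(1i * ph[src])
    angular_spectrum_propagate(A, pitch, z, medium, frequency)
  }
  uniformity <- function(amp_sup)
    1 - (max(amp_sup) - min(amp_sup)) / (max(amp_sup) + min(amp_sup))

  w <- rep(1, sum(sup))
  trace <- numeric(0)
  V <- NULL
  for (it in seq_len(max_iter)) {
    V <- propagate_src(phase)
    amp_sup <- Mod(V[sup])
    u <- uniformity(amp_sup)
    trace <- c(trace, u)
    if (u >= 1 - tol) break
    # amplitude constraint on the target block; freedom in the padding border
    w <- pmin(pmax(w * mean(amp_sup) / pmax(amp_sup, 1e-30),
                   weight_clamp[1]), weight_clamp[2])
    Vc <- V
    Vc[block] <- I_pad[block] * exp(1i * Arg(V[block]))
    Vc[sup] <- (w * I_pad[sup]) * exp(1i * Arg(V[sup]))
    Ab <- angular_spectrum_propagate(Vc, pitch, -z, medium, frequency)
    phase <- Arg(Ab)
    if (it == max_iter) V <- propagate_src(phase)
  }
  energy <- Mod(V)^2
  eff <- sum(energy[sup]) / sum(energy)
  holo <- structure(list(phase = matrix(phase[src], d[1], d[2]),
                         source_pixel_pitch = pitch, plane_z = 0),
                    class = "hologram")
  achieved <- field_from_pixels(matrix(V[block], d[1], d[2]), pitch, z,
                                frequency, medium, "gsw hologram")
  structure(list(hologram = holo, achieved_field = achieved,
                 weights = w, iterations_run = length(trace),
                 uniformity_history = cummax(trace),
                 uniformity_trace = trace, efficiency = eff,
                 frequency = frequency, seed = seed),
            class = "gsw_result")
}

#' @export
print.gsw_result <- function(x, ...) {
  cat(sprintf("<gsw_result> %d iterations, uniformity %.4f, efficiency %.3f, f = %g MHz\n",
              x$iterations_run, utils::tail(x$uniformity_history, 1),
              x$efficiency, x$frequency))
  invisible(x)
}

#' Sample a planar hologram onto the curved ring array
#'
#' Maps each array element to the nearest hologram pixel under its (x, y)
#' projection and compensates the spherical-cap sag so that the curved array
#' reproduces the planar hologram's wavefront: an element sitting at
#' z = sag (closer to the target than the z = 0 hologram plane) has the
#' paraxial phase advance `k * sag` removed. Amplitudes are uniform.
#'
#' @param hologram a `hologram` (from [gsw_synthesize()]).
#' @param geometry a `ring_array_geometry` whose elements must all project
#'   inside the hologram extent.
#' @inheritParams angular_spectrum_propagate
#' @return complex excitation vector.
#' @export
sample_hologram_to_elements <- function(hologram, geometry,
                                        medium = ringfus::medium(), frequency) {
  stopifnot(inherits(hologram, "hologram"))
  d <- dim(hologram$phase)
  p <- hologram$source_pixel_pitch
  ix <- round(geometry$positions[, 1] / p + (d[1] + 1) / 2)
  iy <- round(geometry$positions[, 2] / p + (d[2] + 1) / 2)
  out <- which(ix < 1 | ix > d[1] | iy < 1 | iy > d[2])
  if (length(out))
    stop("elements project outside the hologram extent: ",
         paste(utils::head(out, 20), collapse = ", "),
         if (length(out) > 20) sprintf(" ... (%d total)", length(out)) else "")
  k <- wavenumber(frequency, medium)
  ph <- hologram$phase[cbind(ix, iy)] - k * geometry$positions[, 3]
  exp(1i * ph)
}

#' Pattern fidelity metrics
#'
#' Compares an achieved field-magnitude map with its target image on the same
#' physical extent: normalized (zero-mean) cross-correlation, support
#' uniformity, and the fraction of field energy landing on the target
#' support.
#'
#' @param achieved a `pressure_field` on the target plane (or a magnitude
#'   matrix with the target's extent).
#' @param target a [target_pattern()].
#' @param support_threshold support definition, fraction of the image max.
#' @return list with `correlation`, `uniformity`, `efficiency`.
#' @export
pattern_quality <- function(achieved, target, support_threshold = 0.1) {
  stopifnot(inherits(target, "target_pattern"))
  A <- if (inherits(achieved, "pressure_field")) {
    ext_a <- achieved$grid$dim * achieved$grid$spacing
    ext_t <- target$pixels * target$pixel_pitch
    if (any(abs(ext_a - ext_t) / ext_t > 0.01))
      stop("extent mismatch: achieved ", paste(signif(ext_a, 4), collapse = " x "),
           " mm vs target ", paste(signif(ext_t, 4), collapse = " x "), " mm")
    Mod(achieved$pressure)
  } else as.matrix(achieved)
  I <- target$amplitude
  if (!all(dim(A) == dim(I))) {       # nearest-neighbour resample to target px
    i1 <- pmin(pmax(round(seq(1, nrow(A), length.out = nrow(I))), 1), nrow(A))
    i2 <- pmin(pmax(round(seq(1, ncol(A), length.out = ncol(I))), 1), ncol(A))
    A <- A[i1, i2]
  }
  corr <- if (stats::sd(A) == 0 || stats::sd(I) == 0) 0
          else stats::cor(as.vector(A), as.vector(I))
  sup <- I >= support_threshold * max(I)
  amp <- A[sup]
  unif <- 1 - (max(amp) - min(amp)) / (max(amp) + min(amp))
  eff <- sum(A[sup]^2) / sum(A^2)
  list(correlation = corr, uniformity = unif, efficiency = eff)
}
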