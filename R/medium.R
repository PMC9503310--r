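#' Acoustic propagation medium
#'
#' Describes the homogeneous medium (vitreous-like by default) in which
#' continuous-wave fields are propagated. Attenuation follows the power law
#' \eqn{a(f) = a_0 f^\gamma} in dB/cm with \eqn{f} in MHz; it is applied only
#' where explicitly requested (dosimetry pipelines), never silently.
#'
#' Internally the package works in mm / MHz / microseconds, so the sound
#' speed is converted once to mm/us (1500 m/s = 1.5 mm/us); all user-facing
#' arguments stay in the SI-style units documented here.
#'
#' @param sound_speed speed of sound in m/s (default 1500).
#' @param density mass density in kg/m^3 (default 1000).
#' @param attenuation_a0 attenuation coefficient at 1 MHz, dB/cm (default 0.1,
#'   a vitreous-like value; see [calibrate_lens_a0()] to match a measured
#'   through-tissue loss).
#' @param attenuation_gamma power-law exponent, constrained to [1.0, 1.9].
#' @return An object of class `fus_medium`.
#' @examples
#' m <- medium()
#' wavelength_mm(20, m)  # 0.075 mm at 20 MHz
#' @export
medium <- function(sound_speed = 1500, density = 1000,
                   attenuation_a0 = 0.1, attenuation_gamma = 1.2) {
  stopifnot(is.numeric(sound_speed), length(sound_speed) == 1L, sound_speed > 0,
            is.numeric(density), length(density) == 1L, density > 0,
            is.numeric(attenuation_a0), attenuation_a0 >= 0)
  if (attenuation_gamma < 1.0 || attenuation_gamma > 1.9)
    stop("attenuation_gamma must lie in [1.0, 1.9], got ", attenuation_gamma)
  structure(list(sound_speed = sound_speed,
                 density = density,
                 attenuation_a0 = attenuation_a0,
                 attenuation_gamma = attenuation_gamma),
            class = "fus_medium")
}

#' @export
print.fus_medium <- function(x, ...) {
  cat(sprintf("<fus_medium> c = %g m/s, rho = %g kg/m^3, a0 = %g dB/cm @ 1 MHz, gamma = %g\n",
              x$sound_speed, x$density, x$attenuation_a0, x$attenuation_gamma))
  invisible(x)
}

#' Acoustic wavelength
#'
#' @param frequency frequency in MHz.
#' @param medium a [medium()] object.
#' @return wavelength in mm (\eqn{\lambda = c/f}).
#' @export
wavelength_mm <- function(frequency, medium = ringfus::medium()) {
  stopifnot(frequency > 0)
  (medium$sound_speed / 1000) / frequency
}

#' Acoustic wavenumber
#'
#' @inheritParams wavelength_mm
#' @return wavenumber \eqn{k = 2\pi f / c} in rad/mm.
#' @export
wavenumber <- function(frequency, medium = ringfus::medium()) {
  2 * pi / wavelength_mm(frequency, medium)
}

# Evaluate code with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is restored on exit so geometry construction never perturbs
# user-level randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}
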