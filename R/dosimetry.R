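#' Dosimetry / frequency-selection parameters
#'
#' Constants of the resolution, stimulation-efficacy and attenuation scaling
#' laws used to compare candidate stimulation frequencies.
#'
#' @param K diffraction-limit constant in \eqn{D_l = K \lambda F_\#}
#'   (typically 1).
#' @param f_number system F-number (focal distance / aperture).
#' @param beta sonophore strain exponent, constrained to [0.8, 0.9]; the
#'   maximal areal membrane strain scales as
#'   \eqn{\epsilon_{max} \propto P_A f^{-\beta}}.
#' @param a0 attenuation coefficient at 1 MHz, dB/cm.
#' @param gamma attenuation power-law exponent, in [1.0, 1.9].
#' @param intensity_limit regulatory ophthalmic intensity ceiling, mW/cm^2
#'   (default 50).
#' @return An object of class `dose_params`.
#' @export
dose_params <- function(K = 1, f_number = 1, beta = 0.85,
                        a0 = 0.1, gamma = 1.2, intensity_limit = 50) {
  stopifnot(K > 0, f_number > 0, a0 >= 0, intensity_limit > 0)
  if (beta < 0.8 || beta > 0.9)
    stop("beta must lie in [0.8, 0.9], got ", beta)
  if (gamma < 1.0 || gamma > 1.9)
    stop("gamma must lie in [1.0, 1.9], got ", gamma)
  structure(list(K = K, f_number = f_number, beta = beta, a0 = a0,
                 gamma = gamma, intensity_limit = intensity_limit),
            class = "dose_params")
}

#' Diffraction-limited lateral resolution
#'
#' \eqn{D_l = K \lambda F_\# = K (v/f) F_\#}: the FWHM-scale focal width set
#' by wavelength and F-number.
#'
#' @param frequency MHz.
#' @param params a [dose_params()].
#' @param medium a [medium()] supplying the sound speed v.
#' @return resolution in mm. At 20 MHz, v = 1500 m/s, K = F# = 1 this is
#'   0.075 mm — one wavelength, the reference element pitch.
#' @export
fwhm_resolution <- function(frequency, params = dose_params(),
                            medium = ringfus::medium()) {
  stopifnot(frequency > 0)
  params$K * wavelength_mm(frequency, medium) * params$f_number
}

#' Pressure scaling required to hold stimulation efficacy across frequency
#'
#' Under the bilayer-sonophore strain law \eqn{\epsilon_{max} \propto
#' P_A f^{-\beta}}, keeping the maximal areal strain constant when moving
#' from `f1` to `f2` requires the negative peak pressure to grow by
#' \eqn{(f_2/f_1)^\beta}. The exponent rule is swappable because the
#' literature also quotes \eqn{\beta/2} and \eqn{1/(2\beta)} forms.
#'
#' @param f1,f2 frequencies in MHz.
#' @param params a [dose_params()].
#' @param rule exponent interpretation: `"beta"` (default), `"half_beta"`
#'   (\eqn{\beta/2}) or `"inv_two_beta"` (\eqn{1/(2\beta)}).
#' @return dimensionless pressure ratio \eqn{P_A(f_2)/P_A(f_1)}.
#' @export
required_pressure_ratio <- function(f1, f2, params = dose_params(),
                                    rule = c("beta", "half_beta", "inv_two_beta")) {
  stopifnot(f1 > 0, f2 > 0)
  rule <- match.arg(rule)
  expo <- switch(rule, beta = params$beta, half_beta = params$beta / 2,
                 inv_two_beta = 1 / (2 * params$beta))
  (f2 / f1)^expo
}

#' Power-law attenuation over a path
#'
#' \eqn{a(f) = a_0 f^\gamma} in dB/cm, integrated over `path_cm`.
#'
#' @param frequency MHz.
#' @param path_cm path length in cm.
#' @param params a [dose_params()].
#' @return total attenuation in dB.
#' @export
attenuation_db <- function(frequency, path_cm, params = dose_params()) {
  stopifnot(frequency > 0, path_cm >= 0)
  params$a0 * frequency^params$gamma * path_cm
}

#' Calibrate a0 from a measured through-tissue loss
#'
#' Chooses the 1 MHz coefficient so that the power law reproduces a measured
#' total loss at a given frequency and path — e.g. the crystalline lens's
#' 7.8 dB at 10 MHz.
#'
#' @param total_db measured loss in dB.
#' @param frequency measurement frequency, MHz.
#' @param path_cm tissue path, cm.
#' @param gamma power-law exponent.
#' @return a0 in dB/cm at 1 MHz.
#' @export
calibrate_lens_a0 <- function(total_db = 7.8, frequency = 10, path_cm = 0.4,
                              gamma = 1.2) {
  stopifnot(total_db >= 0, frequency > 0, path_cm > 0)
  total_db / (frequency^gamma * path_cm)
}

#' Ophthalmic acoustic power budget
#'
#' Converts the regulatory intensity ceiling (mW/cm^2, spatial-average style)
#' into the maximum time-average acoustic power deliverable over a square
#' stimulation pattern of side `pattern_side` mm. When a `stated_budget_mW`
#' is supplied, the result reports whether the limit-derived power stays
#' within it and the intensity that the stated budget would imply over the
#' same area — a stated budget exceeding `intensity_limit * area` is flagged
#' rather than silently accepted.
#'
#' @param pattern_side side of the square pattern, mm.
#' @param params a [dose_params()].
#' @param stated_budget_mW optional externally stated power requirement to
#'   check against.
#' @return list with `area_cm2`, `max_power_mW`, and, when a budget is given,
#'   `stated_budget_mW`, `within_budget`, `implied_intensity_mW_cm2` and a
#'   human-readable `note` flagging any inconsistency.
#' @export
safety_power_budget <- function(pattern_side, params = dose_params(),
                                stated_budget_mW = NULL) {
  stopifnot(pattern_side > 0)
  area <- (pattern_side / 10)^2
  max_power <- params$intensity_limit * area
  out <- list(area_cm2 = area, max_power_mW = max_power,
              intensity_limit_mW_cm2 = params$intensity_limit)
  if (!is.null(stated_budget_mW)) {
    implied <- stated_budget_mW / area
    out$stated_budget_mW <- stated_budget_mW
    out$within_budget <- max_power <= stated_budget_mW
    out$implied_intensity_mW_cm2 <- implied
    out$note <- if (implied > params$intensity_limit * 1.001) {
      sprintf(paste0("stated budget %.4g mW over %.4g cm^2 implies ",
                     "%.4g mW/cm^2, exceeding the %.4g mW/cm^2 limit; ",
                     "the limit-compliant power is %.4g mW"),
              stated_budget_mW, area, implied, params$intensity_limit,
              max_power)
    } else "stated budget is consistent with the intensity limit"
  }
  out
}
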