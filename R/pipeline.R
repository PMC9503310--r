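#' Single-focus field study
#'
#' End-to-end convenience wrapper for the resolution experiments: builds the
#' ring geometry, drives a single focus at `(0, 0, depth)` (conjugate-phase
#' by default, or the minimum-norm solution), evaluates the field on a
#' lateral or axial plane and measures the -3 dB beam widths.
#'
#' @param spec a [ring_array_spec()].
#' @param frequency MHz (default: `spec$center_frequency`).
#' @param depth focal depth in mm.
#' @param plane `"lateral"` or `"axial"`.
#' @param extent,spacing grid geometry (see [field_grid()]).
#' @param medium a [medium()].
#' @param method excitation solver: `"conjugate"` phase or `"minnorm"`.
#' @return list with `geometry`, `excitation`, `field` (a `pressure_field`)
#'   and `widths` (from [measure_beam_widths()]).
#' @export
single_focus_field <- function(spec = ring_array_spec(),
                               frequency = spec$center_frequency,
                               depth = 7, plane = c("lateral", "axial"),
                               extent = NULL, spacing = 0.01,
                               medium = ringfus::medium(),
                               method = c("conjugate", "minnorm")) {
  plane <- match.arg(plane)
  method <- match.arg(method)
  geom <- build_ring_geometry(spec)
  focus <- c(0, 0, depth)
  exc <- if (method == "conjugate") {
    conjugate_phase_excitation(geom, focus, medium, frequency)
  } else {
    H <- build_propagator(geom, matrix(focus, ncol = 3), medium, frequency)
    solve_min_norm(H, focus_set(focus))$excitation
  }
  grid <- field_grid(plane, extent = extent, spacing = spacing, depth = depth)
  fld <- evaluate_field(geom, exc, grid, medium, frequency)
  list(geometry = geom, excitation = exc, field = fld,
       widths = measure_beam_widths(fld))
}

#' Image-to-pattern synthesis pipeline
#'
#' Runs the full holographic chain on a target image: weighted
#' Gerchberg-Saxton synthesis on the planar source plane and, optionally,
#' sampling of the hologram onto the curved ring array followed by a
#' Rayleigh-Sommerfeld re-evaluation of the achieved pattern. Quality
#' metrics always refer to the field the selected path actually produced,
#' and the report records which path that was.
#'
#' @param target a [target_pattern()].
#' @param frequency MHz.
#' @param medium a [medium()].
#' @param path `"planar"` evaluates the pattern from the planar hologram by
#'   angular-spectrum propagation; `"elements"` additionally samples the
#'   hologram onto `geometry` and recomputes the field with the discrete
#'   forward model (requires every element to project inside the hologram
#'   extent).
#' @param geometry ring geometry for the `"elements"` path.
#' @param out_dir if non-`NULL`, writes `hologram.pgm` / `hologram.csv`,
#'   `achieved_magnitude.pgm`, and `report.json` there.
#' @param ... further arguments passed to [gsw_synthesize()].
#' @return list with `gsw` (the `gsw_result`), `achieved` (the evaluated
#'   `pressure_field`), `quality` (from [pattern_quality()]), `path`, and
#'   `report` (the written summary list).
#' @export
pattern_pipeline <- function(target, frequency = 20,
                             medium = ringfus::medium(),
                             path = c("planar", "elements"),
                             geometry = NULL, out_dir = NULL, ...) {
  path <- match.arg(path)
  gsw <- gsw_synthesize(target, medium, frequency, ...)
  achieved <- gsw$achieved_field
  excitation <- NULL
  if (path == "elements") {
    if (is.null(geometry)) stop("the 'elements' path needs a geometry")
    excitation <- sample_hologram_to_elements(gsw$hologram, geometry,
                                              medium, frequency)
    ext <- target$pixels * target$pixel_pitch
    grid <- field_grid("lateral", extent = ext,
                       spacing = target$pixel_pitch, depth = target$depth)
    achieved <- evaluate_field(geometry, excitation, grid, medium, frequency)
  }
  quality <- pattern_quality(achieved, target)
  report <- list(path = path, frequency_MHz = frequency,
                 depth_mm = target$depth,
                 pattern_px = target$pixels,
                 pattern_side_mm = target$pixels * target$pixel_pitch,
                 iterations = gsw$iterations_run,
                 uniformity = utils::tail(gsw$uniformity_history, 1),
                 gsw_efficiency = gsw$efficiency,
                 quality = quality, seed = gsw$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_hologram(gsw$hologram,
                   path_csv = file.path(out_dir, "hologram.csv"),
                   path_pgm = file.path(out_dir, "hologram.pgm"))
    write_field_pgm(achieved, file.path(out_dir, "achieved_magnitude.pgm"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(gsw = gsw, achieved = achieved, quality = quality, path = path,
       excitation = excitation, report = report)
}

#' Frequency-selection dosimetry report
#'
#' Bundles the four analytic dose quantities for one operating point.
#'
#' @param frequency MHz.
#' @param params a [dose_params()].
#' @param medium a [medium()].
#' @param depth_cm tissue path for the attenuation figure, cm.
#' @param pattern_side pattern side for the power budget, mm.
#' @param stated_budget_mW optional stated power requirement to check.
#' @param f_ref reference frequency for the pressure-ratio figure, MHz.
#' @return list suitable for JSON serialization.
#' @export
dose_report <- function(frequency = 20, params = dose_params(),
                        medium = ringfus::medium(), depth_cm = 0.7,
                        pattern_side = 8.96, stated_budget_mW = NULL,
                        f_ref = 1) {
  budget <- safety_power_budget(pattern_side, params, stated_budget_mW)
  list(frequency_MHz = frequency,
       resolution_mm = fwhm_resolution(frequency, params, medium),
       pressure_ratio_vs_ref = required_pressure_ratio(f_ref, frequency, params),
       reference_frequency_MHz = f_ref,
       attenuation_db_at_depth = attenuation_db(frequency, depth_cm, params),
       depth_cm = depth_cm,
       budget = budget)
}
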