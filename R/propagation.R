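#' Field sampling grid
#'
#' A regular sampling plane for pressure evaluation: `"lateral"` is an X-Y
#' plane at depth `depth` (the retinal target plane); `"axial"` is an X-Z
#' plane at lateral offset `y = offset`, with z spanning `extent[2]` centered
#' on `depth`.
#'
#' @param plane `"lateral"` or `"axial"`.
#' @param extent plane side lengths in mm, length 2 (first axis x; second
#'   axis y for lateral planes, z for axial planes). Defaults match the
#'   reference field maps: 1.5 x 1.5 mm lateral, 1.5 x 10 mm axial.
#' @param spacing sample spacing in mm (default 0.01 = 10 um).
#' @param depth target depth in mm (default 7, the rat-eye retina).
#' @param offset y offset of an axial plane, mm.
#' @return An object of class `field_grid`.
#' @export
field_grid <- function(plane = c("lateral", "axial"), extent = NULL,
                       spacing = 0.01, depth = 7, offset = 0) {
  plane <- match.arg(plane)
  if (is.null(extent)) extent <- if (plane == "lateral") c(1.5, 1.5) else c(1.5, 10)
  extent <- rep_len(extent, 2)
  stopifnot(spacing > 0, all(extent > 0))
  ax1 <- seq(-extent[1] / 2, extent[1] / 2, by = spacing)
  ax2 <- if (plane == "lateral") {
    seq(-extent[2] / 2, extent[2] / 2, by = spacing)
  } else {
    seq(depth - extent[2] / 2, depth + extent[2] / 2, by = spacing)
  }
  structure(list(plane = plane, extent = extent, spacing = spacing,
                 depth = depth, offset = offset, axis1 = ax1, axis2 = ax2,
                 dim = c(length(ax1), length(ax2))),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %s plane, %d x %d samples, spacing %g mm, depth %g mm\n",
              x$plane, x$dim[1], x$dim[2], x$spacing, x$depth))
  invisible(x)
}

#' Field-point coordinates of a grid
#'
#' @param grid a [field_grid()].
#' @return M x 3 matrix of (x, y, z) in mm; axis 1 (x) varies fastest, so the
#'   M rows unravel column-by-column into the `dim(grid)` pressure matrix.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "field_grid"))
  g <- expand.grid(a = grid$axis1, b = grid$axis2, KEEP.OUT.ATTRS = FALSE)
  if (grid$plane == "lateral") {
    cbind(x = g$a, y = g$b, z = rep(grid$depth, nrow(g)))
  } else {
    cbind(x = g$a, y = rep(grid$offset, nrow(g)), z = g$b)
  }
}

# Pairwise distances (mm) between M field points and N element positions.
pairwise_distances <- function(points, positions) {
  p2 <- rowSums(points^2)
  e2 <- rowSums(positions^2)
  d2 <- outer(p2, e2, "+") - 2 * tcrossprod(points, positions)
  sqrt(pmax(d2, 0))
}

# Attenuation in nepers per mm at `frequency` MHz from the medium's power law
# a0 * f^gamma (dB/cm): 1 Np = 20/log(10) dB, 1 cm = 10 mm.
alpha_np_per_mm <- function(frequency, medium) {
  db_per_cm <- medium$attenuation_a0 * frequency^medium$attenuation_gamma
  db_per_cm / (20 / log(10)) / 10
}

#' Discretized Rayleigh-Sommerfeld forward operator
#'
#' Builds the complex M x N matrix H mapping element excitation velocities U
#' to complex pressures P = H U at the M field points. Each element is a
#' baffled point source radiating a spherical wave with amplitude
#' proportional to its area:
#' \deqn{H_{mn} = \frac{j \rho c k}{2\pi} \, S_n \,
#'   \frac{e^{-j k d_{mn}}}{d_{mn}},}
#' with \eqn{d_{mn}} the element-to-point distance. The harmonic time factor
#' \eqn{e^{j\omega t}} is dropped: entries are complex amplitudes at t = 0,
#' and conjugate (+kd) phases therefore focus. Pressures carry the mixed
#' mm/MHz unit system and are meaningful up to a common scale; all beam
#' metrics and dB maps are relative.
#'
#' @param geometry a `ring_array_geometry`.
#' @param points M x 3 matrix of field points (mm), or a [field_grid()].
#' @param medium a [medium()].
#' @param frequency MHz.
#' @param attenuate if `TRUE`, each entry is damped by `exp(-alpha d)` with
#'   alpha from the medium's power law (off by default: reference field maps
#'   are lossless).
#' @return An object of class `propagation_operator` wrapping the matrix
#'   (`$matrix`) plus the inputs it was built from.
#' @export
build_propagator <- function(geometry, points, medium = ringfus::medium(),
                             frequency, attenuate = FALSE) {
  if (inherits(points, "field_grid")) points <- grid_points(points)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, frequency > 0)
  d <- pairwise_distances(points, geometry$positions)
  dmin <- min(d)
  if (dmin < 1e-9) {
    idx <- which(d == dmin, arr.ind = TRUE)[1, ]
    stop(sprintf("singular distance: field point %d coincides with element %d",
                 idx[1], idx[2]))
  }
  k <- wavenumber(frequency, medium)
  c_mm_us <- medium$sound_speed / 1000
  pref <- 1i * medium$density * c_mm_us * k / (2 * pi)
  H <- pref * exp(-1i * k * d) / d
  if (attenuate) H <- H * exp(-alpha_np_per_mm(frequency, medium) * d)
  H <- sweep(H, 2, geometry$areas, "*")
  structure(list(matrix = H, field_points = points, geometry = geometry,
                 medium = medium, frequency = frequency,
                 attenuate = attenuate),
            class = "propagation_operator")
}

#' Conjugate-phase (time-reversal) focusing excitation
#'
#' The classic delay-and-sum law: each element is driven with unit amplitude
#' and phase `+k d_n`, cancelling the propagation phase `-k d_n` to the focus.
#'
#' @param geometry a `ring_array_geometry`.
#' @param focus length-3 focal point (mm).
#' @inheritParams build_propagator
#' @return complex excitation vector of length N.
#' @export
conjugate_phase_excitation <- function(geometry, focus,
                                       medium = ringfus::medium(), frequency) {
  d <- sqrt(colSums((t(geometry$positions) - focus)^2))
  exp(1i * wavenumber(frequency, medium) * d)
}

#' Evaluate the pressure field on a grid
#'
#' Computes P = H U over the grid points without materializing H for large
#' grids (elements are processed in chunks).
#'
#' @param geometry a `ring_array_geometry`.
#' @param excitation complex excitation vector (length = element count).
#' @param grid a [field_grid()].
#' @inheritParams build_propagator
#' @param chunk elements per block in the accumulation.
#' @return An object of class `pressure_field`: the complex pressure matrix
#'   (`$pressure`, dim = grid dim), the grid, and provenance fields.
#' @export
evaluate_field <- function(geometry, excitation, grid,
                           medium = ringfus::medium(), frequency,
                           attenuate = FALSE, chunk = 128L) {
  stopifnot(inherits(grid, "field_grid"))
  n <- nrow(geometry$positions)
  if (length(excitation) != n)
    stop("excitation length ", length(excitation),
         " does not match element count ", n)
  pts <- grid_points(grid)
  P <- complex(nrow(pts))
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    sub <- array_geometry(geometry$positions[i0:i1, , drop = FALSE],
                          areas = geometry$areas[i0:i1])
    Hc <- build_propagator(sub, pts, medium, frequency, attenuate)$matrix
    P <- P + as.vector(Hc %*% excitation[i0:i1])
  }
  structure(list(grid = grid,
                 pressure = matrix(P, nrow = grid$dim[1], ncol = grid$dim[2]),
                 frequency = frequency, medium = medium,
                 excitation_ref = deparse1(substitute(excitation))),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> %s plane %d x %d, f = %g MHz, |P| in [%.3g, %.3g]\n",
              x$grid$plane, x$grid$dim[1], x$grid$dim[2], x$frequency,
              min(Mod(x$pressure)), max(Mod(x$pressure))))
  invisible(x)
}

#' Normalized magnitude map in dB
#'
#' @param field a `pressure_field`.
#' @param floor_db clip level for zero-pressure samples.
#' @return matrix of `20 log10(|P| / max |P|)`, 0 dB at the grid maximum.
#' @export
magnitude_db <- function(field, floor_db = -120) {
  m <- Mod(field$pressure)
  m <- m / max(m)
  pmax(20 * log10(pmax(m, .Machine$double.xmin)), floor_db)
}

# Interpolated half-width from a 1-D intensity profile, walking outward from
# the peak at `ipk` in direction `step` until intensity crosses `thr`.
# Returns NA when the profile never crosses inside the grid.
half_width_1d <- function(intens, ipk, step, thr, spacing) {
  i <- ipk
  while (TRUE) {
    j <- i + step
    if (j < 1L || j > length(intens)) return(NA_real_)
    if (intens[j] < thr) {
      frac <- (intens[i] - thr) / (intens[i] - intens[j])
      return((abs(i - ipk) + frac) * spacing)
    }
    i <- j
  }
}

#' Beam-width metrics at a focal spot
#'
#' Locates the global intensity maximum of the field and measures, along each
#' principal grid axis through the peak, the width at which intensity
#' \eqn{|P|^2} falls `level_db` below the peak, with linear interpolation
#' between samples. The default -3 dB intensity level is the FWHM.
#'
#' @param field a `pressure_field`.
#' @param level_db level relative to peak intensity, dB (negative).
#' @return list with `peak` (x, y or z, value), `widths` (mm, named by axis;
#'   `NA` with `censored = TRUE` when the profile does not fall to the level
#'   within the grid, i.e. width >= extent), `level_db`.
#' @export
measure_beam_widths <- function(field, level_db = -3) {
  stopifnot(inherits(field, "pressure_field"), level_db < 0)
  I <- Mod(field$pressure)^2
  pk <- which(I == max(I), arr.ind = TRUE)[1, ]
  dm <- dim(I)
  if (pk[1] %in% c(1L, dm[1]) || pk[2] %in% c(1L, dm[2]))
    stop("focus outside grid: intensity peak lies on the grid border")
  thr <- max(I) * 10^(level_db / 10)
  sp <- field$grid$spacing
  prof1 <- I[, pk[2]]   # along axis 1 (x)
  prof2 <- I[pk[1], ]   # along axis 2 (y or z)
  w <- function(prof, ipk) {
    lo <- half_width_1d(prof, ipk, -1L, thr, sp)
    hi <- half_width_1d(prof, ipk, +1L, thr, sp)
    lo + hi
  }
  widths <- c(w(prof1, pk[1]), w(prof2, pk[2]))
  names(widths) <- if (field$grid$plane == "lateral") c("x", "y") else c("x", "z")
  peak_pos <- c(field$grid$axis1[pk[1]], field$grid$axis2[pk[2]])
  list(peak = list(axis1 = peak_pos[1], axis2 = peak_pos[2],
                   value = sqrt(max(I))),
       widths = widths,
       censored = is.na(widths),
       level_db = level_db)
}
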