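#' Ring-array design specification
#'
#' Parameters of the "racing ring" annular transducer: an annulus (outer
#' diameter `outer_diameter`, inner diameter `inner_diameter`) of small
#' elements lying on a spherical cap of radius `curvature_radius` that mimics
#' the corneal curvature, with a central hole that lets the beam bypass the
#' strongly absorbing crystalline lens. Defaults are the reference design:
#' OD 11 mm, ID 9 mm, 512 elements, 0.075 mm pitch (one wavelength at
#' 20 MHz in water), 12 mm curvature.
#'
#' Elements are modeled as point sources placed on a square lattice of
#' spacing `pitch` projected onto the cap; `element_size` enters only through
#' the per-element radiating area (amplitude proportional to area), so the
#' nominal 0.15 mm element on a 0.075 mm pitch is represented without
#' geometric overlap.
#'
#' @param outer_diameter,inner_diameter annulus diameters in mm.
#' @param curvature_radius radius of the spherical cap in mm; the cap apex is
#'   at the origin and the sphere center at `(0, 0, curvature_radius)`, so the
#'   beam propagates toward +z.
#' @param n_elements number of elements kept after sparsification.
#' @param pitch lattice spacing in mm.
#' @param element_size element side length in mm (area = `element_size^2`).
#' @param center_frequency design center frequency in MHz.
#' @param sparsify_seed RNG seed for the random sparse selection (recorded in
#'   the geometry for reproducibility).
#' @return An object of class `ring_array_spec`.
#' @seealso [build_ring_geometry()]
#' @export
ring_array_spec <- function(outer_diameter = 11, inner_diameter = 9,
                            curvature_radius = 12, n_elements = 512,
                            pitch = 0.075, element_size = 0.15,
                            center_frequency = 20, sparsify_seed = 0) {
  if (!(inner_diameter >= 0 && inner_diameter < outer_diameter))
    stop("require 0 <= inner_diameter < outer_diameter")
  if (outer_diameter > 2 * curvature_radius)
    stop("outer_diameter must not exceed 2 * curvature_radius")
  if (n_elements < 1) stop("n_elements must be >= 1")
  if (pitch <= 0) stop("pitch must be > 0")
  if (element_size <= 0) stop("element_size must be > 0")
  structure(list(outer_diameter = outer_diameter,
                 inner_diameter = inner_diameter,
                 curvature_radius = curvature_radius,
                 n_elements = as.integer(n_elements),
                 pitch = pitch,
                 element_size = element_size,
                 center_frequency = center_frequency,
                 sparsify_seed = as.integer(sparsify_seed)),
            class = "ring_array_spec")
}

#' @export
print.ring_array_spec <- function(x, ...) {
  cat(sprintf("<ring_array_spec> OD %g / ID %g mm, R_c %g mm, %d elements, pitch %g mm, f0 %g MHz, seed %d\n",
              x$outer_diameter, x$inner_diameter, x$curvature_radius,
              x$n_elements, x$pitch, x$center_frequency, x$sparsify_seed))
  invisible(x)
}

#' Candidate element lattice on the annular cap
#'
#' Enumerates all nodes of a square x-y lattice of spacing `pitch` (centered
#' on the axis) whose lateral radius lies within the annulus, then projects
#' each node onto the spherical cap via the sag
#' \eqn{z = R_c - \sqrt{R_c^2 - r^2}}. Ordering is deterministic: row-major
#' by y then x.
#'
#' @param spec a [ring_array_spec()].
#' @return numeric matrix with columns `x`, `y`, `z` (mm), one row per
#'   candidate node.
#' @export
build_candidate_grid <- function(spec) {
  stopifnot(inherits(spec, "ring_array_spec"))
  r_out <- spec$outer_diameter / 2
  r_in  <- spec$inner_diameter / 2
  kmax <- floor(r_out / spec$pitch)
  coords <- spec$pitch * seq.int(-kmax, kmax)
  g <- expand.grid(x = coords, y = coords, KEEP.OUT.ATTRS = FALSE)  # x fastest
  r <- sqrt(g$x^2 + g$y^2)
  keep <- r >= r_in & r <= r_out
  if (!any(keep))
    stop("empty geometry: annulus [", r_in, ", ", r_out,
         "] mm holds no lattice node at pitch ", spec$pitch, " mm")
  x <- g$x[keep]; y <- g$y[keep]; r <- r[keep]
  rc <- spec$curvature_radius
  z <- rc - sqrt(rc^2 - r^2)
  cbind(x = x, y = y, z = z)
}

#' Randomly sparsify a candidate set
#'
#' Draws a uniformly random subset of `n` candidates without replacement,
#' preserving the candidates' ordering. The same seed always yields the same
#' subset.
#'
#' @param candidates matrix of candidate positions (rows).
#' @param n number of rows to keep.
#' @param seed RNG seed.
#' @return matrix of the selected rows, original order preserved.
#' @export
sparsify <- function(candidates, n, seed = 0) {
  nc <- nrow(candidates)
  if (n > nc)
    stop("infeasible spec: requested ", n, " elements from only ",
         nc, " candidates")
  if (n == nc) return(candidates)
  idx <- with_seed(seed, sort(sample.int(nc, n)))
  candidates[idx, , drop = FALSE]
}

#' Build the ring-array element geometry
#'
#' Composes [build_candidate_grid()] and [sparsify()], then attaches inward
#' unit normals (pointing from each element toward the sphere center, i.e.
#' into the eye) and per-element radiating areas.
#'
#' @param spec a [ring_array_spec()].
#' @param area_mode `"element"` (default) assigns every element the nominal
#'   area `element_size^2`; `"lattice"` assigns the true spherical surface
#'   patch represented by each lattice node, `pitch^2 * R_c / sqrt(R_c^2 -
#'   r^2)`, which makes a dense (non-sparse) geometry tile the cap exactly —
#'   use this for quantitative comparisons against closed-form radiator
#'   solutions.
#' @return An object of class `ring_array_geometry` with fields `positions`
#'   (n x 3 matrix, mm), `normals` (n x 3), `areas` (mm^2), `spec`,
#'   `candidate_count` and `sparsity_fraction` (= n / candidate count).
#' @examples
#' geom <- build_ring_geometry(ring_array_spec(n_elements = 64))
#' geom
#' @export
build_ring_geometry <- function(spec, area_mode = c("element", "lattice")) {
  area_mode <- match.arg(area_mode)
  cand <- build_candidate_grid(spec)
  pos <- sparsify(cand, spec$n_elements, spec$sparsify_seed)
  rc <- spec$curvature_radius
  center <- c(0, 0, rc)
  d <- sweep(-pos, 2, -center)             # vectors element -> sphere center
  normals <- d / sqrt(rowSums(d^2))
  areas <- if (area_mode == "element") {
    rep(spec$element_size^2, nrow(pos))
  } else {
    r2 <- pos[, 1]^2 + pos[, 2]^2
    spec$pitch^2 * rc / sqrt(rc^2 - r2)
  }
  structure(list(positions = pos, normals = normals, areas = areas,
                 spec = spec, candidate_count = nrow(cand),
                 sparsity_fraction = nrow(pos) / nrow(cand)),
            class = "ring_array_geometry")
}

#' Assemble a geometry from explicit positions
#'
#' Low-level constructor used for custom layouts (dense caps, flattened
#' test geometries). Positions are taken as given; normals default to unit
#' vectors toward `(0, 0, curvature)` when a curvature is supplied, else +z.
#'
#' @param positions n x 3 matrix (mm).
#' @param areas per-element areas (mm^2), recycled.
#' @param normals optional n x 3 matrix of unit normals.
#' @param curvature optional sphere radius used to derive normals.
#' @param spec optional [ring_array_spec()] carried along for provenance.
#' @export
array_geometry <- function(positions, areas, normals = NULL,
                           curvature = NULL, spec = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  n <- nrow(positions)
  areas <- rep_len(areas, n)
  if (is.null(normals)) {
    if (!is.null(curvature)) {
      d <- sweep(-positions, 2, -c(0, 0, curvature))
      normals <- d / sqrt(rowSums(d^2))
    } else {
      normals <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
    }
  }
  structure(list(positions = positions, normals = as.matrix(normals),
                 areas = areas, spec = spec,
                 candidate_count = n, sparsity_fraction = 1),
            class = "ring_array_geometry")
}

#' @export
print.ring_array_geometry <- function(x, ...) {
  r <- sqrt(x$positions[, 1]^2 + x$positions[, 2]^2)
  cat(sprintf("<ring_array_geometry> %d elements (of %d candidates, keep fraction %.3f)\n",
              nrow(x$positions), x$candidate_count, x$sparsity_fraction))
  cat(sprintf("  lateral radius %.3f .. %.3f mm, z sag %.4f .. %.4f mm, total area %.3f mm^2\n",
              min(r), max(r), min(x$positions[, 3]), max(x$positions[, 3]),
              sum(x$areas)))
  invisible(x)
}

#' Export / import geometry as CSV
#'
#' Columns: `element_id, x_mm, y_mm, z_mm, nx, ny, nz, area_mm2`.
#'
#' @param geometry a `ring_array_geometry`.
#' @param path file path.
#' @export
write_geometry_csv <- function(geometry, path) {
  df <- data.frame(element_id = seq_len(nrow(geometry$positions)),
                   x_mm = geometry$positions[, 1],
                   y_mm = geometry$positions[, 2],
                   z_mm = geometry$positions[, 3],
                   nx = geometry$normals[, 1],
                   ny = geometry$normals[, 2],
                   nz = geometry$normals[, 3],
                   area_mm2 = geometry$areas)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm", "nx", "ny", "nz", "area_mm2")
  if (!all(need %in% names(df)))
    stop("geometry CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  array_geometry(positions = as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
                 areas = df$area_mm2,
                 normals = as.matrix(df[, c("nx", "ny", "nz")]))
}
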