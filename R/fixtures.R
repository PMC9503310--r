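#' Recipe for a programmatically generated target pattern
#'
#' All test and demonstration images are generated in code from a recipe, so
#' every fixture is reproducible from `(recipe, seed)` alone.
#'
#' @param kind `"letters"`, `"points"`, `"disks"` or `"checkerboard"`.
#' @param size_px image side in pixels (square, >= 16).
#' @param pixel_pitch pixel size in mm.
#' @param text letters kind: string rendered with the built-in 5x7 font.
#' @param points points kind: n x 2 matrix of (x, y) positions in mm
#'   relative to the plane center (default: one centered point).
#' @param centers,radii disks kind: disk centers (n x 2, mm) and radii (mm).
#' @param n_blocks checkerboard kind: blocks per side.
#' @param fill_fraction letters kind: fraction of the image the text block
#'   may occupy (sets the integer glyph scale).
#' @param seed recorded for provenance.
#' @return An object of class `pattern_recipe`.
#' @export
pattern_recipe <- function(kind = c("letters", "points", "disks", "checkerboard"),
                           size_px = 256, pixel_pitch = 0.035, text = "USC",
                           points = NULL, centers = NULL, radii = NULL,
                           n_blocks = 8, fill_fraction = 0.8, seed = 0) {
  kind <- match.arg(kind)
  if (size_px < 16) stop("size_px must be >= 16")
  structure(list(kind = kind, size_px = as.integer(size_px),
                 pixel_pitch = pixel_pitch, text = text, points = points,
                 centers = centers, radii = radii, n_blocks = n_blocks,
                 fill_fraction = fill_fraction, seed = as.integer(seed)),
            class = "pattern_recipe")
}

# Integer glyph scale for a text of `nch` glyphs on an n-pixel square image:
# glyph cells are 5 wide + 1 spacing column, 7 tall.
letter_scale <- function(n, nch, fill_fraction) {
  cells_w <- 6L * nch - 1L
  max(1L, min(floor(fill_fraction * n / cells_w),
              floor(fill_fraction * n / 7)))
}

#' Render a target pattern from a recipe
#'
#' Deterministic rasterization: letters use the built-in 5x7 stroke font at
#' an integer scale (every font cell becomes an s x s pixel block), points
#' set single pixels, disks fill circles, checkerboards alternate blocks.
#' The image matrix is indexed `[x, y]` with x to the right and y up,
#' matching the lateral field-grid convention.
#'
#' @param recipe a [pattern_recipe()].
#' @param depth target plane depth (mm) for the resulting pattern.
#' @return a [target_pattern()].
#' @examples
#' usc <- render_pattern(pattern_recipe("letters", text = "USC"))
#' usc
#' @export
render_pattern <- function(recipe, depth = 7) {
  stopifnot(inherits(recipe, "pattern_recipe"))
  n <- recipe$size_px
  img <- matrix(0, n, n)
  ax <- pixel_axis(n, recipe$pixel_pitch)
  if (recipe$kind == "letters") {
    chars <- strsplit(recipe$text, "")[[1]]
    bad <- setdiff(unique(chars), names(.font5x7))
    if (length(bad))
      stop("unsupported glyphs: ", paste(sprintf("'%s'", bad), collapse = ", "))
    s <- letter_scale(n, length(chars), recipe$fill_fraction)
    w <- (6L * length(chars) - 1L) * s
    h <- 7L * s
    x0 <- floor((n - w) / 2)
    y0 <- floor((n - h) / 2)
    for (ci in seq_along(chars)) {
      g <- font_glyph(chars[ci])
      for (r in 1:7) for (cc in 1:5) if (g[r, cc] == 1L) {
        xs <- x0 + ((ci - 1L) * 6L + (cc - 1L)) * s + seq_len(s)
        ys <- y0 + (7L - r) * s + seq_len(s)   # font row 1 is the top
        img[xs, ys] <- 1
      }
    }
  } else if (recipe$kind == "points") {
    pts <- recipe$points
    if (is.null(pts)) pts <- matrix(c(0, 0), ncol = 2)
    pts <- matrix(as.numeric(pts), ncol = 2)
    for (i in seq_len(nrow(pts))) {
      ix <- which.min(abs(ax - pts[i, 1]))
      iy <- which.min(abs(ax - pts[i, 2]))
      img[ix, iy] <- 1
    }
  } else if (recipe$kind == "disks") {
    centers <- recipe$centers
    if (is.null(centers)) centers <- matrix(c(0, 0), ncol = 2)
    centers <- matrix(as.numeric(centers), ncol = 2)
    radii <- rep_len(if (is.null(recipe$radii)) 0.2 else recipe$radii,
                     nrow(centers))
    for (i in seq_len(nrow(centers))) {
      d2 <- outer((ax - centers[i, 1])^2, (ax - centers[i, 2])^2, "+")
      img[d2 <= radii[i]^2] <- 1
    }
  } else {                                      # checkerboard
    b <- ceiling(n / recipe$n_blocks)
    bi <- (seq_len(n) - 1L) %/% b
    img <- outer(bi, bi, function(i, j) as.numeric((i + j) %% 2 == 0))
  }
  if (all(img == 0)) stop("rendered pattern is empty")
  target_pattern(img, pixel_pitch = recipe$pixel_pitch, depth = depth)
}

#' Canonical control-point suites
#'
#' Reference focus sets at a given stimulation depth: a single on-axis
#' focus, a lateral pair at +/- `pair_offset` mm, and a 3 x 3 grid spanning
#' `grid_span` mm — all on the plane z = depth.
#'
#' @param depth stimulation depth in mm.
#' @param pair_offset lateral half-separation of the two-focus suite, mm.
#' @param grid_span side of the 3 x 3 grid, mm.
#' @return named list of [focus_set()] objects: `single`, `pair`, `grid3x3`.
#' @export
reference_focus_sets <- function(depth = 7, pair_offset = 0.3, grid_span = 1) {
  stopifnot(depth > 0)
  g <- seq(-grid_span / 2, grid_span / 2, length.out = 3)
  grid9 <- as.matrix(expand.grid(x = g, y = g, KEEP.OUT.ATTRS = FALSE))
  list(single = focus_set(c(0, 0, depth)),
       pair = focus_set(rbind(c(-pair_offset, 0, depth),
                              c(pair_offset, 0, depth))),
       grid3x3 = focus_set(cbind(grid9, z = depth)))
}
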