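#' Write / read plain-text PGM (P2) grayscale images
#'
#' Values are linearly mapped from `range` to 0..`maxval`. The plain (ASCII)
#' variant is used throughout so every artifact stays text.
#'
#' @param img numeric matrix, `[x, y]` indexing with y up; written top row
#'   first as PGM requires.
#' @param path file path.
#' @param maxval PGM maximum gray value.
#' @param range values mapped to 0 and `maxval` (default the image range).
#' @export
write_pgm <- function(img, path, maxval = 255, range = NULL) {
  img <- as.matrix(img)
  if (is.null(range)) range <- c(min(img), max(img))
  span <- if (diff(range) == 0) 1 else diff(range)
  q <- round((pmin(pmax(img, range[1]), range[2]) - range[1]) / span * maxval)
  rows <- t(q)[seq(ncol(q), 1), , drop = FALSE]     # y up -> top row first
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(img), ncol(img)), as.character(maxval)), con)
  utils::write.table(rows, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pgm
#' @return `read_pgm()`: numeric matrix in `[x, y]` (y up) order, scaled to
#'   [0, 1].
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt[-1], collapse = "\n"), quiet = TRUE)
  if (txt[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- tok[1]; h <- tok[2]; maxval <- tok[3]
  px <- matrix(tok[-(1:3)], nrow = h, ncol = w, byrow = TRUE) / maxval
  t(px)[, seq(h, 1), drop = FALSE]
}

#' Read a grayscale target image
#'
#' PGM is read natively; PNG requires the `png` package (color images are
#' averaged to gray).
#'
#' @param path image path (.pgm or .png).
#' @inheritParams target_pattern
#' @return a [target_pattern()].
#' @export
read_target_image <- function(path, pixel_pitch = 0.035, depth = 7) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "pgm") {
    read_pgm(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    t(a)[, seq(nrow(a), 1), drop = FALSE]
  } else stop("unsupported image format: .", ext)
  target_pattern(img, pixel_pitch = pixel_pitch, depth = depth)
}

#' Export a pressure field as flattened CSV
#'
#' Columns: `x_mm, y_mm, z_mm, re, im`.
#'
#' @param field a `pressure_field`.
#' @param path file path.
#' @export
write_field_csv <- function(field, path) {
  pts <- grid_points(field$grid)
  P <- as.vector(field$pressure)
  utils::write.csv(data.frame(x_mm = pts[, 1], y_mm = pts[, 2],
                              z_mm = pts[, 3], re = Re(P), im = Im(P)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a normalized magnitude map as PGM
#'
#' Writes `20 log10(|P|/max)` clipped at `floor_db`, mapped to 0..255
#' (0 dB = white).
#'
#' @param field a `pressure_field`.
#' @param path file path.
#' @param floor_db dynamic-range floor.
#' @export
write_field_pgm <- function(field, path, floor_db = -40) {
  write_pgm(magnitude_db(field, floor_db), path, range = c(floor_db, 0))
}

#' Export a hologram
#'
#' The phase is written both as an exact CSV matrix (radians) and as a PGM
#' with (-pi, pi] mapped to 0..255.
#'
#' @param hologram a `hologram`.
#' @param path_csv,path_pgm output paths (either may be `NULL` to skip).
#' @export
write_hologram <- function(hologram, path_csv = NULL, path_pgm = NULL) {
  if (!is.null(path_csv))
    utils::write.table(hologram$phase, path_csv, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(path_pgm))
    write_pgm(hologram$phase, path_pgm, range = c(-pi, pi))
  invisible(hologram)
}
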