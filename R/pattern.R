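#' Binary tilt-state patterns
#'
#' A tilt pattern assigns each micromirror one of the two steady tilt
#' states. The encoding is a package convention: value 1 maps to +tilt
#' (gamma+), value 0 to -tilt (gamma-).
#'
#' @param states Integer/logical matrix of dimension nx x ny with values
#'   in {0, 1}; `states[mx + 1, my + 1]` is the state of mirror (mx, my).
#' @return An object of class `tilt_pattern` (a 0/1 integer matrix).
#' @seealso [make_pattern()] for the built-in generators.
#' @export
tilt_pattern <- function(states) {
  states <- as.matrix(states)
  mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L))) stop("tilt states must be 0 or 1")
  structure(states, class = c("tilt_pattern", "matrix"))
}

#' @export
print.tilt_pattern <- function(x, ...) {
  cat(sprintf("tilt pattern: %d x %d mirrors, %d in gamma+ state\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# per-mirror tilt angles in degrees for a pattern on a geometry
pattern_gamma <- function(pattern, geom) {
  ifelse(unclass(pattern) == 1L, geom$tilt_deg, -geom$tilt_deg)
}

check_pattern <- function(pattern, geom) {
  if (nrow(pattern) != geom$nx || ncol(pattern) != geom$ny)
    stop(sprintf("pattern is %d x %d but geometry has %d x %d mirrors",
                 nrow(pattern), ncol(pattern), geom$nx, geom$ny))
  invisible(pattern)
}

#' Generate a tilt pattern
#'
#' Built-in pattern motifs for driving the diffraction simulations.
#' "Rows" index the y direction (my), so `h_lines` produces stripes that
#' run horizontally across the device. Periodic kinds require
#' `period >= 2` mirrors. `from_image` thresholds a grayscale raster at
#' 50% of its maximum.
#'
#' @param geom A [dmd_geometry()]; sets the pattern dimensions.
#' @param kind One of `"all_minus"`, `"all_plus"`, `"h_lines"`,
#'   `"v_lines"`, `"diagonal_lines"`, `"checkerboard"`,
#'   `"concentric_circles"`, `"from_image"`.
#' @param period Stripe/tile period in mirrors (periodic kinds).
#' @param duty Duty cycle in (0, 1): fraction of each period set to the
#'   gamma+ state (line kinds only).
#' @param image Numeric matrix (grayscale raster, nx x ny) for
#'   `"from_image"`.
#' @return A [tilt_pattern()].
#' @examples
#' geom <- dmd_geometry(nx = 8, ny = 8)
#' make_pattern(geom, "h_lines", period = 4, duty = 0.5)
#' @export
make_pattern <- function(geom,
                         kind = c("all_minus", "all_plus", "h_lines",
                                  "v_lines", "diagonal_lines",
                                  "checkerboard", "concentric_circles",
                                  "from_image"),
                         period = 4, duty = 0.5, image = NULL) {
  kind <- match.arg(kind)
  nx <- geom$nx; ny <- geom$ny
  periodic <- kind %in% c("h_lines", "v_lines", "diagonal_lines",
                          "checkerboard", "concentric_circles")
  if (periodic && period < 2) stop("period must be >= 2 mirrors")
  mxg <- matrix(0:(nx - 1L), nx, ny)            # mx varies along rows
  myg <- matrix(0:(ny - 1L), nx, ny, byrow = TRUE)
  states <- switch(kind,
    all_minus = matrix(0L, nx, ny),
    all_plus = matrix(1L, nx, ny),
    h_lines = (myg %% period) < duty * period,
    v_lines = (mxg %% period) < duty * period,
    diagonal_lines = ((mxg + myg) %% period) < duty * period,
    checkerboard = ((mxg %/% period) + (myg %/% period)) %% 2 == 0,
    concentric_circles = {
      r <- sqrt((mxg - (nx - 1) / 2)^2 + (myg - (ny - 1) / 2)^2)
      (floor(r / period) %% 2) == 0
    },
    from_image = {
      if (is.null(image)) stop("kind = 'from_image' requires an image matrix")
      image <- as.matrix(image)
      if (nrow(image) != nx || ncol(image) != ny)
        stop("image dimensions must match the geometry")
      if (!all(is.finite(image))) stop("image contains non-finite values")
      if (max(image) == min(image))
        stop("image is constant and cannot be thresholded to a binary pattern")
      image >= 0.5 * max(image)
    })
  tilt_pattern(states + 0L)
}

#' Read a tilt pattern from a file
#'
#' Accepts an ASCII grid of 0/1 characters (one row of the device per
#' line, whitespace optional), an ASCII PGM (`P2`) raster, or a grayscale
#' PNG. Rasters are thresholded at 50% of their maximum. File rows are
#' taken as y (my) running top to bottom, so the first text row is
#' my = ny - 1 (image convention); columns map to mx.
#'
#' @param path Path to the pattern file.
#' @param geom Optional [dmd_geometry()] to validate dimensions against.
#' @return A [tilt_pattern()].
#' @export
read_pattern <- function(path, geom = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    r <- png::readPNG(path)
    if (length(dim(r)) == 3L) r <- r[, , 1]
    r
  } else if (ext %in% c("pgm", "pnm")) {
    read_pgm(path)
  } else {
    read_ascii_grid(path)
  }
  # img rows = file rows = top-down y; convert to states[mx, my] with my up
  states <- t(img[rev(seq_len(nrow(img))), , drop = FALSE])
  if (max(states) == min(states) && !all(states %in% c(0, 1)))
    stop("pattern raster is constant and cannot be thresholded")
  if (!all(states %in% c(0, 1)))
    states <- states >= 0.5 * max(states)
  pat <- tilt_pattern(states + 0L)
  if (!is.null(geom)) check_pattern(pat, geom)
  pat
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    ch <- strsplit(gsub("[[:space:]]", "", l), "")[[1]]
    if (!all(ch %in% c("0", "1"))) stop("ASCII pattern must contain only 0/1")
    as.integer(ch)
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ASCII pattern rows have unequal lengths")
  do.call(rbind, rows)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only ASCII (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a tilt pattern as an ASCII 0/1 grid
#'
#' @param pattern A [tilt_pattern()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pattern <- function(pattern, path) {
  states <- unclass(pattern)
  lines <- apply(t(states)[rev(seq_len(ncol(states))), , drop = FALSE], 1,
                 paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}
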