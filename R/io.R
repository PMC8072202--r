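#' Write an angular map to disk
#'
#' Writers for intensity/displacement maps. `tiff32` stores the values at
#' 32-bit sample depth (min-max normalised; the affine scale needed to
#' recover physical values is stored in a JSON sidecar `<path>.json`
#' together with the axis metadata, making the round trip lossless well
#' below float32 precision). `csv` writes a header row of theta-axis
#' values and a leading phi column, fully self-describing. `png_log` is a
#' display-only 8-bit preview on a logarithmic scale and is never meant
#' to be read back quantitatively.
#'
#' @param map A [field_map()] (complex maps are written as intensity) or
#'   a plain numeric matrix.
#' @param path Output file path.
#' @param format `"tiff32"`, `"csv"` or `"png_log"`.
#' @param axes Optional list with `phi_deg`, `theta_deg` axis vectors
#'   (taken from the map when it is a [field_map()]).
#' @param meta Optional named list merged into the sidecar metadata.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, format = c("tiff32", "csv", "png_log"),
                      axes = NULL, meta = list()) {
  format <- match.arg(format)
  if (inherits(map, "field_map")) {
    axes <- map$grid
    meta <- utils::modifyList(
      list(wavelength_um = map$wavelength_um), c(map$meta, meta))
    z <- intensity(map)
  } else {
    z <- as.matrix(map)
  }
  if (!all(is.finite(z))) stop("map contains non-finite values")
  side <- list(format = format,
               dim = dim(z),
               phi_deg = axes$phi_deg, theta_deg = axes$theta_deg,
               angle_unit = "degree")
  side <- utils::modifyList(side, meta)
  switch(format,
    tiff32 = {
      lo <- min(z); hi <- max(z)
      zn <- if (hi > lo) (z - lo) / (hi - lo) else z * 0
      # rows of the TIFF are the theta axis top-down; store transposed
      tiff::writeTIFF(t(zn)[rev(seq_len(ncol(z))), , drop = FALSE], path,
                      bits.per.sample = 32L, compression = "none")
      side$scale <- list(min = lo, max = hi)
      jsonlite::write_json(side, paste0(path, ".json"),
                           auto_unbox = TRUE, digits = NA)
    },
    csv = {
      tab <- cbind(phi_deg = axes$phi_deg, z)
      colnames(tab) <- c("phi_deg", as.character(axes$theta_deg))
      utils::write.csv(tab, path, row.names = FALSE)
      jsonlite::write_json(side, paste0(path, ".json"),
                           auto_unbox = TRUE, digits = NA)
    },
    png_log = {
      zl <- log10(z - min(z) + 1e-12 * max(abs(z) + 1))
      rng <- range(zl)
      zn <- if (diff(rng) > 0) (zl - rng[1]) / diff(rng) else zl * 0
      png::writePNG(t(zn)[rev(seq_len(ncol(z))), , drop = FALSE], path)
    })
  invisible(path)
}

#' Read back a map written by [write_map()]
#'
#' Supports the `tiff32` and `csv` formats (the PNG preview is not
#' quantitative). Returns the values with axis metadata from the sidecar
#' or CSV header.
#'
#' @param path File path.
#' @return List with `values` (matrix, rows phi, columns theta),
#'   `phi_deg`, `theta_deg`, `meta`.
#' @export
read_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    img <- tiff::readTIFF(path)
    z <- t(img[rev(seq_len(nrow(img))), , drop = FALSE])
    sc <- side$scale
    values <- z * (sc$max - sc$min) + sc$min
    list(values = values, phi_deg = side$phi_deg, theta_deg = side$theta_deg,
         meta = side)
  } else if (ext == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE)
    meta_path <- paste0(path, ".json")
    meta <- if (file.exists(meta_path))
      jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
    list(values = as.matrix(tab[, -1, drop = FALSE]),
         phi_deg = tab[[1]],
         theta_deg = as.numeric(colnames(tab)[-1]),
         meta = meta)
  } else {
    stop("unsupported map format: ", ext)
  }
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised keys (all optional, defaults in parentheses): geometry
#' `pitch_um` (7.56), `mirror_um` (= pitch), `tilt_deg` (12), `nx`, `ny`
#' (50); illumination `wavelength_nm` (532), `phi_a_deg`, `theta_a_deg`
#' (-21, 21), `waist_um`, `centre_x_um`, `centre_y_um`; output
#' `phi_b_deg`, `theta_b_deg` (ranges, c(-15, 15)), `step_deg` (0.1);
#' `approach` ("grating"), `rays` (100000), `seed` (1).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config` with all defaults filled
#'   in.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  build_run_config(raw)
}

build_run_config <- function(raw = list()) {
  cfg <- utils::modifyList(list(
    pitch_um = 7.56, mirror_um = NULL, tilt_deg = 12, nx = 50L, ny = 50L,
    wavelength_nm = 532, phi_a_deg = -21, theta_a_deg = 21,
    waist_um = NULL, centre_x_um = NULL, centre_y_um = NULL,
    phi_b_deg = c(-15, 15), theta_b_deg = c(-15, 15), step_deg = 0.1,
    approach = "grating", rays = 100000L, seed = 1L
  ), raw[!vapply(raw, is.null, logical(1))])
  if (is.null(cfg$mirror_um)) cfg$mirror_um <- cfg$pitch_um
  if (!cfg$approach %in% c("raytrace", "analytic", "grating", "blaze"))
    stop("approach must be one of raytrace, analytic, grating, blaze")
  if (cfg$step_deg <= 0) stop("step_deg must be > 0")
  if (diff(range(cfg$phi_b_deg)) == 0 || diff(range(cfg$theta_b_deg)) == 0)
    stop("output angle ranges must be non-degenerate")
  class(cfg) <- "run_config"
  cfg
}

run_config_geometry <- function(cfg) {
  dmd_geometry(cfg$pitch_um, cfg$mirror_um, cfg$tilt_deg, cfg$nx, cfg$ny)
}
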