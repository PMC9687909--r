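#' Imaging configuration
#'
#' Parameters of the parallel-ray projection model.  Light travels along
#' `z`; each ray is attenuated by the Beer-Lambert law with attenuation
#' coefficient linear in dye concentration, `mu = mu_ref * phi`.  The exit
#' intensity is mapped linearly to 8-bit gray levels with `I0 -> 255`.
#'
#' The default `mu_ref` is calibrated so that a full-concentration dye
#' column of radius 2 mm (path length 4 mm through its core) projects to
#' gray level ~40, comfortably below the gray <= 80 dye-dominance mask:
#' `exp(-mu_ref * 0.004) * 255 ~= 40`.
#'
#' @param width,height Image size in pixels (default 161 x 306).
#' @param I0 Initial intensity before entering the medium (arbitrary
#'   units; maps to gray 255).
#' @param mu_ref Attenuation coefficient at phi = 1, 1/m.
#' @param noise_sd Additive Gaussian gray-level noise (default 0, i.e.
#'   noiseless projection).
#' @param noise_seed Seed for the optional noise.
#' @return Object of class `imaging_config`.
#' @export
imaging_config <- function(width = 161, height = 306, I0 = 1,
                           mu_ref = -log(40 / 255) / 0.004,
                           noise_sd = 0, noise_seed = 1L) {
  if (I0 <= 0) stop("I0 must be > 0", call. = FALSE)
  if (mu_ref < 0) stop("mu_ref must be >= 0", call. = FALSE)
  if (width < 2 || height < 2) stop("image dimensions must be >= 2", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 I0 = I0, mu_ref = mu_ref, noise_sd = noise_sd,
                 noise_seed = as.integer(noise_seed)),
            class = "imaging_config")
}

#' Attenuate a single ray through a column of dye
#'
#' Discretized Beer-Lambert attenuation: the exit intensity of each path
#' element is the entry intensity of the next, so the ray exits with
#' `I0 * prod(exp(-mu_ref * phi_j * dz))`.
#'
#' @param concentrations Dye concentrations along the ray (all >= 0).
#' @param dz Path-element thickness, m.
#' @param I0 Entry intensity.
#' @param mu_ref Attenuation coefficient at phi = 1, 1/m.
#' @return Exit intensity (0 < I <= I0).
#' @export
attenuate_ray <- function(concentrations, dz, I0, mu_ref) {
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (dz <= 0) stop("dz must be > 0", call. = FALSE)
  I0 * exp(-mu_ref * dz * sum(concentrations))
}

#' Pixel-to-physical mapping for a projection image
#'
#' Pixel columns span the duct width (`x` in [-side/2, side/2]), pixel
#' rows span the duct length (`y` in [0, length]), row 1 at the inlet end.
#' Coordinates refer to pixel centres.
#'
#' @param geometry A [duct_geometry()].
#' @param config An [imaging_config()].
#' @return List with `x`, `y` pixel-centre coordinates (m) and pitches
#'   `pitch_x`, `pitch_y` (m/pixel).
#' @export
image_mapping <- function(geometry, config) {
  px <- geometry$side_length / config$width
  py <- geometry$duct_length / config$height
  list(x = seq(-geometry$side_length / 2 + px / 2,
               geometry$side_length / 2 - px / 2, length.out = config$width),
       y = seq(py / 2, geometry$duct_length - py / 2,
               length.out = config$height),
       pitch_x = px, pitch_y = py)
}

# bilinear interpolation of matrix f given axis coordinate vectors,
# evaluated on the tensor grid (xi x yi); clamps outside the hull
.interp2 <- function(xg, yg, f, xi, yi) {
  ix <- findInterval(xi, xg, all.inside = TRUE)
  iy <- findInterval(yi, yg, all.inside = TRUE)
  fx <- (xi - xg[ix]) / (xg[ix + 1] - xg[ix])
  fy <- (yi - yg[iy]) / (yg[iy + 1] - yg[iy])
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  FX <- matrix(fx, length(xi), length(yi))
  FY <- matrix(fy, length(xi), length(yi), byrow = TRUE)
  i0 <- matrix(ix, length(xi), length(yi))
  j0 <- matrix(iy, length(xi), length(yi), byrow = TRUE)
  idx <- function(i, j) i + (j - 1) * nrow(f)
  (1 - FX) * (1 - FY) * f[idx(i0, j0)] +
    FX * (1 - FY) * f[idx(i0 + 1, j0)] +
    (1 - FX) * FY * f[idx(i0, j0 + 1)] +
    FX * FY * f[idx(i0 + 1, j0 + 1)]
}

#' Render a projection image from a concentration volume
#'
#' Integrates attenuation along `z` for every (x, y) column (parallel
#' rays), resamples the optical-depth field onto the pixel grid
#' bilinearly, applies optional Gaussian gray-level noise, and quantizes
#' to 8-bit gray with rounding half-up and clamping.  Quarter-domain
#' volumes are mirrored to the full domain first.
#'
#' @param volume A `concentration_volume`.
#' @param geometry A [duct_geometry()].
#' @param config An [imaging_config()].
#' @return Object of class `projective_image`: integer matrix `gray`
#'   (width x height, values 0-255), `timestamp`, and the physical
#'   `mapping`.
#' @export
render_projection <- function(volume, geometry, config) {
  volume <- mirror_quarter(volume)
  hz <- volume$z[2] - volume$z[1]
  tau <- apply(volume$phi, c(1, 2), sum) * config$mu_ref * hz
  map <- image_mapping(geometry, config)
  tau_px <- .interp2(volume$x, volume$y, tau, map$x, map$y)
  intensity <- 255 * exp(-tau_px)
  if (config$noise_sd > 0) {
    rng <- .seeded_rng(config$noise_seed + round(volume$timestamp * 1e4))
    intensity <- intensity + rng$rnorm(length(intensity)) * config$noise_sd
  }
  gray <- matrix(as.integer(pmin(pmax(floor(intensity + 0.5), 0), 255)),
                 nrow = config$width)
  structure(list(gray = gray, timestamp = volume$timestamp, mapping = map,
                 geometry = geometry, config = config),
            class = "projective_image")
}

# local RNG stream that does not disturb the global .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    s
  })
  env$rnorm <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  }
  env
}

#' Write a projection image as 8-bit grayscale PNG with a JSON sidecar
#'
#' @param image A `projective_image`.
#' @param path Output PNG path; the sidecar is written to `<path>.json`.
#' @param meta Extra metadata recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_projection <- function(image, path, meta = list()) {
  # PNG row-major: rows are image rows (y), columns are x
  arr <- t(image$gray) / 255
  png::writePNG(arr, target = path)
  sidecar <- c(list(timestamp = image$timestamp,
                    pitch_x = image$mapping$pitch_x,
                    pitch_y = image$mapping$pitch_y,
                    width = ncol(arr), height = nrow(arr)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a projection image written by [write_projection()]
#'
#' Accepts PNG (and TIFF when the `tiff` package is available).
#'
#' @param path PNG/TIFF path with an accompanying `<path>.json` sidecar.
#' @param geometry A [duct_geometry()] used to reconstruct the mapping.
#' @return A `projective_image`.
#' @export
read_projection <- function(path, geometry = duct_geometry()) {
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  gray <- t(matrix(as.integer(floor(arr * 255 + 0.5)), nrow = nrow(arr)))
  sc_path <- paste0(path, ".json")
  ts <- 0
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path)
    ts <- as.numeric(sc$timestamp)
  }
  cfg <- imaging_config(width = nrow(gray), height = ncol(gray))
  structure(list(gray = gray, timestamp = ts,
                 mapping = image_mapping(geometry, cfg),
                 geometry = geometry, config = cfg),
            class = "projective_image")
}
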