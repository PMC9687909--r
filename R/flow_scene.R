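#' Duct geometry
#'
#' Describes the square-section duct in which dye perfusion is simulated.
#' Axis convention: `x` lateral, `y` streamwise (flow direction), `z` along
#' the light/projection direction.  The cross-section is square (`x` and `z`
#' extents equal).
#'
#' @param side_length Side of the square cross-section in metres
#'   (default 0.0254 m, i.e. 1 inch).
#' @param duct_length Streamwise length in metres (default 0.0254 m).
#' @return An object of class `duct_geometry`.
#' @export
duct_geometry <- function(side_length = 0.0254, duct_length = 0.0254) {
  if (!is.numeric(side_length) || side_length <= 0 ||
      !is.numeric(duct_length) || duct_length <= 0) {
    stop("invalid geometry: side_length and duct_length must be positive",
         call. = FALSE)
  }
  structure(list(side_length = side_length, duct_length = duct_length),
            class = "duct_geometry")
}

#' Scene configuration
#'
#' Physical and numerical parameters of the dye-perfusion scene.  Density,
#' viscosity and gravity are recorded as metadata of the flow regime; the
#' velocity field itself is the analytic fully developed laminar duct
#' profile, so they do not enter the computation.
#'
#' @param geometry A [duct_geometry()].
#' @param bulk_velocity Cross-section mean streamwise velocity in m/s.
#' @param diffusivity Dye diffusivity D in m^2/s (default 1e-9, a typical
#'   value for dye in water).
#' @param nx,ny,nz Grid resolution (full domain; `x`, `y`, `z`).
#' @param dt_sim Simulation time step in seconds.
#' @param quarter Use quarter-domain symmetry (simulate x >= 0, z >= 0 and
#'   mirror when projecting).
#' @param rho,mu,gravity Fluid density (kg/m^3), viscosity (Pa s) and
#'   gravity (m/s^2); metadata only.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(geometry = duct_geometry(),
                         bulk_velocity = 0.005,
                         diffusivity = 1e-9,
                         nx = 64, ny = 128, nz = 64,
                         dt_sim = 0.02,
                         quarter = TRUE,
                         rho = 998, mu = 1e-3, gravity = 9.81) {
  stopifnot(inherits(geometry, "duct_geometry"))
  if (diffusivity < 0) stop("diffusivity must be >= 0", call. = FALSE)
  if (nx < 2 || ny < 2 || nz < 2) stop("grid resolutions must be >= 2", call. = FALSE)
  if (dt_sim <= 0) stop("dt_sim must be > 0", call. = FALSE)
  if (bulk_velocity <= 0) stop("bulk_velocity must be > 0", call. = FALSE)
  structure(list(geometry = geometry, bulk_velocity = bulk_velocity,
                 diffusivity = diffusivity, nx = as.integer(nx),
                 ny = as.integer(ny), nz = as.integer(nz),
                 dt_sim = dt_sim, quarter = isTRUE(quarter),
                 rho = rho, mu = mu, gravity = gravity),
            class = "scene_config")
}

# Analytic cross-section mean of the unscaled series profile (unit pressure
# scaling); used to normalise the profile to a prescribed bulk velocity.
.duct_series_mean <- function(n_terms) {
  n <- seq(1, by = 2, length.out = n_terms)
  sum((1 / n^3) * (2 / (n * pi)) * (1 - (2 / (n * pi)) * tanh(n * pi / 2)))
}

.duct_series_eval <- function(xs, zs, side, n_terms) {
  # xs, zs in metres, centred on the duct axis; returns unscaled v(x, z)
  n <- seq(1, by = 2, length.out = n_terms)
  v <- matrix(0, nrow = length(xs), ncol = length(zs))
  for (k in seq_along(n)) {
    nk <- n[k]
    sgn <- (-1)^((nk - 1) / 2)
    cx <- cos(nk * pi * xs / side)
    cz <- 1 - cosh(nk * pi * zs / side) / cosh(nk * pi / 2)
    v <- v + (sgn / nk^3) * outer(cx, cz)
  }
  v
}

#' Fully developed laminar velocity profile in a rectangular duct
#'
#' Evaluates the classical Fourier-series solution of pressure-driven
#' laminar flow in a square duct on a cross-section grid, scaled so that the
#' analytic cross-section mean equals `bulk_velocity`.  The lateral
#' components `u` and `w` are identically zero and the no-slip condition
#' holds on all four walls.
#'
#' @param geometry A [duct_geometry()].
#' @param bulk_velocity Cross-section mean streamwise velocity, m/s.
#' @param nx,nz Number of grid points across the section (cell centres).
#' @param n_terms Series truncation (odd harmonics); 50 is fully converged
#'   at double precision for grid sizes used here.
#' @param quarter If `TRUE`, return the quarter section x >= 0, z >= 0 with
#'   `nx`, `nz` interpreted as quarter-domain sizes.
#' @return An object of class `flow_field` with elements `v` (nx x nz
#'   matrix, m/s), `x`, `z` (cell-centre coordinates, m), and the geometry.
#' @export
duct_velocity_profile <- function(geometry, bulk_velocity, nx = 64, nz = 64,
                                  n_terms = 50, quarter = FALSE) {
  stopifnot(inherits(geometry, "duct_geometry"))
  if (n_terms < 1) stop("n_terms must be >= 1", call. = FALSE)
  if (bulk_velocity <= 0) stop("bulk_velocity must be > 0", call. = FALSE)
  side <- geometry$side_length
  if (quarter) {
    hx <- (side / 2) / nx
    xs <- seq(hx / 2, side / 2 - hx / 2, length.out = nx)
    zs <- xs
  } else {
    hx <- side / nx
    xs <- seq(-side / 2 + hx / 2, side / 2 - hx / 2, length.out = nx)
    zs <- xs
  }
  raw <- .duct_series_eval(xs, zs, side, n_terms)
  v <- raw * (bulk_velocity / .duct_series_mean(max(n_terms, 50)))
  structure(list(v = v, x = xs, z = zs, geometry = geometry,
                 bulk_velocity = bulk_velocity, quarter = quarter),
            class = "flow_field")
}

#' Evaluate the duct profile at arbitrary points
#'
#' @param geometry A [duct_geometry()].
#' @param bulk_velocity Bulk velocity, m/s.
#' @param x,z Coordinates in metres (centred; may be vectors, recycled).
#' @param n_terms Series truncation.
#' @return Streamwise velocity in m/s (0 outside the duct walls).
#' @export
duct_velocity_at <- function(geometry, bulk_velocity, x, z, n_terms = 50) {
  side <- geometry$side_length
  n <- seq(1, by = 2, length.out = n_terms)
  xy <- cbind(x, z)
  v <- numeric(nrow(xy))
  for (k in seq_along(n)) {
    nk <- n[k]
    sgn <- (-1)^((nk - 1) / 2)
    v <- v + (sgn / nk^3) * cos(nk * pi * xy[, 1] / side) *
      (1 - cosh(nk * pi * xy[, 2] / side) / cosh(nk * pi / 2))
  }
  v <- v * (bulk_velocity / .duct_series_mean(max(n_terms, 50)))
  v[abs(xy[, 1]) >= side / 2 | abs(xy[, 2]) >= side / 2] <- 0
  unname(v)
}

#' Inlet (dye injection) specification
#'
#' The four injection patterns: (1) constant injection with the dye radius
#' ramping from `r_initial` to `r_final`; (2) intermittent uniform injection
#' (0.1 s on / 0.25 s off); (3) intermittent injection with a radial cosine
#' concentration profile `phi0 * cos(omega * r)`; (4) continuous injection
#' with temporally cosine-modulated concentration `cos(4*pi/3 * t)`, clipped
#' below at zero.
#'
#' @param case_id Injection case, 1-4.
#' @param inlet_speed Dye injection speed, m/s (default 0.005).
#' @param r_initial Initial dye radius for case 1, m (default 0.37 mm).
#' @param r_final Final/steady dye radius, m (default 2.0 mm).
#' @param ramp_duration Case-1 radius ramp time, s (linear ramp).
#' @param on_duration,off_duration Case 2/3 injection schedule, s.
#' @param phi0 Peak concentration (dimensionless, in (0, 1]).
#' @param omega Radial angular frequency for case 3, rad/m.
#' @param temporal_omega Temporal angular frequency for case 4, rad/s.
#' @return An object of class `inlet_spec`.
#' @export
inlet_spec <- function(case_id,
                       inlet_speed = 0.005,
                       r_initial = 0.00037,
                       r_final = 0.002,
                       ramp_duration = 1.0,
                       on_duration = 0.1,
                       off_duration = 0.25,
                       phi0 = 1.0,
                       omega = 500,
                       temporal_omega = 4 * pi / 3) {
  if (!case_id %in% 1:4) stop("unknown case_id (must be 1, 2, 3 or 4)", call. = FALSE)
  if (r_initial <= 0 || r_initial > r_final)
    stop("require 0 < r_initial <= r_final", call. = FALSE)
  if (phi0 <= 0 || phi0 > 1) stop("phi0 must lie in (0, 1]", call. = FALSE)
  structure(list(case_id = as.integer(case_id), inlet_speed = inlet_speed,
                 r_initial = r_initial, r_final = r_final,
                 ramp_duration = ramp_duration,
                 on_duration = on_duration, off_duration = off_duration,
                 period = on_duration + off_duration,
                 phi0 = phi0, omega = omega, temporal_omega = temporal_omega),
            class = "inlet_spec")
}

#' Is the intermittent injection on at time t?
#'
#' Cases 2 and 3 inject for `on_duration` then pause for `off_duration`,
#' repeating with period `on + off`.  Cases 1 and 4 always inject.
#'
#' @param spec An [inlet_spec()].
#' @param t Time in seconds.
#' @return Logical vector.
#' @export
injection_on <- function(spec, t) {
  if (spec$case_id %in% c(2L, 3L)) {
    (t %% spec$period) < spec$on_duration
  } else {
    rep(TRUE, length(t))
  }
}

#' Current dye radius
#'
#' Case 1 ramps the radius linearly from `r_initial` at t = 0 to `r_final`
#' at `ramp_duration`, constant thereafter; other cases use `r_final`.
#'
#' @param spec An [inlet_spec()].
#' @param t Time in seconds (vectorised).
#' @return Radius in metres.
#' @export
inlet_radius <- function(spec, t) {
  stopifnot(all(t >= 0))
  if (spec$case_id == 1L) {
    frac <- pmin(t / spec$ramp_duration, 1)
    spec$r_initial + frac * (spec$r_final - spec$r_initial)
  } else {
    rep(spec$r_final, length(t))
  }
}

#' Inlet dye concentration
#'
#' Concentration imposed at the dye inlet at time `t` and radial distance
#' `r` from the duct axis.  Cases 1/2: uniform `phi0` inside the current
#' radius (case 2 gated by the on/off schedule).  Case 3:
#' `phi0 * cos(omega * r)` inside the radius, gated by the schedule.
#' Case 4: `cos(temporal_omega * t)` clipped below at zero (negative values
#' read as "no dye injected"), uniform inside the radius.
#'
#' @param spec An [inlet_spec()].
#' @param t Time in seconds (scalar).
#' @param r Radial distance(s) in metres.
#' @return Concentration in [0, 1], same length as `r`.
#' @export
inlet_concentration <- function(spec, t, r) {
  stopifnot(t >= 0, all(r >= 0))
  rad <- inlet_radius(spec, t)
  inside <- r <= rad
  on <- injection_on(spec, t)
  phi <- numeric(length(r))
  if (!on) return(phi)
  if (spec$case_id %in% c(1L, 2L)) {
    phi[inside] <- spec$phi0
  } else if (spec$case_id == 3L) {
    phi[inside] <- pmax(spec$phi0 * cos(spec$omega * r[inside]), 0)
  } else {
    phi[inside] <- max(cos(spec$temporal_omega * t), 0)
  }
  phi
}

# --- scalar transport -------------------------------------------------------

#' Create an empty concentration volume on the scene grid
#'
#' @param config A [scene_config()].
#' @param timestamp Time in seconds.
#' @return An object of class `concentration_volume`: 3-D array `phi`
#'   (nx x ny x nz, values in [0, 1]) plus grid coordinate vectors.  When
#'   `config$quarter` is `TRUE` the array covers x >= 0, z >= 0 only.
#' @export
concentration_volume <- function(config, timestamp = 0) {
  g <- scene_grid(config)
  structure(list(phi = array(0, dim = c(g$nx, g$ny, g$nz)),
                 x = g$x, y = g$y, z = g$z, timestamp = timestamp,
                 quarter = config$quarter),
            class = "concentration_volume")
}

#' Scene grid coordinates
#'
#' Cell-centre coordinates of the simulation grid.  In quarter mode the
#' lateral axes cover `[0, side/2]`; otherwise `[-side/2, side/2]`.  The
#' streamwise axis covers `[0, duct_length]`.
#'
#' @param config A [scene_config()].
#' @return List with `x`, `y`, `z`, cell sizes `hx`, `hy`, `hz`, and sizes.
#' @export
scene_grid <- function(config) {
  side <- config$geometry$side_length
  len <- config$geometry$duct_length
  nx <- config$nx; ny <- config$ny; nz <- config$nz
  if (config$quarter) {
    nxq <- nx %/% 2L; nzq <- nz %/% 2L
    hx <- (side / 2) / nxq; hz <- (side / 2) / nzq
    x <- seq(hx / 2, side / 2 - hx / 2, length.out = nxq)
    z <- seq(hz / 2, side / 2 - hz / 2, length.out = nzq)
    nx <- nxq; nz <- nzq
  } else {
    hx <- side / nx; hz <- side / nz
    x <- seq(-side / 2 + hx / 2, side / 2 - hx / 2, length.out = nx)
    z <- seq(-side / 2 + hz / 2, side / 2 - hz / 2, length.out = nz)
  }
  hy <- len / config$ny
  y <- seq(hy / 2, len - hy / 2, length.out = config$ny)
  list(x = x, y = y, z = z, hx = hx, hy = hy, hz = hz,
       nx = nx, ny = config$ny, nz = nz)
}

#' Flow field sampled on the scene grid
#'
#' @param config A [scene_config()].
#' @param n_terms Series truncation for the duct profile.
#' @return `flow_field` with `v` evaluated at the scene's (x, z) cell
#'   centres (quarter or full, matching the config).
#' @export
scene_flow <- function(config, n_terms = 50) {
  g <- scene_grid(config)
  v <- matrix(duct_velocity_at(config$geometry, config$bulk_velocity,
                               rep(g$x, times = g$nz),
                               rep(g$z, each = length(g$x)),
                               n_terms = n_terms),
              nrow = length(g$x))
  structure(list(v = v, x = g$x, z = g$z, geometry = config$geometry,
                 bulk_velocity = config$bulk_velocity,
                 quarter = config$quarter),
            class = "flow_field")
}

# Catmull-Rom cubic interpolation weights for fractional offset f in [0,1)
.cubic_weights <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  list(w0 = -0.5 * f3 + f2 - 0.5 * f,
       w1 = 1.5 * f3 - 2.5 * f2 + 1,
       w2 = -1.5 * f3 + 2 * f2 + 0.5 * f,
       w3 = 0.5 * f3 - 0.5 * f2)
}

#' Advance the concentration one time step
#'
#' Semi-Lagrangian advection (unconditionally stable) followed by explicit
#' diffusion, then re-imposition of the inlet boundary.  For the default
#' unidirectional duct flow (u = w = 0) departure points move only along y
#' and a cubic (Catmull-Rom) interpolation is used to limit numerical
#' diffusion; with nonzero lateral velocities a trilinear semi-Lagrangian
#' step is taken.  Departure points upstream of the inlet sample the inlet
#' concentration; the outlet is zero-gradient.  Concentrations are clamped
#' to [0, 1] (cubic interpolation can overshoot by a small amount near
#' sharp fronts).
#'
#' @param volume A `concentration_volume`.
#' @param flow A `flow_field` on the same cross-section grid (streamwise
#'   component), or a list with full `u`, `v`, `w` arrays on the volume
#'   grid for the general path.
#' @param inlet An [inlet_spec()] or `NULL` for no injection.
#' @param dt Time step, s.
#' @param D Diffusivity, m^2/s.
#' @param interp `"cubic"` (default, unidirectional flow) or `"linear"`.
#' @return The advanced `concentration_volume` (timestamp + dt).
#' @export
transport_step <- function(volume, flow, inlet, dt, D = 1e-9,
                           interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  phi <- volume$phi
  dims <- dim(phi)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  hy <- volume$y[2] - volume$y[1]
  general <- is.list(flow) && !inherits(flow, "flow_field")

  t_new <- volume$timestamp + dt
  inlet_plane <- if (is.null(inlet)) {
    matrix(0, nx, nz)
  } else {
    rr <- sqrt(outer(volume$x^2, volume$z^2, "+"))
    matrix(inlet_concentration(inlet, t_new, as.vector(rr)), nx, nz)
  }

  if (!general) {
    if (!identical(dim(flow$v), c(nx, nz)))
      stop("grid mismatch between volume and flow field", call. = FALSE)
    # displacement in cells along y, constant per (x, z) column
    s <- flow$v * dt / hy
    phi <- .advect_y(phi, s, inlet_plane, interp)
  } else {
    if (!identical(dim(flow$v), dims))
      stop("grid mismatch between volume and flow field", call. = FALSE)
    hx <- volume$x[2] - volume$x[1]
    hz <- volume$z[2] - volume$z[1]
    phi <- .advect_trilinear(phi, flow$u * dt / hx, flow$v * dt / hy,
                             flow$w * dt / hz, inlet_plane)
  }

  if (D > 0) {
    hx <- volume$x[2] - volume$x[1]
    hz <- volume$z[2] - volume$z[1]
    rx <- D * dt / hx^2; ry <- D * dt / hy^2; rz <- D * dt / hz^2
    if (max(rx, ry, rz) > 1 / 6)
      stop("diffusion number exceeds explicit stability limit; reduce dt",
           call. = FALSE)
    phi <- .diffuse(phi, rx, ry, rz)
  }

  if (!is.null(inlet)) phi[, 1, ] <- inlet_plane
  phi[phi < 0] <- 0
  phi[phi > 1] <- 1
  volume$phi <- phi
  volume$timestamp <- t_new
  volume
}

# Semi-Lagrangian advection along y only; s = displacement in cells per
# column (nx x nz).  Ghost planes upstream hold the inlet concentration,
# downstream copy the last plane (zero-gradient outflow).
.advect_y <- function(phi, s, inlet_plane, interp) {
  dims <- dim(phi); nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  smax <- ceiling(max(abs(s))) + 2L
  npad <- smax + 2L
  padded <- array(0, dim = c(nx, ny + 2L * npad, nz))
  padded[, npad + seq_len(ny), ] <- phi
  for (k in seq_len(npad)) padded[, k, ] <- inlet_plane
  for (k in seq_len(npad)) padded[, ny + npad + k, ] <- phi[, ny, ]

  # departure j index (fractional) for each (i, j, k): j - s[i, k]
  sarr <- aperm(array(s, dim = c(nx, nz, ny)), c(1, 3, 2))
  jgrid <- array(rep(seq_len(ny), each = nx), dim = c(nx, ny, nz))
  jd <- jgrid - sarr
  j0 <- floor(jd)
  f <- jd - j0
  base <- npad + j0  # index of the "w1" node in padded coords

  flat <- function(joff) {
    idx <- array(seq_len(nx * nz), dim = c(nx, nz))
    # linear index into padded array: i + (j-1)*nx + (k-1)*nx*nyp
    iarr <- array(rep(seq_len(nx), times = ny * nz), dim = c(nx, ny, nz))
    karr <- array(rep(seq_len(nz), each = nx * ny), dim = c(nx, ny, nz))
    jarr <- base + joff
    iarr + (jarr - 1) * nx + (karr - 1) * nx * (ny + 2L * npad)
  }
  if (interp == "cubic") {
    w <- .cubic_weights(f)
    out <- w$w0 * padded[flat(-1L)] + w$w1 * padded[flat(0L)] +
      w$w2 * padded[flat(1L)] + w$w3 * padded[flat(2L)]
  } else {
    out <- (1 - f) * padded[flat(0L)] + f * padded[flat(1L)]
  }
  array(out, dim = dims)
}

# General trilinear semi-Lagrangian step; sx, sy, sz are per-cell
# displacements in cells.  Lateral boundaries clamp (no-flux walls);
# upstream ghost = inlet concentration, downstream ghost = last plane.
.advect_trilinear <- function(phi, sx, sy, sz, inlet_plane) {
  dims <- dim(phi); nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  iarr <- array(rep(seq_len(nx), times = ny * nz), dim = dims)
  jarr <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = dims)
  karr <- array(rep(seq_len(nz), each = nx * ny), dim = dims)
  xd <- iarr - sx; yd <- jarr - sy; zd <- karr - sz
  x0 <- floor(xd); y0 <- floor(yd); z0 <- floor(zd)
  fx <- xd - x0; fy <- yd - y0; fz <- zd - z0
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  below <- y0 < 1L  # departure upstream of the inlet plane
  val <- array(0, dim = dims)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wi <- (if (dx == 0) 1 - fx else fx) *
          (if (dy == 0) 1 - fy else fy) *
          (if (dz == 0) 1 - fz else fz)
    ii <- cl(x0 + dx, nx); jj <- cl(y0 + dy, ny); kk <- cl(z0 + dz, nz)
    lin <- ii + (jj - 1) * nx + (kk - 1) * nx * ny
    contrib <- phi[lin]
    if (any(below)) {
      # nodes at or below the inlet sample the inlet boundary value
      jraw <- y0 + dy
      use_inlet <- jraw < 1L
      if (any(use_inlet)) {
        linxz <- cl(x0 + dx, nx)[use_inlet] + (cl(z0 + dz, nz)[use_inlet] - 1) * nx
        contrib[use_inlet] <- inlet_plane[linxz]
      }
    }
    val <- val + wi * contrib
  }
  val
}

# Explicit second-order diffusion with Neumann walls; y boundaries use
# zero-gradient ghosts as well (the inlet plane is overwritten afterwards).
.diffuse <- function(phi, rx, ry, rz) {
  d <- dim(phi); nx <- d[1]; ny <- d[2]; nz <- d[3]
  ixp <- c(2:nx, nx); ixm <- c(1, 1:(nx - 1))
  iyp <- c(2:ny, ny); iym <- c(1, 1:(ny - 1))
  izp <- c(2:nz, nz); izm <- c(1, 1:(nz - 1))
  phi +
    rx * (phi[ixp, , , drop = FALSE] - 2 * phi + phi[ixm, , , drop = FALSE]) +
    ry * (phi[, iyp, , drop = FALSE] - 2 * phi + phi[, iym, , drop = FALSE]) +
    rz * (phi[, , izp, drop = FALSE] - 2 * phi + phi[, , izm, drop = FALSE])
}

#' Total dye mass in a volume
#'
#' Integral of concentration over the volume (quarter volumes are reported
#' as the quarter integral).
#'
#' @param volume A `concentration_volume`.
#' @return Mass in concentration x m^3 units.
#' @export
dye_mass <- function(volume) {
  hx <- volume$x[2] - volume$x[1]
  hy <- volume$y[2] - volume$y[1]
  hz <- volume$z[2] - volume$z[1]
  sum(volume$phi) * hx * hy * hz
}

#' Run one injection case
#'
#' Integrates the scalar-transport model for `duration` seconds and exports
#' concentration volumes at every multiple of `export_interval` together
#' with a companion export `pair_offset` (default 0.02 s) later; every
#' interval/companion pair later becomes one optical-flow image pair.
#'
#' @param case_id Injection case 1-4, or an [inlet_spec()].
#' @param config A [scene_config()].
#' @param duration Simulated time, s (>= export_interval + pair_offset).
#' @param export_interval Export cadence, s (0.2 or 0.3 in the default
#'   schedule).
#' @param pair_offset Companion offset, s (default 0.02).
#' @return An object of class `scene_sequence`: list with `snapshots`
#'   (each: `timestamp`, `volume`, `truth` center-plane ground truth),
#'   `pairs` (index pairs into snapshots), the flow field, and metadata.
#' @export
run_case <- function(case_id, config = scene_config(), duration,
                     export_interval = 0.2, pair_offset = 0.02) {
  inlet <- if (inherits(case_id, "inlet_spec")) case_id else inlet_spec(case_id)
  if (duration < export_interval + pair_offset)
    stop("duration must be >= export_interval + pair_offset", call. = FALSE)
  dt <- config$dt_sim
  # export times must fall on the step grid
  stopifnot(abs(export_interval / dt - round(export_interval / dt)) < 1e-9,
            abs(pair_offset / dt - round(pair_offset / dt)) < 1e-9)
  flow <- scene_flow(config)
  vol <- concentration_volume(config, timestamp = 0)
  n_steps <- round(duration / dt)
  base_times <- seq(export_interval, duration - pair_offset,
                    by = export_interval)
  export_times <- sort(c(base_times, base_times + pair_offset))
  eps <- dt * 1e-6
  snapshots <- vector("list", length(export_times))
  si <- 1L
  truth <- center_plane_truth(config, flow)
  for (step in seq_len(n_steps)) {
    vol <- transport_step(vol, flow, inlet, dt, D = config$diffusivity)
    while (si <= length(export_times) &&
           vol$timestamp >= export_times[si] - eps) {
      snapshots[[si]] <- list(timestamp = export_times[si], volume = vol)
      si <- si + 1L
    }
  }
  pairs <- matrix(seq_along(export_times), ncol = 2, byrow = TRUE)
  structure(list(snapshots = snapshots[seq_len(si - 1L)],
                 pairs = pairs[pairs[, 2] <= si - 1L, , drop = FALSE],
                 flow = flow, truth = truth, inlet = inlet, config = config,
                 export_interval = export_interval,
                 pair_offset = pair_offset),
            class = "scene_sequence")
}

#' Center-plane ground-truth velocity field
#'
#' Ground truth for supervision is extracted at the duct center plane
#' (z = 0): `v(x, y) = v(x, z = 0)` from the duct profile (independent of y
#' for fully developed flow) and `u = 0`.
#'
#' @param config A [scene_config()].
#' @param flow Optional precomputed `flow_field` (quarter or full).
#' @return List with `x` (full-width coordinates), `y`, and matrices `u`,
#'   `v` (length(x) x length(y)), in m/s.
#' @export
center_plane_truth <- function(config, flow = NULL) {
  g <- scene_grid(config)
  if (config$quarter) {
    x <- c(-rev(g$x), g$x)
  } else {
    x <- g$x
  }
  v_line <- duct_velocity_at(config$geometry, config$bulk_velocity,
                             x, rep(0, length(x)))
  list(x = x, y = g$y,
       u = matrix(0, length(x), length(g$y)),
       v = matrix(v_line, length(x), length(g$y)))
}

#' Mirror a quarter-domain volume to the full domain
#'
#' @param volume A quarter-domain `concentration_volume`.
#' @return Full-domain `concentration_volume` (symmetry in x and z).
#' @export
mirror_quarter <- function(volume) {
  if (!isTRUE(volume$quarter)) return(volume)
  phi <- volume$phi
  nx <- dim(phi)[1]; nz <- dim(phi)[3]
  full <- array(0, dim = c(2 * nx, dim(phi)[2], 2 * nz))
  full[nx + 1:nx, , nz + 1:nz] <- phi
  full[nx:1, , nz + 1:nz] <- phi
  full[nx + 1:nx, , nz:1] <- phi
  full[nx:1, , nz:1] <- phi
  structure(list(phi = full, x = c(-rev(volume$x), volume$x),
                 y = volume$y, z = c(-rev(volume$z), volume$z),
                 timestamp = volume$timestamp, quarter = FALSE),
            class = "concentration_volume")
}
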