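#' Optical-flow configuration
#'
#' Parameters of the variational optical-flow solver.  The data term is
#' the brightness-transport residual `Qt + V.grad(Q) + Q div(V) - D lap(Q)`
#' and the regulariser penalises velocity gradients with weight `lambda`.
#'
#' @param dt Frame interval, s (default 0.02).
#' @param D Diffusion coefficient in the brightness-transport constraint,
#'   m^2/s (converted internally to pixel units; negligible at the default
#'   scales but part of the model).
#' @param lambda Smoothness weight (gray-level^2 units).  The default was
#'   calibrated on synthetic sub-pixel blob translations so a 0.5-pixel
#'   shift is recovered within 10%.
#' @param max_iter Iteration cap for the fixed-point sweeps.
#' @param tol Relative objective-decrease tolerance for convergence.
#' @return Object of class `ofm_config`.
#' @export
ofm_config <- function(dt = 0.02, D = 1e-9, lambda = 5000,
                       max_iter = 500, tol = 1e-6) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  structure(list(dt = dt, D = D, lambda = lambda,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "ofm_config")
}

# first derivative along rows (x) with central differences interior and
# one-sided differences at the borders
.ddx <- function(f) {
  n <- nrow(f)
  d <- (f[c(2:n, n), , drop = FALSE] - f[c(1, 1:(n - 1)), , drop = FALSE]) / 2
  d[1, ] <- f[2, ] - f[1, ]
  d[n, ] <- f[n, ] - f[n - 1, ]
  d
}

.ddy <- function(f) t(.ddx(t(f)))

.d2x <- function(f) {
  n <- nrow(f)
  f[c(2:n, n), , drop = FALSE] - 2 * f + f[c(1, 1:(n - 1)), , drop = FALSE]
}

.d2y <- function(f) t(.d2x(t(f)))

# 4-neighbour average with replicated (Neumann) borders
.avg4 <- function(f) {
  n <- nrow(f); m <- ncol(f)
  (f[c(2:n, n), , drop = FALSE] + f[c(1, 1:(n - 1)), , drop = FALSE] +
   f[, c(2:m, m), drop = FALSE] + f[, c(1, 1:(m - 1)), drop = FALSE]) / 4
}

#' Intensity gradients of a projection image
#'
#' Central differences in the interior, one-sided at the borders, in
#' gray-levels per pixel.  The gradients accompany every optical-flow
#' vector as features: they indicate whether a vector was computed from a
#' low- or high-contrast region.
#'
#' @param image A `projective_image` (or a bare gray matrix, x by y).
#' @return List with matrices `Ix`, `Iy`.
#' @export
intensity_gradients <- function(image) {
  g <- if (inherits(image, "projective_image")) image$gray else image
  if (nrow(g) < 3 || ncol(g) < 3) stop("image must be at least 3 x 3", call. = FALSE)
  g <- matrix(as.numeric(g), nrow(g))
  list(Ix = .ddx(g), Iy = .ddy(g))
}

# forward difference along rows with a zero last row (Neumann); .fdxT is
# its exact adjoint, so the discrete objective has a consistent gradient
.fdx <- function(f) {
  n <- nrow(f)
  out <- f[c(2:n, n), , drop = FALSE] - f
  out[n, ] <- 0
  out
}

.fdxT <- function(g) {
  n <- nrow(g)
  out <- g[c(1, 1:(n - 1)), , drop = FALSE] - g
  out[1, ] <- -g[1, ]
  out[n, ] <- g[n - 1, ]
  out
}

.fdy <- function(f) t(.fdx(t(f)))
.fdyT <- function(g) t(.fdxT(t(g)))

# variational objective: data residual squared + lambda * |grad V|^2
.ofm_objective <- function(u, v, Qx, Qy, Qbar, cterm, lambda) {
  r <- cterm + u * Qx + v * Qy + Qbar * (.fdx(u) + .fdy(v))
  sum(r^2) + lambda * (sum(.fdx(u)^2) + sum(.fdy(u)^2) +
                       sum(.fdx(v)^2) + sum(.fdy(v)^2))
}

#' Estimate per-pixel velocity from an image pair
#'
#' Solves the extended brightness-transport constraint with a global
#' (Horn-Schunck style) smoothness prior.  The model residual is
#' `Qt + u Qx + v Qy + Q (du/dx + dv/dy) - D lap(Q)`; the divergence
#' source term accounts for dye-column thickness changes and the
#' diffusion term for dye spreading, both absent from the classical
#' brightness-constancy constraint.  Spatial terms are evaluated on the
#' frame average for second-order accuracy in time.  The objective is a
#' convex quadratic in the velocity fields; it is minimised by conjugate
#' gradients on its normal equations, so the recorded objective history
#' is non-increasing and the solver terminates at a controlled residual
#' tolerance.
#'
#' @param frame_a,frame_b Consecutive `projective_image`s (same shape).
#'   Expected pattern displacement below ~1 pixel for best accuracy.
#' @param config An [ofm_config()].
#' @return Object of class `ofm_field`: matrices `u`, `v` (m/s), `Ix`,
#'   `Iy` (gray/pixel), pixel-unit fields `u_px`, `v_px`, the energy
#'   history, iteration count, convergence flag, and the image mapping.
#' @export
estimate_flow <- function(frame_a, frame_b, config = ofm_config()) {
  if (!identical(dim(frame_a$gray), dim(frame_b$gray)))
    stop("frames have different shapes", call. = FALSE)
  Qa <- matrix(as.numeric(frame_a$gray), nrow(frame_a$gray))
  Qb <- matrix(as.numeric(frame_b$gray), nrow(frame_b$gray))
  Qbar <- (Qa + Qb) / 2
  Qt <- Qb - Qa                       # gray per frame
  Qx <- .ddx(Qbar); Qy <- .ddy(Qbar)  # gray per pixel
  map <- frame_a$mapping
  Dx <- config$D * config$dt / map$pitch_x^2  # pixel^2 per frame
  Dy <- config$D * config$dt / map$pitch_y^2
  cterm <- Qt - (Dx * .d2x(Qbar) + Dy * .d2y(Qbar))
  lambda <- config$lambda

  u <- matrix(0, nrow(Qa), ncol(Qa))
  v <- u
  # normal equations (A^T A + lambda G^T G) V = -A^T c with
  # A V = Qx u + Qy v + Qbar (du/dx + dv/dy)
  applyA <- function(u, v) Qx * u + Qy * v + Qbar * (.fdx(u) + .fdy(v))
  applyAT <- function(r) list(u = Qx * r + .fdxT(Qbar * r),
                              v = Qy * r + .fdyT(Qbar * r))
  applyH <- function(u, v) {
    at <- applyAT(applyA(u, v))
    list(u = at$u + lambda * (.fdxT(.fdx(u)) + .fdyT(.fdy(u))),
         v = at$v + lambda * (.fdxT(.fdx(v)) + .fdyT(.fdy(v))))
  }
  b <- applyAT(cterm)
  ru <- -b$u; rv <- -b$v  # residual of the normal equations at V = 0
  pu <- ru; pv <- rv
  rs <- sum(ru^2) + sum(rv^2)
  rs0 <- rs
  rs_floor <- 1e-12 * length(ru)  # identical frames: nothing to solve
  history <- .ofm_objective(u, v, Qx, Qy, Qbar, cterm, lambda)
  converged <- rs <= rs_floor
  iter <- 0L
  while (!converged && iter < config$max_iter) {
    iter <- iter + 1L
    hp <- applyH(pu, pv)
    denom <- sum(pu * hp$u) + sum(pv * hp$v)
    if (denom <= 0) { converged <- TRUE; break }
    alpha <- rs / denom
    u <- u + alpha * pu; v <- v + alpha * pv
    ru <- ru - alpha * hp$u; rv <- rv - alpha * hp$v
    rs_new <- sum(ru^2) + sum(rv^2)
    history <- c(history, .ofm_objective(u, v, Qx, Qy, Qbar, cterm, lambda))
    if (rs_new <= config$tol^2 * rs0 + rs_floor) { converged <- TRUE; break }
    beta <- rs_new / rs
    pu <- ru + beta * pu; pv <- rv + beta * pv
    rs <- rs_new
  }
  energy <- history[length(history)]
  if (!converged)
    warning(sprintf("optical flow did not converge in %d iterations (final objective %.4g)",
                    iter, energy))
  grads <- intensity_gradients(frame_a)
  structure(list(u = u * map$pitch_x / config$dt,
                 v = v * map$pitch_y / config$dt,
                 u_px = u, v_px = v,
                 Ix = grads$Ix, Iy = grads$Iy,
                 energy = history, iterations = iter,
                 converged = converged, mapping = map,
                 dt = config$dt),
            class = "ofm_field")
}

#' Persist an optical-flow field as CSV with a JSON sidecar
#'
#' Columns: pixel_i, pixel_j (1-based), x_m, y_m, u_ofm, v_ofm, Ix, Iy.
#'
#' @param field An `ofm_field`.
#' @param path Output CSV path.
#' @param meta Extra sidecar metadata (e.g. pair timestamps).
#' @return `path`, invisibly.
#' @export
write_ofm_field <- function(field, path, meta = list()) {
  nx <- nrow(field$u); ny <- ncol(field$u)
  df <- data.frame(
    pixel_i = rep(seq_len(nx), times = ny),
    pixel_j = rep(seq_len(ny), each = nx),
    x_m = rep(field$mapping$x, times = ny),
    y_m = rep(field$mapping$y, each = nx),
    u_ofm = as.vector(field$u), v_ofm = as.vector(field$v),
    Ix = as.vector(field$Ix), Iy = as.vector(field$Iy))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(list(iterations = field$iterations,
                              converged = field$converged,
                              dt = field$dt), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
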