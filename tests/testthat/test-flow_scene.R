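test_that("duct profile matches the classical square-duct solution", {
  g <- duct_geometry()
  # converged series: centerline-to-bulk ratio of square-duct laminar flow
  expect_equal(duct_velocity_at(g, 1, 0, 0), 2.0962, tolerance = 1e-4)
  # no-slip on the walls
  expect_equal(duct_velocity_at(g, 1, g$side_length / 2, 0), 0)
  expect_equal(duct_velocity_at(g, 1, 0.003, -g$side_length / 2), 0)
  # symmetry under x -> -x and z -> -z
  ff <- duct_velocity_profile(g, 1, nx = 32, nz = 32)
  expect_equal(ff$v, ff$v[32:1, ], tolerance = 1e-12)
  expect_equal(ff$v, ff$v[, 32:1], tolerance = 1e-12)
  # discrete cross-section mean approaches the bulk velocity
  expect_equal(mean(duct_velocity_profile(g, 2, 128, 128)$v), 2,
               tolerance = 1e-3)
})

test_that("duct profile agrees with a finite-difference Poisson oracle", {
  skip_if_not_installed("Matrix")
  n <- 64
  g <- duct_geometry()
  # -lap(v) = const on the node-centred interior grid (walls are Dirichlet
  # nodes): the standard second-order 5-point Poisson problem
  h <- g$side_length / (n + 1)
  xs <- seq(-g$side_length / 2 + h, g$side_length / 2 - h, length.out = n)
  N <- n * n
  idx <- function(i, j) (j - 1) * n + i
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    ii <- c(ii, idx(i, j)); jj <- c(jj, idx(i, j)); xx <- c(xx, 4)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      a <- i + d[1]; b <- j + d[2]
      if (a >= 1 && a <= n && b >= 1 && b <= n) {
        ii <- c(ii, idx(i, j)); jj <- c(jj, idx(a, b)); xx <- c(xx, -1)
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx / h^2)
  v_fd <- as.numeric(Matrix::solve(A, rep(1, N)))
  v_fd <- matrix(v_fd, n, n)
  v_series <- matrix(duct_velocity_at(g, 1, rep(xs, n), rep(xs, each = n)),
                     n, n)
  # scale both to unit mean and compare in relative L2
  v_fd <- v_fd / mean(v_fd)
  v_series <- v_series / mean(v_series)
  rel_l2 <- sqrt(sum((v_fd - v_series)^2) / sum(v_series^2))
  expect_lt(rel_l2, 1e-3)
})

test_that("inlet concentration reproduces the four injection patterns", {
  # case 3: radial cosine, phi0 = 1, omega = 500/m
  s3 <- inlet_spec(3)
  expect_equal(round(inlet_concentration(s3, t = 0.05, r = 0.002), 2), 0.54)
  expect_equal(inlet_concentration(s3, t = 0.05, r = 0), 1.0)
  # case 4: temporal cosine, cos(0) = 1, clipped at 0 in the trough
  s4 <- inlet_spec(4)
  expect_equal(inlet_concentration(s4, t = 0, r = 0), 1.0)
  expect_equal(inlet_concentration(s4, t = 0.75, r = 0), 0)  # cos(pi) < 0
  # case 2 schedule: period 0.35 s, t = 0.36 is injecting again
  s2 <- inlet_spec(2)
  expect_equal(s2$period, 0.35)
  expect_true(injection_on(s2, 0.36))
  expect_false(injection_on(s2, 0.2))
  # outside the radius: no dye
  expect_equal(inlet_concentration(s2, t = 0.01, r = 0.01), 0)
  expect_error(inlet_spec(5), "case_id")
})

test_that("case-1 radius ramps linearly from 0.37 mm to 2.0 mm", {
  s1 <- inlet_spec(1, ramp_duration = 1.0)
  expect_equal(inlet_radius(s1, 0), 0.00037)
  expect_equal(inlet_radius(s1, 1.0), 0.002)
  expect_equal(inlet_radius(s1, 5), 0.002)
  expect_equal(inlet_radius(s1, 0.5), (0.00037 + 0.002) / 2)
  expect_equal(inlet_radius(inlet_spec(2), 0), 0.002)
})

test_that("transport is the identity for zero velocity and diffusivity", {
  sc <- scene_config(nx = 16, ny = 32, nz = 16, quarter = FALSE)
  vol <- concentration_volume(sc)
  gr <- scene_grid(sc)
  set.seed(7)
  vol$phi <- array(runif(gr$nx * gr$ny * gr$nz), dim = c(gr$nx, gr$ny, gr$nz))
  zero <- structure(list(v = matrix(0, gr$nx, gr$nz)), class = "flow_field")
  out <- transport_step(vol, zero, NULL, dt = 0.05, D = 0)
  expect_equal(out$phi, vol$phi, tolerance = 1e-14)
})

test_that("a Gaussian blob advects at the flow speed and stays bounded", {
  sc <- scene_config(nx = 24, ny = 64, nz = 24, quarter = FALSE, dt_sim = 0.01)
  gr <- scene_grid(sc)
  vol <- concentration_volume(sc)
  y0 <- 0.008; sig <- 0.002
  blob <- 0.8 * exp(-(outer(rep(1, gr$nx), gr$y) - y0)^2 / (2 * sig^2))
  vol$phi <- array(rep(blob, times = gr$nz), dim = c(gr$nx, gr$ny, gr$nz))
  V0 <- 0.02
  flow <- structure(list(v = matrix(V0, gr$nx, gr$nz)), class = "flow_field")
  dt <- 0.05
  mass0 <- dye_mass(vol)
  out <- vol
  for (k in 1:4) out <- transport_step(out, flow, NULL, dt = dt, D = 0)
  com <- function(v) sum(sweep(v$phi, 2, gr$y, "*")) / sum(v$phi)
  # displacement matches the analytic translation within one cell
  expect_equal(com(out) - com(vol), V0 * dt * 4, tolerance = gr$hy / (V0 * dt * 4))
  # pointwise comparison against the translated analytic Gaussian
  blob4 <- 0.8 * exp(-(outer(rep(1, gr$nx), gr$y) - y0 - 4 * V0 * dt)^2 / (2 * sig^2))
  expect_lt(max(abs(out$phi[1, , 1] - blob4[1, ])), 0.02)
  # concentration bounds and closed-run mass conservation within 1%
  expect_gte(min(out$phi), 0)
  expect_lte(max(out$phi), 1)
  expect_equal(dye_mass(out) / mass0, 1, tolerance = 0.01)
})

test_that("pure diffusion grows the blob variance by 2 D dt per step", {
  sc <- scene_config(nx = 16, ny = 64, nz = 16, quarter = FALSE)
  gr <- scene_grid(sc)
  vol <- concentration_volume(sc)
  y0 <- 0.0127; sig <- 0.0015
  blob <- 0.5 * exp(-(outer(rep(1, gr$nx), gr$y) - y0)^2 / (2 * sig^2))
  vol$phi <- array(rep(blob, times = gr$nz), dim = c(gr$nx, gr$ny, gr$nz))
  zero <- structure(list(v = matrix(0, gr$nx, gr$nz)), class = "flow_field")
  D <- 1e-6; dt <- 0.01; nstep <- 10
  out <- vol
  for (k in seq_len(nstep)) out <- transport_step(out, zero, NULL, dt, D = D)
  vary <- function(v) {
    w <- apply(v$phi, 2, sum); m <- sum(w * gr$y) / sum(w)
    sum(w * (gr$y - m)^2) / sum(w)
  }
  expect_equal(vary(out) - vary(vol), 2 * D * dt * nstep, tolerance = 0.05 * 2 * D * dt * nstep)
})

test_that("transport rejects grid mismatches and unstable diffusion steps", {
  sc <- scene_config(nx = 16, ny = 32, nz = 16, quarter = FALSE)
  vol <- concentration_volume(sc)
  bad <- structure(list(v = matrix(0, 8, 8)), class = "flow_field")
  expect_error(transport_step(vol, bad, NULL, 0.01), "grid mismatch")
  gr <- scene_grid(sc)
  zero <- structure(list(v = matrix(0, gr$nx, gr$nz)), class = "flow_field")
  expect_error(transport_step(vol, zero, NULL, dt = 10, D = 1e-3),
               "stability")
})

test_that("quarter-domain symmetry reproduces the full-domain field", {
  mk <- function(quarter) {
    sc <- scene_config(nx = 16, ny = 32, nz = 16, quarter = quarter,
                       dt_sim = 0.02)
    vol <- concentration_volume(sc)
    flow <- scene_flow(sc)
    inlet <- inlet_spec(1)
    for (k in 1:10) vol <- transport_step(vol, flow, inlet, sc$dt_sim,
                                          D = sc$diffusivity)
    mirror_quarter(vol)
  }
  full <- mk(FALSE); mirrored <- mk(TRUE)
  expect_equal(mirrored$phi, full$phi, tolerance = 1e-10)
})

test_that("run_case honours the export schedule and pairing contract", {
  sc <- scene_config(nx = 16, ny = 32, nz = 16, quarter = TRUE, dt_sim = 0.02)
  seq_ <- run_case(2, sc, duration = 0.92, export_interval = 0.3)
  # k interval exports -> 2k snapshots, k pairs
  expect_equal(length(seq_$snapshots), 6)
  expect_equal(nrow(seq_$pairs), 3)
  ts <- vapply(seq_$snapshots, function(s) s$timestamp, numeric(1))
  expect_true(all(diff(ts) > 0))
  # every companion is exactly 0.02 s after its interval export
  for (p in seq_len(nrow(seq_$pairs)))
    expect_equal(ts[seq_$pairs[p, 2]] - ts[seq_$pairs[p, 1]], 0.02,
                 tolerance = 1e-9)
  expect_error(run_case(2, sc, duration = 0.1, export_interval = 0.3),
               "duration")
  # the reference corpus size: 106 snapshots pair into 53 datasets
  expect_equal(pair_count(106), 53)
  expect_error(pair_count(7), "odd")
})

test_that("concentration stays within [0, 1] across a full case run", {
  sc <- scene_config(nx = 16, ny = 32, nz = 16, quarter = TRUE, dt_sim = 0.02)
  for (cid in c(3, 4)) {
    seq_ <- run_case(cid, sc, duration = 0.62, export_interval = 0.3)
    for (s in seq_$snapshots) {
      expect_gte(min(s$volume$phi), 0)
      expect_lte(max(s$volume$phi), 1)
    }
  }
})
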