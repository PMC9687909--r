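test_that("intensity gradients are exact for linear and quadratic ramps", {
  u <- matrix(100L, 9, 9)
  g <- intensity_gradients(u)
  expect_true(all(g$Ix == 0) && all(g$Iy == 0))
  ramp <- matrix(2L * row(matrix(0L, 9, 9)), 9)
  g <- intensity_gradients(ramp)
  expect_true(all(g$Ix == 2))
  quad <- matrix(as.integer(row(matrix(0L, 9, 9))^2), 9)
  g <- intensity_gradients(quad)
  # central difference is exact for quadratics: d(x^2)/dx = 2x
  for (c_ in 2:8) expect_equal(g$Ix[c_, 5], 2 * c_)
  expect_error(intensity_gradients(matrix(0L, 2, 2)), "3 x 3")
})

test_that("identical frames yield a zero flow field", {
  fa <- blob_image(0)
  oc <- ofm_config(dt = 1)
  oc$D <- 0  # with D > 0 a static diffusing pattern implies real drift
  fl <- estimate_flow(fa, fa, oc)
  expect_lt(max(abs(fl$u)), 1e-6)
  expect_lt(max(abs(fl$v)), 1e-6)
})

test_that("a half-pixel translation is recovered within 10%", {
  fa <- blob_image(0)
  fb <- blob_image(0.5)
  oc <- ofm_config(dt = 1, lambda = 5000, max_iter = 500, tol = 1e-7)
  fl <- suppressWarnings(estimate_flow(fa, fb, oc))
  sel <- abs(fl$Iy) > stats::quantile(abs(fl$Iy), 0.9)
  v_true <- 0.5 * fa$mapping$pitch_y
  expect_equal(mean(fl$v[sel]), v_true, tolerance = 0.1)
  # independent oracle: exhaustive sub-pixel shift search by
  # cross-correlation finds the same displacement
  s_hat <- xcorr_shift_oracle(fa, fb)
  expect_equal(s_hat, 0.5, tolerance = 0.1)
  expect_equal(mean(fl$v_px[sel]), s_hat, tolerance = 0.1 * s_hat + 0.051)
  # lateral component stays near zero on average
  expect_lt(abs(mean(fl$u_px[sel])), 0.05)
})

test_that("a pure-diffusion pair with matched D yields near-zero motion", {
  blur <- 2  # sigma^2 growth in px^2
  fa <- blob_image(0)
  D_match <- blur * fa$mapping$pitch_x^2 / 2  # dt = 1 frame
  fb <- blob_image(0, blur = blur)
  oc <- ofm_config(dt = 1, lambda = 5000, max_iter = 500, tol = 1e-7)
  oc$D <- D_match
  fl <- suppressWarnings(estimate_flow(fa, fb, oc))
  sel <- (abs(fl$Ix) + abs(fl$Iy)) >
    stats::quantile(abs(fl$Ix) + abs(fl$Iy), 0.9)
  speed <- sqrt(fl$u^2 + fl$v^2)
  v_ref <- 0.5 * fa$mapping$pitch_y  # the translation-case speed above
  expect_lt(mean(speed[sel]), 0.05 * v_ref)
})

test_that("the variational objective is non-increasing over iterations", {
  fl <- suppressWarnings(estimate_flow(blob_image(0), blob_image(0.7),
                                       ofm_config(dt = 1, max_iter = 200)))
  expect_true(all(diff(fl$energy) <= 1e-9 * fl$energy[1]))
  expect_lt(fl$energy[length(fl$energy)], fl$energy[1])
})

test_that("rotating both frames rotates the recovered field", {
  rot90 <- function(img) {
    g <- t(img$gray)[ncol(img$gray):1, ]
    cfg <- imaging_config(width = nrow(g), height = ncol(g))
    structure(list(gray = g, timestamp = 0,
                   mapping = image_mapping(duct_geometry(), cfg),
                   geometry = duct_geometry(), config = cfg),
              class = "projective_image")
  }
  oc <- ofm_config(dt = 1, lambda = 5000, max_iter = 400, tol = 1e-7)
  fa <- blob_image(0); fb <- blob_image(0.5)
  f1 <- suppressWarnings(estimate_flow(fa, fb, oc))
  f2 <- suppressWarnings(estimate_flow(rot90(fa), rot90(fb), oc))
  s1 <- abs(f1$Iy) > stats::quantile(abs(f1$Iy), 0.9)
  s2 <- abs(f2$Ix) > stats::quantile(abs(f2$Ix), 0.9)
  # a +y shift becomes a -x shift under the 90-degree rotation
  expect_equal(mean(f2$u_px[s2]), -mean(f1$v_px[s1]), tolerance = 0.02)
})

test_that("infinite smoothing drives the field towards a constant", {
  fa <- blob_image(0); fb <- blob_image(0.5)
  lo <- suppressWarnings(estimate_flow(fa, fb, ofm_config(dt = 1, lambda = 5e3,
                                                          max_iter = 300)))
  hi <- suppressWarnings(estimate_flow(fa, fb, ofm_config(dt = 1, lambda = 5e8,
                                                          max_iter = 300)))
  expect_lt(stats::var(as.vector(hi$v)), 1e-3 * stats::var(as.vector(lo$v)))
  expect_lt(stats::var(as.vector(hi$u)), 1e-3 * stats::var(as.vector(lo$u)) + 1e-20)
})

test_that("recovery error grows with displacement beyond one pixel", {
  # sharp blob (sigma 2 px) so the linearised constraint degrades past 1 px
  oc <- ofm_config(dt = 1, lambda = 5000, max_iter = 400, tol = 1e-7)
  err <- sapply(c(0.5, 1.25, 1.75, 2.5), function(s) {
    fa <- blob_image(0, sigma = 2)
    fb <- blob_image(s, sigma = 2)
    fl <- suppressWarnings(estimate_flow(fa, fb, oc))
    sel <- abs(fl$Iy) > stats::quantile(abs(fl$Iy), 0.9)
    abs(mean(fl$v_px[sel]) - s) / s
  })
  expect_lt(err[1], err[2])
  expect_lt(err[2], err[3])
  expect_lt(err[3], err[4])
})

test_that("flow estimation validates frame shapes", {
  expect_error(estimate_flow(blob_image(0, w = 32, h = 32),
                             blob_image(0, w = 31, h = 32)),
               "shapes")
})

test_that("optical-flow fields persist to CSV with sidecars", {
  fl <- suppressWarnings(estimate_flow(blob_image(0, w = 16, h = 16),
                                       blob_image(0.4, w = 16, h = 16),
                                       ofm_config(dt = 1, max_iter = 50)))
  path <- file.path(withr::local_tempdir(), "pair.csv")
  write_ofm_field(fl, path, meta = list(t_a = 0, t_b = 0.02))
  df <- read.csv(path)
  expect_equal(nrow(df), 256)
  expect_named(df, c("pixel_i", "pixel_j", "x_m", "y_m",
                     "u_ofm", "v_ofm", "Ix", "Iy"))
  expect_equal(matrix(df$v_ofm, 16), fl$v, ignore_attr = TRUE)
})
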