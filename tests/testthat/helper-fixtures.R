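# Shared fixtures, memoized so expensive objects are built once per session.

.fixture_env <- new.env(parent = emptyenv())

get_fixtures <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_fixtures(seed)
  .fixture_env[[key]]
}

# Full default-configuration pipeline run (the scaled-down study
# conditions); shared by the acceptance tests.
get_default_run <- function() {
  if (is.null(.fixture_env$default_run))
    .fixture_env$default_run <- run_pipeline(default_pipeline_config(1),
                                             verbose = FALSE)
  .fixture_env$default_run
}

# Synthetic projective image containing a Gaussian dark blob; `shift_px`
# moves the blob along y (row axis of the duct), `blur` adds sigma^2
# growth in px^2 (heat-kernel evolution, amplitude rescaled accordingly).
blob_image <- function(shift_px = 0, w = 64, h = 64, sigma = 6, blur = 0,
                       depth = 200) {
  s2 <- sigma^2 + blur
  amp <- depth * sigma^2 / s2
  gray <- 255 - amp * exp(-((row(matrix(0, w, h)) - w / 2)^2 +
                            (col(matrix(0, w, h)) - h / 2 - shift_px)^2) / (2 * s2))
  cfg <- imaging_config(width = w, height = h)
  structure(list(gray = matrix(as.integer(floor(gray + 0.5)), w),
                 timestamp = 0,
                 mapping = image_mapping(duct_geometry(), cfg),
                 geometry = duct_geometry(), config = cfg),
            class = "projective_image")
}

# Exhaustive sub-pixel shift search maximizing cross-correlation between
# frame_a shifted along y and frame_b; independent oracle for the
# optical-flow translation tests.
xcorr_shift_oracle <- function(frame_a, frame_b, shifts = seq(0, 2, by = 0.05)) {
  ga <- frame_a$gray; gb <- frame_b$gray
  m <- ncol(ga)
  score <- sapply(shifts, function(s) {
    j0 <- floor(s); f <- s - j0
    cols <- (j0 + 2):m          # columns where A(c - s) is in range
    pred <- (1 - f) * ga[, cols - j0] + f * ga[, cols - j0 - 1]
    -mean((pred - gb[, cols])^2)
  })
  shifts[which.max(score)]
}

# Small synthetic sample table with a known linear feature-target map
# (optionally noisy); used for the regression-model contract tests.
linear_table <- function(n = 400, sigma = 0, seed = 42,
                         B = rbind(c(0.8, -0.1), c(0.2, 0.9),
                                   c(0.001, -0.002), c(-0.003, 0.001)),
                         intercept = c(0.001, 0.004)) {
  set.seed(seed)
  X <- cbind(u_ofm = rnorm(n, 0, 0.003), v_ofm = rnorm(n, 0.005, 0.002),
             Ix = rnorm(n, 0, 10), Iy = rnorm(n, 0, 10))
  Y <- cbind(X %*% B[, 1] + intercept[1], X %*% B[, 2] + intercept[2])
  if (sigma > 0) Y <- Y + matrix(rnorm(2 * n, 0, sigma), n)
  tab <- data.frame(pixel_i = rep(1:20, length.out = n),
                    pixel_j = rep(1:20, each = 20, length.out = n),
                    x = 0, y = 0,
                    u_ofm = X[, 1], v_ofm = X[, 2], Ix = X[, 3], Iy = X[, 4],
                    u_truth = Y[, 1], v_truth = Y[, 2],
                    pair_id = 1L, timestamp = 0,
                    split = rep(c("train", "test"), c(n - n %/% 5, n %/% 5)))
  class(tab) <- c("sample_table", class(tab))
  attr(tab, "B") <- B
  attr(tab, "intercept") <- intercept
  tab
}
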