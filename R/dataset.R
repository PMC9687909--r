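#' Dye-dominance mask
#'
#' Pixels with gray level at or below `threshold` (default 80) are taken
#' as dye-dominant; only those pixels become supervised-learning samples.
#'
#' @param image A `projective_image` (or gray matrix).
#' @param threshold Gray level in [0, 255].
#' @return Logical matrix, `TRUE` where gray <= threshold.
#' @export
dye_mask <- function(image, threshold = 80) {
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]", call. = FALSE)
  g <- if (inherits(image, "projective_image")) image$gray else image
  g <= threshold
}

#' Assemble supervised-learning samples from a scene
#'
#' Joins optical-flow features at dye-dominant pixels with center-plane
#' ground-truth velocities.  One record is produced per masked pixel per
#' image pair; ground truth is sampled at the pixel's physical (x, y) by
#' bilinear interpolation of the center-plane slices.
#'
#' @param truth Center-plane ground truth as returned by
#'   [center_plane_truth()] (list with `x`, `y`, `u`, `v`).
#' @param ofm_fields List of `ofm_field`s, one per image pair.
#' @param masks List of logical masks, one per pair (same shape as the
#'   fields).
#' @param pair_times Optional numeric vector of pair timestamps.
#' @param threshold Mask threshold recorded as provenance.
#' @return Object of class `sample_table`: a `data.frame` with columns
#'   pixel_i, pixel_j, x, y, u_ofm, v_ofm, Ix, Iy, u_truth, v_truth,
#'   pair_id, timestamp, plus provenance attributes.
#' @export
assemble_samples <- function(truth, ofm_fields, masks,
                             pair_times = NULL, threshold = 80) {
  if (length(ofm_fields) != length(masks))
    stop("need one mask per optical-flow field", call. = FALSE)
  if (is.null(truth$u) || is.null(truth$v))
    stop("ground-truth center-plane slice missing", call. = FALSE)
  recs <- vector("list", length(ofm_fields))
  for (p in seq_along(ofm_fields)) {
    fld <- ofm_fields[[p]]
    msk <- masks[[p]]
    if (!identical(dim(msk), dim(fld$u)))
      stop("mask and field shapes differ", call. = FALSE)
    sel <- which(msk)
    if (!length(sel)) { recs[[p]] <- NULL; next }
    nx <- nrow(fld$u)
    pi_ <- ((sel - 1L) %% nx) + 1L
    pj <- ((sel - 1L) %/% nx) + 1L
    xs <- fld$mapping$x[pi_]
    ys <- fld$mapping$y[pj]
    ut <- .interp_points(truth$x, truth$y, truth$u, xs, ys)
    vt <- .interp_points(truth$x, truth$y, truth$v, xs, ys)
    recs[[p]] <- data.frame(
      pixel_i = pi_, pixel_j = pj, x = xs, y = ys,
      u_ofm = fld$u[sel], v_ofm = fld$v[sel],
      Ix = fld$Ix[sel], Iy = fld$Iy[sel],
      u_truth = ut, v_truth = vt,
      pair_id = p,
      timestamp = if (is.null(pair_times)) NA_real_ else pair_times[p])
  }
  tab <- do.call(rbind, recs)
  if (is.null(tab)) tab <- data.frame()
  attr(tab, "threshold") <- threshold
  class(tab) <- c("sample_table", class(tab))
  tab
}

# bilinear interpolation at scattered points (clamped at the hull)
.interp_points <- function(xg, yg, f, xi, yi) {
  ix <- findInterval(xi, xg, all.inside = TRUE)
  iy <- findInterval(yi, yg, all.inside = TRUE)
  fx <- pmin(pmax((xi - xg[ix]) / (xg[ix + 1] - xg[ix]), 0), 1)
  fy <- pmin(pmax((yi - yg[iy]) / (yg[iy + 1] - yg[iy]), 0), 1)
  n <- nrow(f)
  idx <- function(i, j) i + (j - 1) * n
  (1 - fx) * (1 - fy) * f[idx(ix, iy)] + fx * (1 - fy) * f[idx(ix + 1, iy)] +
    (1 - fx) * fy * f[idx(ix, iy + 1)] + fx * fy * f[idx(ix + 1, iy + 1)]
}

#' Duplicate-coordinate train/test split
#'
#' Multiple records share a pixel coordinate when several time instances
#' contain dye there.  For every coordinate key with multiplicity m >= 2,
#' exactly one record (chosen uniformly) goes to the test set and the
#' remaining m - 1 to training; singleton keys go to training (or are
#' dropped, per `singletons`).  Keys are exact pixel indices (i, j), which
#' makes "same coordinates" well defined on the fixed pixel grid.
#'
#' @param table A `sample_table`.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param singletons `"train"` (default) or `"drop"`.
#' @return The table with an added `split` column ("train"/"test").
#' @export
split_by_duplicates <- function(table, seed = 1L, singletons = c("train", "drop")) {
  singletons <- match.arg(singletons)
  if (!nrow(table)) stop("sample table is empty", call. = FALSE)
  key <- paste(table$pixel_i, table$pixel_j, sep = ":")
  lab <- rep("train", nrow(table))
  rng <- .seeded_rng(seed)
  groups <- split(seq_len(nrow(table)), key)
  # deterministic order independent of hash/locale quirks
  groups <- groups[order(names(groups))]
  m <- lengths(groups)
  draws <- rng$rnorm(length(groups))  # one uniform-ish draw per key
  pick <- 1L + (floor(stats::pnorm(draws) * m) %% m)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (m[g] >= 2L) {
      lab[idx[pick[g]]] <- "test"
    } else if (singletons == "drop") {
      lab[idx] <- "drop"
    }
  }
  if (singletons == "drop") {
    keep <- lab != "drop"
    table <- table[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  table$split <- lab
  attr(table, "split_seed") <- seed
  table
}

#' Standardize features on training statistics
#'
#' Computes per-column mean and standard deviation on the training rows of
#' the four features (and two targets) and returns a scaler applied before
#' model fitting; predictions are mapped back through the inverse target
#' transform.  Zero-variance columns are guarded (sd clamped to 1).
#'
#' @param table A split `sample_table`.
#' @return List with `x_center`, `x_scale`, `y_center`, `y_scale` and
#'   helper closures `scale_x`, `scale_y`, `unscale_y`.
#' @export
feature_scaler <- function(table) {
  tr <- table[table$split == "train", , drop = FALSE]
  X <- as.matrix(tr[, c("u_ofm", "v_ofm", "Ix", "Iy")])
  Y <- as.matrix(tr[, c("u_truth", "v_truth")])
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd)
  yc <- colMeans(Y); ys <- apply(Y, 2, stats::sd)
  xs[!is.finite(xs) | xs < 1e-12] <- 1
  # a degenerate (constant) target column inherits the pooled target
  # scale, so model errors on it stay on the problem's velocity scale
  pooled <- stats::sd(as.vector(Y))
  ys[!is.finite(ys) | ys < 1e-12] <- if (is.finite(pooled) && pooled > 1e-12) pooled else 1
  list(x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
       scale_x = function(X) sweep(sweep(X, 2, xc), 2, xs, "/"),
       scale_y = function(Y) sweep(sweep(Y, 2, yc), 2, ys, "/"),
       unscale_y = function(Y) sweep(sweep(Y, 2, ys, "*"), 2, yc, "+"))
}

#' Persist a sample table as CSV with a JSON sidecar
#'
#' @param table A `sample_table`.
#' @param path Output CSV path.
#' @param meta Extra sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path, meta = list()) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  side <- c(list(n = nrow(table),
                 threshold = attr(table, "threshold"),
                 split_seed = attr(table, "split_seed"),
                 n_train = sum(table$split == "train"),
                 n_test = sum(table$split == "test")), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sample table written by [write_sample_table()]
#'
#' @param path CSV path.
#' @return A `sample_table`.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.csv(path)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    attr(tab, "threshold") <- meta$threshold
    attr(tab, "split_seed") <- meta$split_seed
  }
  class(tab) <- c("sample_table", class(tab))
  tab
}
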