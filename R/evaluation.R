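#' Mean absolute error
#'
#' `MAE = mean(|p - g|)` over all elements (both velocity components are
#' pooled when matrices are supplied).
#'
#' @param pred,truth Numeric vectors or matrices of equal size.
#' @return MAE in the units of the inputs (m/s for velocities).
#' @export
mae <- function(pred, truth) {
  if (!length(pred) || length(pred) != length(truth))
    stop("pred and truth must be non-empty and of equal length", call. = FALSE)
  mean(abs(pred - truth))
}

#' Mean squared error
#'
#' `MSE = mean((p - g)^2)`.
#'
#' @inheritParams mae
#' @return MSE in squared input units.
#' @export
mse <- function(pred, truth) {
  if (!length(pred) || length(pred) != length(truth))
    stop("pred and truth must be non-empty and of equal length", call. = FALSE)
  mean((pred - truth)^2)
}

#' Default streamwise evaluation stations
#'
#' The nine Y locations (m) at which velocity profiles and percentage
#' errors are reported.
#'
#' @return Numeric vector of station coordinates in metres.
#' @export
default_stations <- function() {
  c(0.00083, 0.00166, 0.00332, 0.00498, 0.00664,
    0.00830, 0.00996, 0.01162, 0.01328)
}

#' Per-station percentage-error profile of the v-velocity
#'
#' For each station y, the error is computed with definition D1
#' (station-wise relative L1):
#' `100 * mean_x |v_est - v_truth| / mean_x |v_truth|`,
#' where the mean runs over the masked (dye-dominant) pixels of the
#' station row.  Stations whose truth magnitude vanishes are skipped with
#' a warning.  Alternative definitions are available: `"pointwise"`
#' (mean of pointwise 100|dv|/|v|) and `"max"` (normalisation by the
#' station max |v_truth|).
#'
#' @param v_est Matrix of estimated v (nx x ny grid, m/s); `NA` entries
#'   are treated as unmasked.
#' @param v_truth Matrix of ground-truth v on the same grid.
#' @param y Grid y-coordinates (length ny), m.
#' @param stations Station y-locations, m (default [default_stations()]).
#' @param definition `"D1"` (default), `"pointwise"`, or `"max"`.
#' @return Object of class `error_profile`: data.frame with `y_station`
#'   and `error_pct`.
#' @export
v_error_profile <- function(v_est, v_truth, y,
                            stations = default_stations(),
                            definition = c("D1", "pointwise", "max")) {
  definition <- match.arg(definition)
  if (any(stations < min(y) - (y[2] - y[1]) | stations > max(y) + (y[2] - y[1])))
    stop("stations outside the field extent", call. = FALSE)
  err <- rep(NA_real_, length(stations))
  for (s in seq_along(stations)) {
    j <- which.min(abs(y - stations[s]))
    est <- v_est[, j]; tru <- v_truth[, j]
    keep <- is.finite(est) & is.finite(tru)
    est <- est[keep]; tru <- tru[keep]
    if (!length(est) || mean(abs(tru)) == 0) {
      warning(sprintf("station y = %g skipped (no mask coverage or zero truth)",
                      stations[s]))
      next
    }
    err[s] <- switch(definition,
      D1 = 100 * mean(abs(est - tru)) / mean(abs(tru)),
      pointwise = 100 * mean(abs(est - tru) / abs(tru)),
      max = 100 * mean(abs(est - tru)) / max(abs(tru)))
  }
  out <- data.frame(y_station = stations, error_pct = err)
  class(out) <- c("error_profile", class(out))
  out
}

#' Extract a velocity profile along a horizontal line
#'
#' Bilinear interpolation of the (u, v) field at streamwise position `y`.
#'
#' @param field List with `x`, `y` coordinate vectors and `u`, `v`
#'   matrices (length(x) x length(y)).
#' @param y Station in metres (must lie within the field extent).
#' @return data.frame with columns `x`, `u`, `v`.
#' @export
extract_profile <- function(field, y) {
  if (y < min(field$y) || y > max(field$y))
    stop("y outside the field extent", call. = FALSE)
  j <- findInterval(y, field$y, all.inside = TRUE)
  f <- (y - field$y[j]) / (field$y[j + 1] - field$y[j])
  f <- min(max(f, 0), 1)
  data.frame(x = field$x,
             u = (1 - f) * field$u[, j] + f * field$u[, j + 1],
             v = (1 - f) * field$v[, j] + f * field$v[, j + 1])
}

#' Aggregate per-pixel fields from sample records
#'
#' Averages record values per pixel over all pairs in which the pixel was
#' masked, yielding center-plane comparison fields for OFM, model
#' predictions, and ground truth on the image pixel grid.
#'
#' @param table A `sample_table`.
#' @param value Numeric vector aligned with the table rows (e.g. v_ofm or
#'   a model prediction).
#' @param dims Image dimensions c(width, height).
#' @param mapping Image mapping (for the returned coordinates).
#' @return List with `x`, `y`, and matrix `field` (NA where never masked).
#' @export
pixel_field <- function(table, value, dims, mapping) {
  acc <- matrix(0, dims[1], dims[2])
  cnt <- matrix(0L, dims[1], dims[2])
  idx <- cbind(table$pixel_i, table$pixel_j)
  for (r in seq_len(nrow(table))) {
    acc[idx[r, 1], idx[r, 2]] <- acc[idx[r, 1], idx[r, 2]] + value[r]
    cnt[idx[r, 1], idx[r, 2]] <- cnt[idx[r, 1], idx[r, 2]] + 1L
  }
  fld <- acc / cnt
  fld[cnt == 0L] <- NA_real_
  list(x = mapping$x, y = mapping$y, field = fld)
}

#' Summarize a full run
#'
#' Builds the model-by-loss metric grid, the OFM-versus-model error
#' reduction summary, and paired t-tests of fold MAEs against the LASSO
#' baseline.
#'
#' @param cv_results Named list of `cv_scores` (one per model/loss
#'   combination, names like "mlp/mae").
#' @param ofm_error Average OFM v-error (percent), optional.
#' @param model_error Average corrected v-error (percent), optional.
#' @return Object of class `run_summary` with elements `grid` (data.frame
#'   model, loss, mean_mae, sd_mae, mean_mse, sd_mse, p_vs_lasso) and the
#'   error summary.
#' @export
summarize_run <- function(cv_results, ofm_error = NA_real_,
                          model_error = NA_real_) {
  rows <- lapply(names(cv_results), function(nm) {
    cv <- cv_results[[nm]]
    data.frame(model = attr(cv, "kind"), loss = attr(cv, "loss"),
               mean_mae = attr(cv, "mean_mae"), sd_mae = attr(cv, "sd_mae"),
               mean_mse = attr(cv, "mean_mse"), sd_mse = attr(cv, "sd_mse"))
  })
  grid <- do.call(rbind, rows)
  grid$p_vs_lasso <- NA_real_
  for (i in seq_len(nrow(grid))) {
    if (grid$model[i] == "lasso") next
    base_nm <- paste0("lasso/", grid$loss[i])
    if (!base_nm %in% names(cv_results)) next
    a <- cv_results[[paste0(grid$model[i], "/", grid$loss[i])]]$mae
    b <- cv_results[[base_nm]]$mae
    if (length(a) == length(b) && length(a) > 1 && stats::sd(a - b) > 0)
      grid$p_vs_lasso[i] <- stats::t.test(a, b, paired = TRUE)$p.value
  }
  structure(list(grid = grid, ofm_error_pct = ofm_error,
                 model_error_pct = model_error,
                 error_reduction = ofm_error / model_error),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Model performance (cross-validated):\n")
  print(format(x$grid, digits = 4), row.names = FALSE)
  if (is.finite(x$ofm_error_pct))
    cat(sprintf("\nAverage v-error: OFM %.1f%% -> corrected %.1f%% (x%.1f reduction)\n",
                x$ofm_error_pct, x$model_error_pct, x$error_reduction))
  invisible(x)
}
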