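#' Default pipeline configuration
#'
#' A single structured configuration drives every stage: scene generation,
#' projection, optical flow, dataset assembly, model training and
#' evaluation.  The default schedule exports image pairs every 0.2 s
#' (cases 1-2) or 0.3 s (cases 3-4) with companions 0.02 s later, giving
#' 106 snapshots and 53 optical-flow pairs across the four injection
#' cases.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scene = list(nx = 64L, ny = 128L, nz = 64L, quarter = TRUE,
                 dt_sim = 0.02, bulk_velocity = 0.005, diffusivity = 1e-9,
                 side_length = 0.0254, duct_length = 0.0254),
    cases = list(
      list(case_id = 1L, duration = 2.9, export_interval = 0.2),
      list(case_id = 2L, duration = 2.7, export_interval = 0.2),
      list(case_id = 3L, duration = 4.0, export_interval = 0.3),
      list(case_id = 4L, duration = 4.0, export_interval = 0.3)),
    imaging = list(width = 161L, height = 306L, noise_sd = 0),
    ofm = list(dt = 0.02, lambda = 5000, max_iter = 500, tol = 1e-6),
    dataset = list(threshold = 80, singletons = "train"),
    models = list(
      list(kind = "lasso"), list(kind = "mlp"),
      list(kind = "cnn"), list(kind = "lstm")),
    train = list(loss = "mae", cv_k = 10L, cv_repeats = 3L,
                 cv_max_n = 4000L, fit_max_n = 12000L,
                 epochs_mlp = 100L, epochs_deep = 500L),
    evaluation = list(definition = "D1")
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return The configuration (read) or `path` (write).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  merged <- utils::modifyList(base, cfg)
  class(merged) <- "pipeline_config"
  merged
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stable short hash of a configuration (provenance sidecars)
.config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 3)
  s1 <- 1; s2 <- 0
  v <- as.integer(raw)
  # Adler-32 style rolling checksum, chunked for speed
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    cs <- cumsum(chunk)
    s2 <- (s2 + length(chunk) * s1 + sum(cs %% 65521)) %% 65521
    s1 <- (s1 + cs[length(cs)]) %% 65521
  }
  sprintf("%04x%04x", s2, s1)
}

.scene_config_from <- function(config) {
  scene_config(
    geometry = duct_geometry(config$scene$side_length,
                             config$scene$duct_length),
    bulk_velocity = config$scene$bulk_velocity,
    diffusivity = config$scene$diffusivity,
    nx = config$scene$nx, ny = config$scene$ny, nz = config$scene$nz,
    dt_sim = config$scene$dt_sim, quarter = config$scene$quarter)
}

.imaging_config_from <- function(config) {
  imaging_config(width = config$imaging$width, height = config$imaging$height,
                 noise_sd = config$imaging$noise_sd,
                 noise_seed = config$seed)
}

.ofm_config_from <- function(config) {
  ofm_config(dt = config$ofm$dt, D = config$scene$diffusivity,
             lambda = config$ofm$lambda, max_iter = config$ofm$max_iter,
             tol = config$ofm$tol)
}

.model_configs_from <- function(config, loss = NULL) {
  loss <- if (is.null(loss)) config$train$loss else loss
  lapply(config$models, function(m) {
    kind <- m$kind
    epochs <- if (kind == "mlp") config$train$epochs_mlp else config$train$epochs_deep
    model_config(kind, loss = loss, epochs = epochs,
                 seed = config$seed + match(kind, c("lasso", "mlp", "cnn", "lstm")))
  })
}

#' Run the full pipeline in memory
#'
#' Simulates the four injection cases, renders the projection-image
#' pairs, estimates optical flow, assembles and splits the sample table,
#' cross-validates the four regressors, fits final models on the training
#' split, and computes the per-station v-error profiles for raw OFM and
#' the MLP correction.
#'
#' @param config A `pipeline_config`.
#' @param verbose Print per-stage progress.
#' @return List with `table`, `cv` (named list of `cv_scores`), `models`,
#'   `profiles` (OFM and MLP `error_profile`s), `fields` (aggregated
#'   test-pixel fields), `summary` (a `run_summary`), and stage metadata.
#' @export
run_pipeline <- function(config = default_pipeline_config(), verbose = TRUE) {
  t0 <- Sys.time()
  sc <- .scene_config_from(config)
  ic <- .imaging_config_from(config)
  oc <- .ofm_config_from(config)
  say <- function(...) if (verbose) message(sprintf(...))

  all_fields <- list(); all_masks <- list(); all_times <- list()
  truth <- NULL
  n_snapshots <- 0L
  for (case in config$cases) {
    tc <- Sys.time()
    seq_ <- run_case(case$case_id, sc, case$duration, case$export_interval)
    truth <- seq_$truth
    n_snapshots <- n_snapshots + length(seq_$snapshots)
    for (p in seq_len(nrow(seq_$pairs))) {
      ia <- seq_$pairs[p, 1]; ib <- seq_$pairs[p, 2]
      fa <- render_projection(seq_$snapshots[[ia]]$volume, sc$geometry, ic)
      fb <- render_projection(seq_$snapshots[[ib]]$volume, sc$geometry, ic)
      fld <- suppressWarnings(estimate_flow(fa, fb, oc))
      all_fields[[length(all_fields) + 1L]] <- fld
      all_masks[[length(all_masks) + 1L]] <- dye_mask(fa, config$dataset$threshold)
      all_times[[length(all_times) + 1L]] <- fa$timestamp
    }
    say("case %d: %d pairs [%.1fs]", case$case_id, nrow(seq_$pairs),
        as.numeric(difftime(Sys.time(), tc, units = "secs")))
  }

  table <- assemble_samples(truth, all_fields, all_masks,
                            pair_times = unlist(all_times),
                            threshold = config$dataset$threshold)
  table <- split_by_duplicates(table, seed = config$seed,
                               singletons = config$dataset$singletons)
  say("samples: %d records (%d train / %d test) from %d pairs, %d snapshots",
      nrow(table), sum(table$split == "train"), sum(table$split == "test"),
      length(all_fields), n_snapshots)

  # cross-validation (optionally on a seeded subsample, the desk-scale
  # problem size)
  cv_tab <- table
  if (nrow(cv_tab) > config$train$cv_max_n) {
    rng <- .seeded_rng(config$seed + 97L)
    keep <- order(rng$rnorm(nrow(cv_tab)))[seq_len(config$train$cv_max_n)]
    cv_tab <- cv_tab[sort(keep), , drop = FALSE]
  }
  # final fits use the training split, capped at the configured size
  fit_tab <- table[table$split == "train", , drop = FALSE]
  if (!is.null(config$train$fit_max_n) &&
      nrow(fit_tab) > config$train$fit_max_n) {
    rng <- .seeded_rng(config$seed + 131L)
    keep <- order(rng$rnorm(nrow(fit_tab)))[seq_len(config$train$fit_max_n)]
    fit_tab <- fit_tab[sort(keep), , drop = FALSE]
  }
  cv <- list()
  models <- list()
  for (mc in .model_configs_from(config)) {
    tm <- Sys.time()
    cv[[paste0(mc$kind, "/", mc$loss)]] <-
      cross_validate(mc, cv_tab, k = config$train$cv_k,
                     repeats = config$train$cv_repeats,
                     seed = config$seed + 11L)
    models[[mc$kind]] <- fit_model(fit_tab, mc)
    say("model %s: cv mean MAE %.3g [%.1fs]", mc$kind,
        attr(cv[[paste0(mc$kind, "/", mc$loss)]], "mean_mae"),
        as.numeric(difftime(Sys.time(), tm, units = "secs")))
  }

  # per-station v-error profiles on the held-out (test) records
  te <- table[table$split == "test", , drop = FALSE]
  dims <- c(ic$width, ic$height)
  map <- image_mapping(sc$geometry, ic)
  pred_mlp <- predict(models$mlp, te)
  f_ofm <- pixel_field(te, te$v_ofm, dims, map)
  f_mlp <- pixel_field(te, pred_mlp[, "v"], dims, map)
  f_tru <- pixel_field(te, te$v_truth, dims, map)
  stations <- default_stations()
  prof_ofm <- v_error_profile(f_ofm$field, f_tru$field, map$y, stations,
                              definition = config$evaluation$definition)
  prof_mlp <- v_error_profile(f_mlp$field, f_tru$field, map$y, stations,
                              definition = config$evaluation$definition)
  summary <- summarize_run(cv,
                           ofm_error = mean(prof_ofm$error_pct, na.rm = TRUE),
                           model_error = mean(prof_mlp$error_pct, na.rm = TRUE))
  say("avg v-error: OFM %.1f%%, MLP %.1f%% [total %.1fs]",
      summary$ofm_error_pct, summary$model_error_pct,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(table = table, cv = cv, models = models,
       profiles = list(ofm = prof_ofm, mlp = prof_mlp),
       fields = list(ofm = f_ofm, mlp = f_mlp, truth = f_tru),
       summary = summary, truth = truth,
       n_snapshots = n_snapshots, n_pairs = length(all_fields),
       config = config, mapping = map)
}

# ---- file-based stage commands -------------------------------------------

.write_sidecar <- function(dir, config, stage, extra = list()) {
  jsonlite::write_json(c(list(stage = stage, config_hash = .config_hash(config),
                              seed = config$seed, version = "0.1.0"),
                         extra),
                       file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
}

.check_sidecar <- function(dir, config, force = FALSE) {
  p <- file.path(dir, "sidecar.json")
  if (!file.exists(p)) stop("missing sidecar in ", dir, call. = FALSE)
  sc <- jsonlite::read_json(p)
  if (!force && !identical(sc$config_hash, .config_hash(config)))
    stop("stage outputs in ", dir,
         " were produced with a different configuration (use force to override)",
         call. = FALSE)
  invisible(sc)
}

#' Pipeline stage commands
#'
#' File-based stage drivers mirroring the in-memory [run_pipeline()]:
#' `af_simulate` writes scene sequences, `af_project` projection images
#' (PNG), `af_ofm` optical-flow tables (CSV), `af_build` the sample
#' table, `af_train` fitted models and the CV report, and `af_evaluate`
#' the evaluation report.  Every stage directory carries a JSON sidecar
#' with the configuration hash and seed; stages refuse to consume
#' outputs from a different configuration unless `force = TRUE`.
#' `af_run_all` chains all stages (skipping completed ones when
#' `resume = TRUE`).
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory root.
#' @param force Accept inputs with a mismatching configuration hash.
#' @param resume Skip stages whose outputs already exist with a matching
#'   hash.
#' @return The output directory, invisibly.
#' @export
af_simulate <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- .scene_config_from(config)
  for (case in config$cases) {
    seq_ <- run_case(case$case_id, sc, case$duration, case$export_interval)
    saveRDS(seq_, file.path(outdir, sprintf("case%d.rds", case$case_id)))
  }
  .write_sidecar(outdir, config, "simulate",
                 list(n_cases = length(config$cases)))
  invisible(outdir)
}

#' @rdname af_simulate
#' @param scenes_dir Directory written by `af_simulate`.
#' @export
af_project <- function(config, scenes_dir, outdir, force = FALSE) {
  .check_sidecar(scenes_dir, config, force)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- .scene_config_from(config)
  ic <- .imaging_config_from(config)
  n <- 0L
  for (case in config$cases) {
    seq_ <- readRDS(file.path(scenes_dir, sprintf("case%d.rds", case$case_id)))
    for (i in seq_along(seq_$snapshots)) {
      img <- render_projection(seq_$snapshots[[i]]$volume, sc$geometry, ic)
      write_projection(img, file.path(outdir,
        sprintf("case%d_%03d.png", case$case_id, i)),
        meta = list(case_id = case$case_id, index = i))
      n <- n + 1L
    }
  }
  .write_sidecar(outdir, config, "project", list(n_images = n))
  invisible(outdir)
}

#' @rdname af_simulate
#' @param images_dir Directory written by `af_project`.
#' @export
af_ofm <- function(config, images_dir, outdir, force = FALSE) {
  .check_sidecar(images_dir, config, force)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- .scene_config_from(config)
  oc <- .ofm_config_from(config)
  files <- sort(list.files(images_dir, pattern = "^case[0-9]+_[0-9]+\\.png$",
                           full.names = TRUE))
  cases <- sub("^case([0-9]+)_.*$", "\\1", basename(files))
  for (cs in unique(cases)) {
    cf <- files[cases == cs]
    if (length(cf) %% 2L != 0L)
      stop("odd number of images for case ", cs, "; orphan frame: ",
           basename(cf[length(cf)]), call. = FALSE)
    for (p in seq_len(length(cf) %/% 2L)) {
      fa <- read_projection(cf[2 * p - 1], sc$geometry)
      fb <- read_projection(cf[2 * p], sc$geometry)
      fld <- suppressWarnings(estimate_flow(fa, fb, oc))
      write_ofm_field(fld, file.path(outdir, sprintf("case%s_pair%03d.csv", cs, p)),
                      meta = list(t_a = fa$timestamp, t_b = fb$timestamp))
    }
  }
  .write_sidecar(outdir, config, "ofm")
  invisible(outdir)
}

#' @rdname af_simulate
#' @param ofm_dir Directory written by `af_ofm`.
#' @export
af_build <- function(config, ofm_dir, scenes_dir, outdir, force = FALSE) {
  .check_sidecar(ofm_dir, config, force)
  .check_sidecar(scenes_dir, config, force)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- .scene_config_from(config)
  ic <- .imaging_config_from(config)
  map <- image_mapping(sc$geometry, ic)
  truth <- center_plane_truth(sc)
  files <- sort(list.files(ofm_dir, pattern = "\\.csv$", full.names = TRUE))
  fields <- list(); masks <- list(); times <- numeric(0)
  for (f in files) {
    df <- utils::read.csv(f)
    nx <- max(df$pixel_i); ny <- max(df$pixel_j)
    fld <- list(u = matrix(df$u_ofm, nx, ny), v = matrix(df$v_ofm, nx, ny),
                Ix = matrix(df$Ix, nx, ny), Iy = matrix(df$Iy, nx, ny),
                mapping = map)
    class(fld) <- "ofm_field"
    # reconstruct the mask from the first frame of the pair
    sidecar <- jsonlite::read_json(paste0(f, ".json"))
    case_pair <- sub("\\.csv$", "", basename(f))
    img_idx <- 2L * as.integer(sub(".*pair0*([0-9]+)$", "\\1", case_pair)) - 1L
    cs <- sub("^case([0-9]+)_.*$", "\\1", case_pair)
    img <- read_projection(file.path(dirname(ofm_dir), "images",
      sprintf("case%s_%03d.png", cs, img_idx)), sc$geometry)
    fields[[length(fields) + 1L]] <- fld
    masks[[length(masks) + 1L]] <- dye_mask(img, config$dataset$threshold)
    times <- c(times, as.numeric(sidecar$t_a))
  }
  tab <- assemble_samples(truth, fields, masks, pair_times = times,
                          threshold = config$dataset$threshold)
  tab <- split_by_duplicates(tab, seed = config$seed,
                             singletons = config$dataset$singletons)
  write_sample_table(tab, file.path(outdir, "samples.csv"))
  .write_sidecar(outdir, config, "build", list(n = nrow(tab)))
  invisible(outdir)
}

#' @rdname af_simulate
#' @param samples_dir Directory written by `af_build`.
#' @export
af_train <- function(config, samples_dir, outdir, force = FALSE) {
  .check_sidecar(samples_dir, config, force)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tab <- read_sample_table(file.path(samples_dir, "samples.csv"))
  rows <- list()
  for (mc in .model_configs_from(config)) {
    cv <- cross_validate(mc, tab, k = config$train$cv_k,
                         repeats = config$train$cv_repeats,
                         seed = config$seed + 11L)
    mod <- fit_model(tab, mc)
    save_model(mod, file.path(outdir, paste0(mc$kind, ".rds")))
    rows[[length(rows) + 1L]] <- cbind(model = mc$kind, loss = mc$loss,
                                       as.data.frame(cv))
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(outdir, "cv_report.csv"), row.names = FALSE)
  .write_sidecar(outdir, config, "train")
  invisible(outdir)
}

#' @rdname af_simulate
#' @param models_dir Directory written by `af_train`.
#' @export
af_evaluate <- function(config, models_dir, samples_dir, outdir, force = FALSE) {
  .check_sidecar(models_dir, config, force)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- .scene_config_from(config)
  ic <- .imaging_config_from(config)
  map <- image_mapping(sc$geometry, ic)
  tab <- read_sample_table(file.path(samples_dir, "samples.csv"))
  te <- tab[tab$split == "test", , drop = FALSE]
  mlp <- load_model(file.path(models_dir, "mlp.rds"))
  pred <- predict(mlp, te)
  dims <- c(ic$width, ic$height)
  f_ofm <- pixel_field(te, te$v_ofm, dims, map)
  f_mlp <- pixel_field(te, pred[, "v"], dims, map)
  f_tru <- pixel_field(te, te$v_truth, dims, map)
  prof_ofm <- v_error_profile(f_ofm$field, f_tru$field, map$y)
  prof_mlp <- v_error_profile(f_mlp$field, f_tru$field, map$y)
  utils::write.csv(data.frame(y_station = prof_ofm$y_station,
                              ofm_error_pct = prof_ofm$error_pct,
                              mlp_error_pct = prof_mlp$error_pct),
                   file.path(outdir, "error_profile.csv"), row.names = FALSE)
  # contour-ready center-plane export
  keep <- which(is.finite(f_tru$field), arr.ind = TRUE)
  utils::write.csv(data.frame(x = map$x[keep[, 1]], y = map$y[keep[, 2]],
                              v_ofm = f_ofm$field[keep],
                              v_mlp = f_mlp$field[keep],
                              v_truth = f_tru$field[keep]),
                   file.path(outdir, "center_plane_fields.csv"),
                   row.names = FALSE)
  .write_sidecar(outdir, config, "evaluate",
                 list(ofm_error = mean(prof_ofm$error_pct, na.rm = TRUE),
                      mlp_error = mean(prof_mlp$error_pct, na.rm = TRUE)))
  invisible(outdir)
}

#' @rdname af_simulate
#' @export
af_run_all <- function(config, outdir, resume = FALSE, force = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(dir, fun) {
    d <- file.path(outdir, dir)
    done <- resume && file.exists(file.path(d, "sidecar.json")) &&
      tryCatch({ .check_sidecar(d, config, force); TRUE },
               error = function(e) FALSE)
    if (!done) fun(d)
    d
  }
  scenes <- stage("scenes", function(d) af_simulate(config, d))
  images <- stage("images", function(d) af_project(config, scenes, d, force))
  ofm <- stage("ofm", function(d) af_ofm(config, images, d, force))
  samples <- stage("samples", function(d) af_build(config, ofm, scenes, d, force))
  models <- stage("models", function(d) af_train(config, samples, d, force))
  stage("report", function(d) af_evaluate(config, models, samples, d, force))
  invisible(outdir)
}

#' Miniature end-to-end fixture set
#'
#' Builds a coarse-grid, short-duration configuration covering all four
#' injection cases (a few seconds end to end) and runs the scene,
#' projection, optical-flow and dataset stages.  Used by the test suite
#' for fast integration checks.  Asserts the projector calibration: every
#' case yields a non-empty dye mask and at least one image pair.
#'
#' @param seed Integer seed.
#' @return List with `config`, `table`, `fields`, `masks`, `truth`, and
#'   per-case pair counts.
#' @export
make_fixtures <- function(seed = 1L) {
  cfg <- default_pipeline_config(seed)
  cfg$scene$nx <- 32L; cfg$scene$ny <- 64L; cfg$scene$nz <- 32L
  cfg$imaging$width <- 61L; cfg$imaging$height <- 117L
  cfg$cases <- list(
    list(case_id = 1L, duration = 0.92, export_interval = 0.3),
    list(case_id = 2L, duration = 0.92, export_interval = 0.3),
    list(case_id = 3L, duration = 0.92, export_interval = 0.3),
    list(case_id = 4L, duration = 0.92, export_interval = 0.3))
  cfg$ofm$max_iter <- 200L
  cfg$train$epochs_mlp <- 30L
  cfg$train$epochs_deep <- 60L
  cfg$train$cv_k <- 5L
  cfg$train$cv_repeats <- 1L
  cfg$train$cv_max_n <- 4000L

  sc <- .scene_config_from(cfg)
  ic <- .imaging_config_from(cfg)
  oc <- .ofm_config_from(cfg)
  fields <- list(); masks <- list(); times <- numeric(0)
  pairs_per_case <- integer(0)
  truth <- NULL
  for (case in cfg$cases) {
    seq_ <- run_case(case$case_id, sc, case$duration, case$export_interval)
    truth <- seq_$truth
    np <- nrow(seq_$pairs)
    stopifnot(np >= 1)
    nonempty <- FALSE
    for (p in seq_len(np)) {
      fa <- render_projection(seq_$snapshots[[seq_$pairs[p, 1]]]$volume,
                              sc$geometry, ic)
      fb <- render_projection(seq_$snapshots[[seq_$pairs[p, 2]]]$volume,
                              sc$geometry, ic)
      fld <- suppressWarnings(estimate_flow(fa, fb, oc))
      msk <- dye_mask(fa, cfg$dataset$threshold)
      nonempty <- nonempty || any(msk)
      fields[[length(fields) + 1L]] <- fld
      masks[[length(masks) + 1L]] <- msk
      times <- c(times, fa$timestamp)
    }
    stopifnot(nonempty)  # projector calibration: mask non-empty per case
    pairs_per_case <- c(pairs_per_case, np)
  }
  tab <- assemble_samples(truth, fields, masks, pair_times = times,
                          threshold = cfg$dataset$threshold)
  tab <- split_by_duplicates(tab, seed = seed)
  stopifnot(all(c("train", "test") %in% tab$split))
  list(config = cfg, table = tab, fields = fields, masks = masks,
       truth = truth, pairs_per_case = pairs_per_case,
       mapping = image_mapping(sc$geometry, ic),
       scene_config = sc, imaging_config = ic, ofm_config = oc)
}

#' Pair snapshots into optical-flow datasets
#'
#' The export schedule guarantees every interval snapshot a companion
#' 0.02 s later, so `n` snapshots yield `n / 2` analysis pairs.
#'
#' @param n_snapshots Total snapshot count (must be even).
#' @return Number of OFM data sets.
#' @export
pair_count <- function(n_snapshots) {
  if (n_snapshots %% 2L != 0L)
    stop("snapshots do not pair: odd count ", n_snapshots, call. = FALSE)
  n_snapshots %/% 2L
}
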