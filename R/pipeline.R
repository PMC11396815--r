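#' Pipeline configuration
#'
#' Bundles every stage's settings. In `"synthetic"` mode scenes come from
#' [generate_experiment()] (the scene seed is re-derived from the pipeline
#' seed so one top-level seed drives every stage); in `"ingest"` mode they
#' are read from `input_dir` (a directory written by [write_experiment()]).
#'
#' @param mode `"synthetic"` or `"ingest"`
#' @param scene a [scene_config()] (synthetic mode)
#' @param input_dir experiment directory (ingest mode)
#' @param vi_threshold NDVI canopy-mask threshold
#' @param glcm_levels gray-level count G for texture quantization
#' @param alpha Pearson screening level
#' @param train_fraction training fraction of the sample split
#' @param learners a [learner_config()]
#' @param combos input combinations (default [INPUT_COMBINATIONS])
#' @param models learners to evaluate
#' @param output_dir optional directory for feature tables, reports and the
#'   evaluation CSV
#' @param seed top-level integer seed; all stage seeds derive from it
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(mode = c("synthetic", "ingest"),
                            scene = scene_config(),
                            input_dir = NULL,
                            vi_threshold = 0.3,
                            glcm_levels = 32,
                            alpha = 0.01,
                            train_fraction = 2 / 3,
                            learners = learner_config(),
                            combos = INPUT_COMBINATIONS,
                            models = c("XGBoost", "RF", "GA-BP"),
                            output_dir = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "ingest" && is.null(input_dir))
    stop_config("input_dir", "is required in ingest mode")
  if (!is.null(input_dir) && !is.null(output_dir) &&
      normalizePath(input_dir, mustWork = FALSE) ==
      normalizePath(output_dir, mustWork = FALSE))
    stop_config("output_dir", "must differ from input_dir")
  if (mode == "synthetic") validate_scene_config(scene)
  if (vi_threshold < -1 || vi_threshold >= 1)
    stop_config("vi_threshold", "must lie in [-1, 1)")
  if (glcm_levels < 2) stop_config("glcm_levels", "must be at least 2")
  if (!(alpha > 0 && alpha <= 1)) stop_config("alpha", "must lie in (0, 1]")
  structure(list(mode = mode, scene = scene, input_dir = input_dir,
                 vi_threshold = vi_threshold, glcm_levels = glcm_levels,
                 alpha = alpha, train_fraction = train_fraction,
                 learners = learners, combos = combos, models = models,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Accepts the nested layout `mode`, `seed`, `input_dir`, `output_dir`,
#' `scene: {...}` (fields of [scene_config()]), `masking: {vi_threshold}`,
#' `glcm: {levels}`, `screening: {alpha}`, `split: {train_fraction}`,
#' `learners: {xgboost: {...}, random_forest: {...}, gabp: {...}}`,
#' `models: [...]`. Unknown fields raise an error.
#'
#' @param path YAML file
#' @param seed optional override of the file's seed
#' @return a [pipeline_config()]
#' @export
pipeline_config_from_yaml <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("mode", "seed", "input_dir", "output_dir", "scene", "masking",
             "glcm", "screening", "split", "learners", "models")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop_config(extra[1], "is not a recognised pipeline setting")
  sc <- if (!is.null(y[["scene"]])) {
    bad <- setdiff(names(y[["scene"]]), names(formals(scene_config)))
    if (length(bad)) stop_config(paste0("scene.", bad[1]), "is not recognised")
    do.call(scene_config, y[["scene"]])
  } else scene_config()
  lrn <- y[["learners"]]
  lc <- if (!is.null(lrn)) {
    args <- list()
    if (!is.null(lrn[["xgboost"]])) args$xgboost <- lrn[["xgboost"]]
    if (!is.null(lrn[["random_forest"]]))
      args$random_forest <- lrn[["random_forest"]]
    if (!is.null(lrn[["gabp"]]))
      args$gabp <- do.call(gabp_config, lrn[["gabp"]])
    do.call(learner_config, args)
  } else learner_config()
  pipeline_config(
    mode = y[["mode"]] %||% "synthetic",
    scene = sc,
    input_dir = y[["input_dir"]],
    vi_threshold = y[["masking"]][["vi_threshold"]] %||% 0.3,
    glcm_levels = y[["glcm"]][["levels"]] %||% 32,
    alpha = y[["screening"]][["alpha"]] %||% 0.01,
    train_fraction = y[["split"]][["train_fraction"]] %||% (2 / 3),
    learners = lc,
    models = unlist(y[["models"]]) %||% c("XGBoost", "RF", "GA-BP"),
    output_dir = y[["output_dir"]],
    seed = seed %||% (y[["seed"]] %||% 1L))
}

# Per-layer vegetation-index tables with NIR-band selection on the training
# rows only (avoids leaking validation SMC into the band choice).
vi_tables_for_layers <- function(refl, truth, tr_idx) {
  vi800 <- compute_vi_table(refl, nir_band = 800)
  vi900 <- compute_vi_table(refl, nir_band = 900)
  ids <- rownames(refl)
  tabs <- list(); sels <- list()
  for (ly in LAYER_NAMES) {
    smc <- truth[[LAYER_SMC_COLUMNS[[ly]]]]
    sel <- select_nir_band(vi800[tr_idx, , drop = FALSE],
                           vi900[tr_idx, , drop = FALSE], smc[tr_idx])
    vim <- matrix(NA_real_, length(ids), length(VI_CATALOG),
                  dimnames = list(ids, VI_CATALOG))
    for (nm in VI_CATALOG) {
      if (is.na(sel[nm])) next
      vim[, nm] <- if (sel[nm] == 900L) vi900[, nm] else vi800[, nm]
    }
    tabs[[ly]] <- vim[, colSums(is.na(vim)) == 0, drop = FALSE]
    sels[[ly]] <- sel
  }
  list(tables = tabs, selection = sels)
}

# Per-layer best texture-index pairs (exhaustive search on the full sample,
# matching how the index catalogs are screened) and their feature columns.
ti_tables_for_layers <- function(tf, truth) {
  tabs <- list(); searches <- list()
  for (ly in LAYER_NAMES) {
    smc <- truth[[LAYER_SMC_COLUMNS[[ly]]]]
    search <- search_texture_indices(tf, smc)
    tim <- vapply(seq_len(nrow(search)), function(k) {
      ti_values(search$form[k], tf[, search$t1[k]], tf[, search$t2[k]])
    }, numeric(nrow(tf)))
    colnames(tim) <- search$form
    rownames(tim) <- rownames(tf)
    search <- cbind(layer = ly, search, stringsAsFactors = FALSE)
    tabs[[ly]] <- tim
    searches[[ly]] <- search
  }
  list(tables = tabs, search = do.call(rbind, searches))
}

feature_family_map <- function(tf_names) {
  c(setNames(rep("VIs", length(VI_CATALOG)), VI_CATALOG),
    setNames(rep("TF", length(tf_names)), tf_names),
    setNames(rep("TIs", length(TI_FORMS)), TI_FORMS),
    setNames(rep("TVIs", 4), c("TcD", "NRCT", "CRTD", "SRTD")))
}

#' Build the four per-layer feature families for an experiment
#'
#' Runs masking, band extraction, vegetation indices with per-layer NIR-band
#' selection (selection uses the training split only), GLCM textures, the
#' exhaustive texture-index search, thermal calibration, and the thermal
#' indices.
#'
#' @param experiment an `smc_experiment`
#' @param split a [split_data()] result over the experiment's plot IDs
#' @param vi_threshold,glcm_levels masking and quantization settings
#' @return list with `tables_by_layer` (layer -> plots x features matrix),
#'   `family` (named vector feature -> family), `ti_search` (per-layer best
#'   pairs), `nir_selection` (per-layer NIR band per index),
#'   `calibration_fit`, and `reflectance` (plots x bands means)
#' @export
build_feature_tables <- function(experiment, split, vi_threshold = 0.3,
                                 glcm_levels = 32) {
  scenes <- experiment$scenes
  truth <- experiment$truth
  ids <- vapply(scenes, `[[`, character(1), "plot_id")
  stopifnot(identical(ids, truth$plot_id))
  masks <- lapply(scenes, canopy_mask, vi_threshold = vi_threshold)
  soil_masks <- lapply(masks, `!`)

  refl <- t(vapply(seq_along(scenes),
                   function(i) plot_reflectance(scenes[[i]], masks[[i]]),
                   numeric(6)))
  rownames(refl) <- ids
  tr_idx <- match(split$train_ids, ids)
  vis <- vi_tables_for_layers(refl, truth, tr_idx)

  tex_long <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    d <- plot_texture(scenes[[i]], masks[[i]], levels = glcm_levels)
    d$plot_id <- ids[i]
    d
  }))
  tf <- texture_wide(tex_long)
  tis <- ti_tables_for_layers(tf, truth)
  th <- thermal_feature_table(scenes, masks, soil_masks,
                              calibration = experiment$calibration)

  tables <- lapply(LAYER_NAMES, function(ly) {
    cbind(vis$tables[[ly]], tf, tis$tables[[ly]], th$table)
  })
  names(tables) <- LAYER_NAMES
  list(tables_by_layer = tables, family = feature_family_map(colnames(tf)),
       ti_search = tis$search, nir_selection = vis$selection,
       calibration_fit = th$calibration_fit, reflectance = refl)
}

#' Run the full soil-moisture pipeline
#'
#' Executes the nine stages in order: scenes, masks, vegetation indices,
#' textures, texture indices, thermal calibration, thermal indices,
#' screening, evaluation. Returns (and optionally writes) the feature
#' tables, screening report, evaluation table, and a JSON run report with
#' seeds, versions, stage timings, and accumulated warnings. Deterministic
#' given the configuration.
#'
#' @param config a [pipeline_config()]
#' @return list of class `smc_run`: `evaluation`, `screening`, `features`,
#'   `family`, `ti_search`, `nir_selection`, `truth`, `split`, `report`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  stages <- data.frame(stage = character(0), seconds = numeric(0))
  warnings_log <- character(0)
  timed <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    stages[nrow(stages) + 1, ] <<- list(name, proc.time()[["elapsed"]] - t1)
    res
  }

  experiment <- timed("scenes", {
    if (config$mode == "synthetic") {
      sc <- config$scene
      sc$seed <- derive_seed(config$seed, "scene")
      generate_experiment(sc)
    } else {
      read_experiment(config$input_dir)
    }
  })
  truth <- experiment$truth
  ids <- truth$plot_id
  split <- split_data(ids, config$train_fraction,
                      seed = derive_seed(config$seed, "split"))

  masks <- timed("masks", lapply(experiment$scenes, canopy_mask,
                                 vi_threshold = config$vi_threshold))
  soil_masks <- lapply(masks, `!`)

  vis <- timed("vegetation_indices", {
    refl <- t(vapply(seq_along(experiment$scenes),
                     function(i) plot_reflectance(experiment$scenes[[i]],
                                                  masks[[i]]),
                     numeric(6)))
    rownames(refl) <- ids
    vi_tables_for_layers(refl, truth, match(split$train_ids, ids))
  })

  tf <- timed("textures", {
    tex_long <- do.call(rbind, lapply(seq_along(experiment$scenes),
      function(i) {
        d <- plot_texture(experiment$scenes[[i]], masks[[i]],
                          levels = config$glcm_levels)
        d$plot_id <- ids[i]
        d
      }))
    texture_wide(tex_long)
  })
  tis <- timed("texture_indices", ti_tables_for_layers(tf, truth))

  thermals <- timed("thermal_calibration", {
    raw <- lapply(experiment$scenes, `[[`, "thermal")
    if (!is.null(experiment$calibration)) {
      cal <- calibrate_thermal(raw[[1]], experiment$calibration)
      list(rasters = lapply(raw, function(t) cal$a * t + cal$b),
           fit = cal[c("a", "b", "r_squared")])
    } else list(rasters = raw, fit = NULL)
  })
  th_table <- timed("thermal_indices", {
    ext <- field_canopy_extremes(thermals$rasters, masks)
    rows <- mapply(function(sc, t, cm, sm) {
      thermal_indices(thermal_summary(sc, t, cm, sm, ext))
    }, experiment$scenes, thermals$rasters, masks, soil_masks)
    tab <- t(rows)
    rownames(tab) <- ids
    tab
  })

  tables <- lapply(LAYER_NAMES, function(ly) {
    cbind(vis$tables[[ly]], tf, tis$tables[[ly]], th_table)
  })
  names(tables) <- LAYER_NAMES
  family <- feature_family_map(colnames(tf))

  screening <- timed("screening", {
    out <- lapply(LAYER_NAMES, function(ly) {
      screen_features(tables[[ly]], truth[[LAYER_SMC_COLUMNS[[ly]]]],
                      alpha = config$alpha, family = family, layer = ly)
    })
    names(out) <- LAYER_NAMES
    for (ly in LAYER_NAMES) {
      for (fam in c("VIs", "TF", "TIs", "TVIs")) {
        s <- out[[ly]]
        if (!any(s$selected & s$family == fam))
          warnings_log <- c(warnings_log, sprintf(
            "screening: no %s feature selected for layer %s", fam, ly))
      }
    }
    out
  })

  evaluation <- timed("evaluation", {
    evaluate_combinations(tables, screening, truth, split,
                          cfg = config$learners, combos = config$combos,
                          models = config$models,
                          seed = derive_seed(config$seed, "models"))
  })

  report <- list(
    package = "smcfusion",
    version = as.character(utils::packageVersion("smcfusion")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    mode = config$mode,
    n_plots = length(ids),
    stages = stages,
    n_stages = nrow(stages),
    calibration_fit = thermals$fit,
    warnings = warnings_log,
    elapsed_seconds = proc.time()[["elapsed"]] - t0)

  run <- structure(list(evaluation = evaluation,
                        screening = do.call(rbind, screening),
                        features = tables,
                        family = family,
                        ti_search = tis$search,
                        nir_selection = vis$selection,
                        truth = truth,
                        split = split,
                        report = report), class = "smc_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' Write pipeline outputs
#'
#' Writes per-layer feature tables, the screening report, the texture-index
#' search table, the evaluation table, a copy of the ground truth, and the
#' JSON run report into `out_dir`.
#'
#' @param run an `smc_run`
#' @param out_dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (ly in names(run$features)) {
    p <- file.path(out_dir, sprintf("features_%s.csv", gsub("-", "_", ly)))
    df <- data.frame(plot_id = rownames(run$features[[ly]]),
                     run$features[[ly]], check.names = FALSE)
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in c("screening", "ti_search", "evaluation")) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(run[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(run$truth, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(run$report, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.smc_run <- function(x, ...) {
  cat(sprintf("<smc_run: %d plots, %d evaluation rows, %d stages, %.1f s>\n",
              length(x$truth$plot_id), nrow(x$evaluation),
              x$report$n_stages, x$report$elapsed_seconds))
  invisible(x)
}
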