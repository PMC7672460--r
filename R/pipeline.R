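#' Assemble a run configuration
#'
#' Collects everything one end-to-end run needs. Data can be given as
#' in-memory objects (as produced by [generate_sct()] / [generate_ifc()]
#' or the readers) or loaded from the paths in a YAML config via
#' [read_run_config()].
#'
#' @param sct_counts raw [count_matrix()].
#' @param sct_markers raw [marker_table()] for the SCT cells.
#' @param ifc_markers raw [marker_table()] for the IFC cells (standard
#'   mode; optional in label-free mode when `ifc_images` is given).
#' @param gates an [gate_set()] on normalized markers.
#' @param preprocess an [preprocess_config()].
#' @param model an [model_config()].
#' @param cnn an [cnn_config()] (label-free mode).
#' @param ifc_images an [image_stack()] (label-free mode).
#' @param adt optional surface-protein [marker_table()]; columns named in
#'   `adt_targets` are appended to the regression targets.
#' @param adt_targets ADT columns to predict directly (e.g. `"CD4"`).
#' @param out_dir optional artifact directory; when set, predictions,
#'   metrics and a manifest are written there.
#' @param seed global seed; per-stage seeds are derived with
#'   [stage_seed()].
#' @return list of class `ifc_run_config`.
#' @export
run_config <- function(sct_counts, sct_markers, ifc_markers = NULL,
                       gates = NULL, preprocess = preprocess_config(),
                       model = model_config(), cnn = cnn_config(),
                       ifc_images = NULL, adt = NULL,
                       adt_targets = character(0), out_dir = NULL,
                       seed = 1L) {
  stopifnot(inherits(sct_counts, "ifc_counts"),
            inherits(sct_markers, "ifc_markers"))
  if (is.null(gates)) stop("run_config: a gate set is required")
  stopifnot(inherits(gates, "ifc_gates"))
  structure(list(sct_counts = sct_counts, sct_markers = sct_markers,
                 ifc_markers = ifc_markers, gates = gates,
                 preprocess = preprocess, model = model, cnn = cnn,
                 ifc_images = ifc_images, adt = adt,
                 adt_targets = adt_targets, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "ifc_run_config")
}

#' Load a run configuration from a YAML file
#'
#' Expected keys: `sct_counts`, `sct_markers`, `ifc_markers`,
#' `ifc_image_dir` (optional), `gates` (population -> marker -> [lo, hi]),
#' `precedence`, `mode`, `seed`, `out_dir`, plus optional `preprocess`,
#' `model` and `cnn` blocks whose keys mirror the corresponding
#' configuration constructors. Referenced files are validated before any
#' compute.
#'
#' @param path YAML file.
#' @return list of class `ifc_run_config` plus a `mode` attribute.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
                         else file.path(base, p)
  for (key in c("sct_counts", "sct_markers", "ifc_markers")) {
    if (is.null(y[[key]]) && key != "ifc_markers")
      stop("config key missing: ", key)
    if (!is.null(y[[key]])) {
      y[[key]] <- resolve(y[[key]])
      if (!file.exists(y[[key]]))
        stop("configured file not found: ", y[[key]])
    }
  }
  if (is.null(y$gates)) stop("config key missing: gates")
  gl <- lapply(y$gates, function(g) lapply(g, unlist))
  gates <- gate_set(gl, precedence = if (!is.null(y$precedence))
    y$precedence else names(gl))
  images <- NULL
  if (!is.null(y$ifc_image_dir)) {
    dirp <- resolve(y$ifc_image_dir)
    tifs <- sort(list.files(dirp, pattern = "\\.tiff?$",
                            full.names = TRUE))
    if (length(tifs) == 0) stop("no TIFF files in ", dirp)
    images <- read_tiff_stack(tifs)
  }
  mk_cfg <- function(ctor, block) do.call(ctor, as.list(block %||% list()))
  cfg <- run_config(
    sct_counts = read_gene_by_cell_csv(y$sct_counts),
    sct_markers = read_marker_csv(y$sct_markers),
    ifc_markers = if (!is.null(y$ifc_markers))
      read_marker_csv(y$ifc_markers),
    gates = gates,
    preprocess = mk_cfg(preprocess_config, y$preprocess),
    model = mk_cfg(model_config, y$model),
    cnn = mk_cfg(cnn_config, y$cnn),
    ifc_images = images,
    out_dir = y$out_dir,
    seed = y$seed %||% 1L)
  attr(cfg, "mode") <- y$mode %||% "standard"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_core <- function(config, ifc_markers_norm, ifc_ids, mode) {
  seed <- config$seed
  pp <- preprocess_sct(config$sct_counts, config$sct_markers,
                       config$preprocess, config$gates)
  targets <- pp$expr
  if (length(config$adt_targets) > 0) {
    if (is.null(config$adt)) stop("adt_targets set but no adt table given")
    targets <- append_surface_targets(targets, config$adt,
                                      config$adt_targets)
  }
  sp <- split_train_test(targets, pp$markers,
                         config$model$train_fraction,
                         seed = stage_seed(seed, "split"))
  mc <- config$model
  mc$seed <- stage_seed(seed, "fit")
  forest <- fit_expression_model(sp$train$markers, sp$train$expr, mc,
                                 kind = "forest")
  test_pred <- predict_expression(forest, sp$test$markers,
                                  per_tree = TRUE)
  marker_genes <- marker_gene_union(pp$ranking)
  metrics <- per_cell_metrics(sp$test$expr, test_pred$mean, marker_genes)
  gene_corr <- per_gene_metrics(sp$test$expr, test_pred$mean)
  uncertainty <- per_tree_uncertainty(test_pred$per_tree, sp$test$expr,
                                      marker_genes)

  ifc_pred <- predict_expression(forest, ifc_markers_norm)
  ifc_labels <- apply_gates(ifc_markers_norm, config$gates)

  sct_profiles <- population_profiles(pp$expr, pp$labels, marker_genes)
  ifc_profiles <- population_profiles(ifc_pred$mean, ifc_labels,
                                      marker_genes)
  res <- list(mode = mode,
              preprocess = pp,
              split = list(train_ids = sp$train$cell_ids,
                           test_ids = sp$test$cell_ids),
              model = forest,
              sct_test_metrics = metrics,
              sct_test_gene_corr = gene_corr,
              sct_test_uncertainty = uncertainty,
              ifc_markers = ifc_markers_norm,
              ifc_labels = ifc_labels,
              ifc_predictions = ifc_pred$mean,
              marker_genes = marker_genes,
              sct_profiles = sct_profiles,
              ifc_profiles = ifc_profiles,
              sct_similarity = population_similarity(sct_profiles),
              ifc_similarity = population_similarity(ifc_profiles),
              seed = seed)
  if (!is.null(config$out_dir)) write_run_artifacts(res, config)
  res
}

write_run_artifacts <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_predictions(res$ifc_predictions, out("ifc_predictions.csv"))
  save_expression_model(res$model, out("expression_model.rds"))
  jsonlite::write_json(
    list(mode = res$mode, seed = res$seed,
         package_version = as.character(utils::packageVersion("ifcseq")),
         n_sct_cells = length(res$preprocess$counts$cell_ids),
         n_genes = length(res$preprocess$counts$gene_ids),
         n_ifc_cells = length(res$ifc_markers$cell_ids),
         marker_bounds = res$preprocess$markers$bounds,
         medians = as.list(res$sct_test_metrics$medians),
         stage_seeds = list(split = stage_seed(res$seed, "split"),
                            fit = stage_seed(res$seed, "fit"),
                            cnn = stage_seed(res$seed, "cnn"))),
    out("manifest.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(data.frame(cell = res$ifc_labels$cell_ids,
                              population = res$ifc_labels$labels),
                   out("ifc_labels.csv"), row.names = FALSE)
  invisible(NULL)
}

#' Run the standard-mode pipeline end to end
#'
#' Preprocess the SCT experiment, co-register the measured IFC markers,
#' fit the forest on the SCT training split, evaluate on the SCT test
#' split, predict expression for every IFC cell, and compare population
#' profiles across modalities.
#'
#' @param config an [run_config()] with `ifc_markers` set.
#' @return list with the preprocessed data, fitted model, SCT test-set
#'   metrics (per-cell, per-gene, per-tree uncertainty), IFC predictions
#'   and labels, and population profile/similarity objects for both
#'   modalities.
#' @export
run_standard <- function(config) {
  stopifnot(inherits(config, "ifc_run_config"))
  if (is.null(config$ifc_markers))
    stop("run_standard: ifc_markers are required in standard mode")
  run_core(config, normalize_markers(config$ifc_markers),
           config$ifc_markers$cell_ids, "standard")
}

#' Run the label-free pipeline end to end
#'
#' As [run_standard()], but the IFC marker values are first regressed from
#' the brightfield images: the CNN is trained on the IFC training images
#' against the measured (normalized) markers, then its predictions replace
#' the measured markers for expression prediction. The two modes differ
#' only in marker provenance.
#'
#' @param config an [run_config()] with `ifc_images` (and, for CNN
#'   training, `ifc_markers`) set.
#' @param marker_predictor optional function `(image_stack) ->
#'   marker_table` replacing the internal train-then-predict step (e.g. a
#'   pre-trained model, or an oracle in tests).
#' @return as [run_standard()], plus `cnn` (the trained model, `NULL`
#'   when `marker_predictor` is supplied).
#' @export
run_labelfree <- function(config, marker_predictor = NULL) {
  stopifnot(inherits(config, "ifc_run_config"))
  if (is.null(config$ifc_images))
    stop("run_labelfree: ifc_images are required in label-free mode")
  cnn <- NULL
  if (is.null(marker_predictor)) {
    if (is.null(config$ifc_markers))
      stop("run_labelfree: measured ifc_markers are required to train ",
           "the CNN (or pass marker_predictor)")
    measured <- normalize_markers(config$ifc_markers)
    cc <- config$cnn
    cc$seed <- stage_seed(config$seed, "cnn")
    cnn <- build_marker_cnn(n_markers = ncol(measured$values),
                            seed = stage_seed(config$seed, "cnn-init"))
    cnn <- train_marker_cnn(cnn, config$ifc_images, measured, cc)
    predicted <- predict_markers(cnn, config$ifc_images)
  } else {
    predicted <- marker_predictor(config$ifc_images)
    stopifnot(inherits(predicted, "ifc_markers"))
    if (!predicted$normalized)
      stop("marker_predictor must return normalized markers")
  }
  res <- run_core(config, predicted, predicted$cell_ids, "labelfree")
  res$cnn <- cnn
  res
}
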