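#' Configuration of the marker-to-expression regression model
#'
#' Defaults follow the published setup: an ensemble of 50 trees minimizing
#' the mean absolute error, `sqrt(p)` candidate features per split, and a
#' 70/30 train/test split of the SCT experiment. No validation set or
#' hyperparameter tuning is exposed.
#'
#' @param n_trees ensemble size.
#' @param split_criterion only `"absolute_error"` is implemented (splits
#'   minimize the summed absolute deviation around the per-target median).
#' @param max_features only `"sqrt"` is implemented.
#' @param train_fraction fraction of SCT cells used for training.
#' @param min_leaf minimum samples per leaf.
#' @param seed integer seed for bootstrap and feature sampling.
#' @return a list of class `ifc_model_config`.
#' @export
model_config <- function(n_trees = 50L, split_criterion = "absolute_error",
                         max_features = "sqrt", train_fraction = 0.7,
                         min_leaf = 1L, seed = 1L) {
  stopifnot(n_trees >= 1, train_fraction > 0, train_fraction < 1,
            min_leaf >= 1)
  split_criterion <- match.arg(split_criterion, "absolute_error")
  max_features <- match.arg(max_features, "sqrt")
  structure(list(n_trees = as.integer(n_trees),
                 split_criterion = split_criterion,
                 max_features = max_features,
                 train_fraction = train_fraction,
                 min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "ifc_model_config")
}

#' Split cells into a training and a test set
#'
#' @param expr an [expression_matrix()].
#' @param markers an [marker_table()] covering the same cells.
#' @param train_fraction fraction of cells assigned to training;
#'   `round(fraction * n)` cells are drawn.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list with elements `train` and `test`, each a list of aligned
#'   `expr` and `markers` objects, plus the cell-id vectors.
#' @export
split_train_test <- function(expr, markers, train_fraction = 0.7,
                             seed = 1L) {
  stopifnot(inherits(expr, "ifc_expr"), inherits(markers, "ifc_markers"))
  if (!setequal(expr$cell_ids, markers$cell_ids))
    stop("split_train_test: expr and markers must cover the same cells")
  n <- length(expr$cell_ids)
  if (n < 2) stop("split_train_test: need at least 2 cells")
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("split_train_test: degenerate split (", n_train, "/", n, ")")
  idx <- with_seed(seed, sample.int(n, n_train))
  take <- function(keep) {
    ids <- expr$cell_ids[keep]
    m <- markers$values[match(ids, markers$cell_ids), , drop = FALSE]
    list(expr = expression_matrix(expr$values[keep, , drop = FALSE]),
         markers = marker_table(m, normalized = markers$normalized,
                                bounds = markers$bounds),
         cell_ids = ids)
  }
  list(train = take(sort(idx)), test = take(sort(setdiff(seq_len(n), idx))))
}

#' Fit the marker-to-expression model
#'
#' Learns the map from normalized surface-marker values to per-cell
#' expression over all targets jointly. `kind = "forest"` fits the
#' multi-output random forest (mean-absolute-error splits, per-target
#' median leaves, `sqrt(p)` features per split); `kind = "linear"` fits the
#' ordinary least-squares baseline.
#'
#' @param markers training [marker_table()] (normalized).
#' @param targets training [expression_matrix()] aligned on cells.
#' @param config an [model_config()].
#' @param kind `"forest"` or `"linear"`.
#' @return an object of class `ifc_model`.
#' @export
fit_expression_model <- function(markers, targets,
                                 config = model_config(),
                                 kind = c("forest", "linear")) {
  kind <- match.arg(kind)
  stopifnot(inherits(markers, "ifc_markers"), inherits(targets, "ifc_expr"),
            inherits(config, "ifc_model_config"))
  if (!identical(markers$cell_ids, targets$cell_ids))
    stop("fit_expression_model: markers and targets must be aligned on ",
         "the same cells in the same order")
  X <- markers$values
  Y <- targets$values
  if (nrow(X) < 2) stop("fit_expression_model: need at least 2 cells")
  if (anyNA(X) || anyNA(Y)) stop("fit_expression_model: NaN in inputs")
  if (any(apply(X, 2, function(v) length(unique(v))) < 2))
    stop("fit_expression_model: constant input marker")
  fitted <- if (kind == "forest") {
    mtry <- max(1L, floor(sqrt(ncol(X))))
    rf_fit_cpp(X, Y, config$n_trees, mtry, config$min_leaf, config$seed,
               bootstrap = TRUE)
  } else {
    # multi-response OLS with intercept
    qr.solve(cbind(1, X), Y)
  }
  structure(list(kind = kind, fitted = fitted,
                 marker_names = markers$marker_names,
                 target_names = targets$target_names,
                 config = config),
            class = "ifc_model")
}

#' @export
print.ifc_model <- function(x, ...) {
  cat("<ifc_model> ", x$kind, ": ", length(x$marker_names),
      " markers -> ", length(x$target_names), " targets",
      if (x$kind == "forest")
        paste0(" (", x$config$n_trees, " trees, MAE splits)"),
      "\n", sep = "")
  invisible(x)
}

#' Predict expression from marker values
#'
#' @param model an `ifc_model` from [fit_expression_model()].
#' @param markers an [marker_table()] with the training marker columns;
#'   values outside \[0, 1\] raise a warning (independent per-modality
#'   normalization can push IFC cells slightly outside the SCT range) but
#'   are passed through unmodified.
#' @param per_tree also return the per-tree prediction stack (forest only).
#' @return list of class `ifc_prediction`: `mean` (an
#'   [expression_matrix()]) and, when requested, `per_tree`
#'   (`cells x targets x trees` array).
#' @export
predict_expression <- function(model, markers, per_tree = FALSE) {
  stopifnot(inherits(model, "ifc_model"), inherits(markers, "ifc_markers"))
  miss <- setdiff(model$marker_names, markers$marker_names)
  if (length(miss))
    stop("predict_expression: missing markers: ",
         paste(miss, collapse = ", "))
  X <- markers$values[, model$marker_names, drop = FALSE]
  if (any(X < 0 | X > 1))
    warning("marker values outside [0, 1]; prediction proceeds unmodified")
  if (model$kind == "forest") {
    res <- rf_predict_cpp(model$fitted, X, per_tree)
    mean_pred <- res$mean
  } else {
    if (per_tree)
      stop("per-tree predictions are only available for forest models")
    res <- NULL
    mean_pred <- cbind(1, X) %*% model$fitted
  }
  dimnames(mean_pred) <- list(markers$cell_ids, model$target_names)
  out <- list(mean = expression_matrix(mean_pred))
  if (per_tree && model$kind == "forest") {
    pt <- res$per_tree
    dimnames(pt) <- list(markers$cell_ids, model$target_names, NULL)
    out$per_tree <- pt
  }
  structure(out, class = "ifc_prediction")
}

#' @export
print.ifc_prediction <- function(x, ...) {
  cat("<ifc_prediction> ", nrow(x$mean$values), " cells x ",
      ncol(x$mean$values), " targets",
      if (!is.null(x$per_tree)) paste0(", ", dim(x$per_tree)[3],
                                       " per-tree slices"),
      "\n", sep = "")
  invisible(x)
}

#' Persist a fitted model with a JSON manifest
#'
#' Writes the model object (RDS) plus a `<path>.json` manifest recording
#' kind, hyperparameters, marker and target names, and the training seed.
#'
#' @param model an `ifc_model`.
#' @param path output path for the binary artifact.
#' @return `path`, invisibly.
#' @export
save_expression_model <- function(model, path) {
  stopifnot(inherits(model, "ifc_model"))
  saveRDS(model, path)
  manifest <- list(format_version = 1L, kind = model$kind,
                   markers = model$marker_names,
                   n_targets = length(model$target_names),
                   config = unclass(model$config))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_expression_model
#' @export
load_expression_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ifc_model")) stop("not an ifc_model artifact: ", path)
  model
}
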