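# markers on a grid plus aligned targets, for controlled regression tests
toy_regression <- function(n, f_list, seed, markers = c("m1", "m2")) {
  set.seed(seed)
  X <- matrix(runif(n * length(markers)), n, length(markers),
              dimnames = list(sprintf("c%04d", 1:n), markers))
  Y <- vapply(f_list, function(f) f(X), numeric(n))
  dimnames(Y) <- list(rownames(X), names(f_list))
  list(markers = marker_table(X, normalized = TRUE),
       targets = expression_matrix(Y))
}

test_that("train/test split has the right sizes and is reproducible", {
  d <- toy_regression(10, list(g = function(X) X[, 1]), seed = 41)
  sp <- split_train_test(d$targets, d$markers, 0.7, seed = 5)
  expect_length(sp$train$cell_ids, 7)
  expect_length(sp$test$cell_ids, 3)
  sp2 <- split_train_test(d$targets, d$markers, 0.7, seed = 5)
  expect_identical(sp$train$cell_ids, sp2$train$cell_ids)
  # union / disjointness on random sizes
  for (n in c(23, 57, 101)) {
    d <- toy_regression(n, list(g = function(X) X[, 1]), seed = n)
    sp <- split_train_test(d$targets, d$markers, 0.7, seed = 1)
    expect_length(intersect(sp$train$cell_ids, sp$test$cell_ids), 0)
    expect_setequal(c(sp$train$cell_ids, sp$test$cell_ids), d$targets$cell_ids)
    expect_identical(length(sp$train$cell_ids), as.integer(round(0.7 * n)))
  }
  expect_error(split_train_test(
    expression_matrix(matrix(1, 1, 1, dimnames = list("c", "g"))),
    marker_table(matrix(1, 1, 1, dimnames = list("c", "m"))), 0.7, 1),
    "at least 2")
})

test_that("forest recovers a deterministic marker function on held-out cells", {
  d <- toy_regression(500, list(t1 = function(X) X[, 1],
                                t2 = function(X) 2 * X[, 1] + 1,
                                t3 = function(X) X[, 1]^2), seed = 42)
  sp <- split_train_test(d$targets, d$markers, 0.7, seed = 7)
  fm <- fit_expression_model(sp$train$markers, sp$train$expr,
                             model_config(seed = 2))
  pr <- predict_expression(fm, sp$test$markers)
  r <- per_gene_metrics(sp$test$expr, pr$mean)
  expect_true(all(r$pearson >= 0.99))
})

test_that("the linear baseline recovers exact linear coefficients", {
  d <- toy_regression(200, list(y = function(X) 3 * X[, 1] - X[, 2]),
                      seed = 43)
  fm <- fit_expression_model(d$markers, d$targets,
                             model_config(seed = 1), kind = "linear")
  expect_equal(unname(fm$fitted[, "y"]), c(0, 3, -1), tolerance = 1e-6)
  pr <- predict_expression(fm, d$markers)
  expect_lt(max(abs(pr$mean$values[, "y"] - d$targets$values[, "y"])),
            1e-8)
})

test_that("constant targets predict that constant; constant markers error", {
  d <- toy_regression(50, list(flat = function(X) rep(2.5, nrow(X)),
                               var = function(X) X[, 2]), seed = 44)
  fm <- fit_expression_model(d$markers, d$targets, model_config(seed = 3))
  pr <- predict_expression(fm, d$markers)
  expect_true(all(pr$mean$values[, "flat"] == 2.5))
  bad <- marker_table(cbind(d$markers$values[, 1, drop = FALSE], k = 0.5),
                      cell_ids = d$markers$cell_ids, normalized = TRUE)
  expect_error(fit_expression_model(bad, d$targets), "constant input")
})

test_that("ensemble identities hold: mean of trees, determinism, 1-tree case", {
  d <- toy_regression(120, list(a = function(X) sin(3 * X[, 1]),
                                b = function(X) X[, 2]), seed = 45)
  fm <- fit_expression_model(d$markers, d$targets,
                             model_config(n_trees = 10, seed = 4))
  pr <- predict_expression(fm, d$markers, per_tree = TRUE)
  expect_lt(max(abs(apply(pr$per_tree, c(1, 2), mean) - pr$mean$values)),
            1e-10)
  # duplicated input rows give identical prediction rows
  dup <- marker_table(d$markers$values[c(1, 1, 2), ],
                      cell_ids = c("x", "y", "z"), normalized = TRUE)
  pd <- predict_expression(fm, dup)
  expect_identical(pd$mean$values["x", ], pd$mean$values["y", ])
  # a single-tree forest's mean is that tree's output exactly
  f1 <- fit_expression_model(d$markers, d$targets,
                             model_config(n_trees = 1, seed = 4))
  p1 <- predict_expression(f1, d$markers, per_tree = TRUE)
  expect_identical(p1$mean$values, p1$per_tree[, , 1])
})

test_that("forest predictions stay within the training target range", {
  d <- toy_regression(300, list(y = function(X) 10 * X[, 1] - 5), seed = 46)
  fm <- fit_expression_model(d$markers, d$targets, model_config(seed = 5))
  wide <- marker_table(matrix(c(-0.2, 1.3, 0.5, 0.5), 2, 2,
                              dimnames = list(c("p", "q"), c("m1", "m2"))))
  expect_warning(pr <- predict_expression(fm, wide), "outside")
  rng <- range(d$targets$values[, "y"])
  expect_true(all(pr$mean$values >= rng[1] & pr$mean$values <= rng[2]))
})

test_that("forest agrees with an established single-target implementation", {
  d <- toy_regression(400, list(y = function(X)
    sin(4 * X[, 1]) + 0.5 * X[, 2]), seed = 47)
  sp <- split_train_test(d$targets, d$markers, 0.7, seed = 2)
  fm <- fit_expression_model(sp$train$markers, sp$train$expr,
                             model_config(seed = 6))
  mine <- predict_expression(fm, sp$test$markers)$mean$values[, "y"]
  set.seed(6)
  rf <- randomForest::randomForest(sp$train$markers$values,
                                   sp$train$expr$values[, "y"],
                                   ntree = 50)
  ref <- predict(rf, sp$test$markers$values)
  expect_gt(cor(mine, ref), 0.95)
  expect_gt(cor(mine, sp$test$expr$values[, "y"]), 0.95)
})

test_that("linear baseline matches the forest on exactly linear data", {
  d <- toy_regression(600, list(y1 = function(X) X[, 1],
                                y2 = function(X) 0.5 * X[, 1] + 0.5 * X[, 2],
                                y3 = function(X) 1 - X[, 2]), seed = 48)
  sp <- split_train_test(d$targets, d$markers, 0.7, seed = 3)
  fo <- fit_expression_model(sp$train$markers, sp$train$expr,
                             model_config(seed = 7))
  li <- fit_expression_model(sp$train$markers, sp$train$expr,
                             model_config(seed = 7), kind = "linear")
  mf <- per_cell_metrics(sp$test$expr,
                         predict_expression(fo, sp$test$markers)$mean)
  ml <- per_cell_metrics(sp$test$expr,
                         predict_expression(li, sp$test$markers)$mean)
  expect_gte(ml$medians["pearson"], mf$medians["pearson"] - 0.02)
})

test_that("model persistence round-trips with a JSON manifest", {
  d <- toy_regression(60, list(y = function(X) X[, 1]), seed = 49)
  fm <- fit_expression_model(d$markers, d$targets,
                             model_config(n_trees = 5, seed = 8))
  p <- withr::local_tempfile(fileext = ".rds")
  save_expression_model(fm, p)
  expect_true(file.exists(paste0(p, ".json")))
  man <- jsonlite::read_json(paste0(p, ".json"))
  expect_identical(man$kind, "forest")
  expect_identical(unlist(man$markers), c("m1", "m2"))
  back <- load_expression_model(p)
  expect_identical(predict_expression(back, d$markers)$mean$values,
                   predict_expression(fm, d$markers)$mean$values)
})
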