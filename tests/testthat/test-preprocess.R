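make_species_counts <- function(m) {
  # m: genes x cells integer matrix; first half HUMAN_, second half MOUSE_
  ng <- nrow(m)
  rownames(m) <- c(paste0("HUMAN_g", seq_len(ng / 2)),
                   paste0("MOUSE_g", seq_len(ng / 2)))
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  count_matrix(m)
}

test_that("species selection keeps cells with strictly more human genes", {
  m <- matrix(0L, 6, 3)
  m[1:4, 1] <- 1L   # 3 human, 1 mouse expressed -> kept
  m[c(1, 4, 5, 6), 2] <- 1L  # 1 human, 3 mouse -> dropped
  m[c(1, 2, 4, 5), 3] <- 1L  # 2 vs 2 tie -> dropped (ambiguous doublet)
  cm <- make_species_counts(m)
  out <- select_species_cells(cm)
  expect_identical(out$cell_ids, "c1")
  expect_identical(out$gene_ids, paste0("g", 1:3))  # prefix stripped
  expect_error(select_species_cells(random_counts(4, 3, 1)),
               "without species prefix")
})

test_that("species selection agrees with per-cell brute force", {
  set.seed(11)
  m <- matrix(rbinom(6 * 5, 1, 0.5), 6, 5)
  cm <- make_species_counts(m)
  out <- select_species_cells(cm)
  expected <- vapply(seq_len(5), function(j)
    sum(m[1:3, j] > 0) > sum(m[4:6, j] > 0), logical(1))
  expect_identical(out$cell_ids, cm$cell_ids[expected])
})

test_that("gene and cell filters honor their boundaries", {
  set.seed(12)
  m <- matrix(0L, 3, 30)
  m[1, 1:19] <- 1L
  m[2, 1:20] <- 1L
  m[3, ] <- 1L
  dimnames(m) <- list(paste0("g", 1:3), paste0("c", 1:30))
  out <- filter_genes_min_cells(count_matrix(m), 20)
  expect_identical(out$gene_ids, c("g2", "g3"))  # 19 dropped, 20 kept

  m2 <- matrix(1L, 250, 2)
  m2[201:250, 1] <- 0L  # cell 1 expresses 200 genes, cell 2 all 250
  m2[250, 2] <- 0L      # cell 2: 249
  dimnames(m2) <- list(paste0("g", 1:250), c("a", "b"))
  expect_identical(filter_cells_min_genes(count_matrix(m2), 200)$cell_ids,
                   c("a", "b"))
  expect_identical(filter_cells_min_genes(count_matrix(m2), 250)$cell_ids,
                   character(0))
  # min_genes = 0 is the identity
  cm <- random_counts(5, 5, 13)
  expect_identical(filter_cells_min_genes(cm, 0)$values, cm$values)
})

test_that("filters equal brute force on random sparse matrices and are idempotent", {
  set.seed(14)
  m <- matrix(rbinom(50 * 100, 1, 0.1) * rpois(50 * 100, 3), 50, 100)
  dimnames(m) <- list(paste0("g", 1:50), paste0("c", 1:100))
  cm <- count_matrix(m)
  fg <- filter_genes_min_cells(cm, 8)
  expect_identical(fg$gene_ids,
                   cm$gene_ids[apply(m, 1, function(r) sum(r > 0) >= 8)])
  fc <- filter_cells_min_genes(cm, 4)
  expect_identical(fc$cell_ids,
                   cm$cell_ids[apply(m, 2, function(cl) sum(cl > 0) >= 4)])
  # idempotence
  expect_identical(filter_genes_min_cells(fg, 8)$values, fg$values)
  expect_identical(filter_cells_min_genes(fc, 4)$values, fc$values)
})

test_that("log transform is elementwise ln(1+x)", {
  expect_identical(log_transform(count_matrix(
    matrix(0L, 1, 1, dimnames = list("g", "c"))))$values[1, 1], 0)
  set.seed(15)
  cm <- random_counts(8, 6, 16)
  lt <- log_transform(cm)
  expect_lt(max(abs(lt$values - t(log1p(cm$values)))), 1e-12)
  expect_error(log_transform(matrix(-1, 2, 2)), "negative")
})

# step-by-step reimplementation of the 20-bin dispersion recipe, written
# independently of the package internals (explicit loops)
hvg_oracle <- function(m, min_mean, max_mean, min_disp) {
  lib <- colSums(m)
  xs <- m
  for (j in seq_len(ncol(m))) xs[, j] <- m[, j] / (lib[j] / median(lib))
  keep <- logical(nrow(m))
  mu <- dl <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    x <- xs[g, ]
    mg <- mean(x)
    vg <- sum((x - mean(x))^2) / (length(x) - 1)
    d <- vg / ifelse(mg == 0, 1e-12, mg)
    dl[g] <- ifelse(d == 0, NA, log(d))
    mu[g] <- log1p(mg)
  }
  bins <- cut(mu, breaks = 20)
  dn <- numeric(length(dl))
  for (g in seq_along(dl)) {
    inbin <- which(bins == bins[g])
    vals <- dl[inbin]
    bm <- mean(vals, na.rm = TRUE)
    bs <- sd(vals, na.rm = TRUE)
    if (is.na(bs) || bs == 0) { bs <- bm; bm <- 0 }
    dn[g] <- (dl[g] - bm) / bs
  }
  !is.na(dn) & mu > min_mean & mu < max_mean & dn > min_disp
}

test_that("HVG selection matches an independent 20-bin recipe", {
  set.seed(17)
  n_genes <- 200; n_cells <- 150
  base <- exp(runif(n_genes, -3, 2))
  m <- matrix(rnbinom(n_genes * n_cells, mu = rep(base, n_cells),
                      size = 0.7), n_genes, n_cells)
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("c", seq_len(n_cells)))
  keep_cells <- colSums(m) > 0
  m <- m[, keep_cells]
  cm <- count_matrix(m)
  out <- select_highly_variable_genes(cm, 0.0125, 3, -0.15)
  expect_identical(out$gene_ids,
                   rownames(m)[hvg_oracle(m, 0.0125, 3, -0.15)])
})

test_that("HVG mean gate and degenerate input behave as specified", {
  # constant expression in every gene -> zero dispersion -> threshold error
  m <- matrix(2L, 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  expect_error(select_highly_variable_genes(count_matrix(m)), "relax")
  # gene A variable with modest mean, gene B huge mean above max_mean
  set.seed(18)
  a <- rpois(50, 1.0)
  b <- rpois(50, 60)
  m2 <- rbind(A = a, B = b)
  colnames(m2) <- paste0("c", 1:50)
  out <- select_highly_variable_genes(count_matrix(m2), 0.0125, 3, -5,
                                      normalize = FALSE)
  expect_identical(out$gene_ids, "A")
})

test_that("Welch statistics match t.test and markers rank correctly", {
  set.seed(19)
  n1 <- 7; n2 <- 9; ng <- 12
  x <- matrix(rnorm((n1 + n2) * ng), nrow = n1 + n2)
  colnames(x) <- paste0("g", seq_len(ng))
  rownames(x) <- paste0("c", seq_len(n1 + n2))
  labels <- rep(c("a", "b"), c(n1, n2))
  expr <- expression_matrix(x)
  rk <- rank_marker_genes(expr, labels, n_top = ng)
  for (g in sample(ng, 4)) {
    tt <- t.test(x[labels == "a", g], x[labels == "b", g])
    expect_equal(rk$rankings$a$score[rk$rankings$a$gene == colnames(x)[g]],
                 unname(tt$statistic), tolerance = 1e-10)
  }
  # scores of the two one-vs-rest directions are antisymmetric
  expect_equal(sort(rk$rankings$a$score), sort(-rk$rankings$b$score),
               tolerance = 1e-10)
})

test_that("planted markers occupy the top ranks; flat genes do not", {
  set.seed(20)
  n <- 60; ng <- 20
  labels <- rep(c("p1", "p2"), each = n / 2)
  x <- matrix(rnorm(n * ng, 1, 0.5), n, ng)
  planted1 <- 1:3; planted2 <- 4:6
  x[labels == "p1", planted1] <- x[labels == "p1", planted1] + 3
  x[labels == "p2", planted2] <- x[labels == "p2", planted2] + 3
  dimnames(x) <- list(paste0("c", 1:n), paste0("g", 1:ng))
  rk <- rank_marker_genes(expression_matrix(x), labels, n_top = 5)
  expect_setequal(rk$rankings$p1$gene[1:3], paste0("g", planted1))
  expect_setequal(rk$rankings$p2$gene[1:3], paste0("g", planted2))
  # an identically distributed gene never outranks a clearly differential one
  expect_false("g7" %in% rk$rankings$p1$gene[1:3])
})

test_that("marker ranking is label-permutation equivariant", {
  set.seed(21)
  x <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(paste0("c", 1:40), paste0("g", 1:10)))
  labels <- sample(c("a", "b"), 40, replace = TRUE)
  labels[1:4] <- c("a", "a", "b", "b")
  expr <- expression_matrix(x)
  r1 <- rank_marker_genes(expr, labels, n_top = 10)
  # renaming populations permutes the ranking lists identically
  swapped <- ifelse(labels == "a", "b", "a")
  r2 <- rank_marker_genes(expr, swapped, n_top = 10)
  expect_equal(r1$rankings$a, r2$rankings$b)
  expect_equal(r1$rankings$b, r2$rankings$a)
  expect_error(rank_marker_genes(expr, c("z", labels[-1]), 5),
               "fewer than 2 cells")
})

test_that("wilcoxon ranking agrees with wilcox.test ordering", {
  set.seed(22)
  n <- 30; ng <- 8
  labels <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * ng), n, ng,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:ng)))
  x[labels == "a", 1] <- x[labels == "a", 1] + 2
  rk <- rank_marker_genes(expression_matrix(x), labels, n_top = ng,
                          method = "wilcoxon")
  expect_identical(rk$rankings$a$gene[1], "g1")
  # z-statistic sign matches the rank-sum direction per gene
  for (g in c(1, 3, 5)) {
    w <- wilcox.test(x[labels == "a", g], x[labels == "b", g])
    z <- rk$rankings$a$score[rk$rankings$a$gene == paste0("g", g)]
    bigger <- w$statistic > (n / 2)^2 / 2
    expect_identical(unname(z > 0), unname(bigger))
  }
})

test_that("the pipeline composes the filters in the published order", {
  tr <- small_truth()
  sct <- generate_sct(tr, n_cells = 300, n_genes = 60, seed = 23)
  pp <- preprocess_sct(sct$counts, sct$markers,
                       preprocess_config(min_cells_per_gene = 5,
                                         n_top_markers = 5),
                       truth_gates(tr))
  # gene filter ran before the log transform
  expect_true(all(rowSums(pp$counts$values > 0) >= 5))
  expect_lt(max(abs(pp$expr$values - t(log1p(pp$counts$values)))), 1e-12)
  expect_true(pp$markers$normalized)
  expect_s3_class(pp$ranking, "ifc_marker_ranking")
  expect_identical(pp$expr$cell_ids, pp$counts$cell_ids)
})

test_that("surface-protein targets append with log transform", {
  expr <- expression_matrix(matrix(rnorm(6), 3, 2,
                                   dimnames = list(paste0("c", 1:3),
                                                   c("g1", "g2"))))
  adt <- marker_table(matrix(c(0, 3, 7), 3, 1,
                             dimnames = list(paste0("c", 1:3), "CD4")))
  out <- append_surface_targets(expr, adt, "CD4")
  expect_identical(out$target_names, c("g1", "g2", "surface_CD4"))
  expect_equal(out$values[, "surface_CD4"],
               setNames(log1p(c(0, 3, 7)), paste0("c", 1:3)))
})
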