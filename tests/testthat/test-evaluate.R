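expr_pair <- function(n_cells, n_genes, seed) {
  set.seed(seed)
  tv <- matrix(rnorm(n_cells * n_genes), n_cells, n_genes,
               dimnames = list(sprintf("c%03d", 1:n_cells),
                               sprintf("g%02d", 1:n_genes)))
  pv <- tv + matrix(rnorm(n_cells * n_genes, sd = 0.8), n_cells, n_genes)
  list(true = expression_matrix(tv), pred = expression_matrix(pv))
}

test_that("per-cell metrics hit the exact identities", {
  d <- expr_pair(6, 5, 61)
  same <- per_cell_metrics(d$true, d$true)
  expect_equal(same$per_cell$pearson, rep(1, 6), tolerance = 1e-12)
  expect_true(all(same$per_cell$rmse == 0))
  anti <- expression_matrix(-d$true$values + 2,
                            d$true$cell_ids, d$true$target_names)
  expect_equal(per_cell_metrics(d$true, anti)$per_cell$pearson,
               rep(-1, 6), tolerance = 1e-12)
})

test_that("per-cell medians equal textbook formulas on a random pair", {
  d <- expr_pair(5, 4, 62)
  m <- per_cell_metrics(d$true, d$pred)
  brute_p <- brute_s <- brute_r <- numeric(5)
  for (i in 1:5) {
    a <- d$true$values[i, ]; b <- d$pred$values[i, ]
    brute_p[i] <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    brute_s[i] <- cor(rank(a), rank(b))
    brute_r[i] <- sqrt(mean((a - b)^2))
  }
  expect_equal(m$per_cell$pearson, brute_p, tolerance = 1e-12)
  expect_equal(m$per_cell$spearman, brute_s, tolerance = 1e-12)
  expect_equal(m$per_cell$rmse, brute_r, tolerance = 1e-12)
  expect_equal(unname(m$medians), c(median(brute_p), median(brute_s),
                                    median(brute_r)), tolerance = 1e-12)
})

test_that("zero-variance cells are excluded from medians and counted", {
  d <- expr_pair(4, 4, 63)
  tv <- d$true$values
  tv[1, ] <- 3  # flat cell: undefined correlation
  m <- per_cell_metrics(expression_matrix(tv, d$true$cell_ids,
                                          d$true$target_names), d$pred)
  expect_identical(m$n_undefined, 1L)
  expect_true(is.na(m$per_cell$pearson[1]))
  expect_false(is.na(m$medians["pearson"]))
  expect_error(per_cell_metrics(d$true, d$pred, c("g01", "g02")),
               "at least 3")
})

test_that("per-gene correlations match brute force", {
  d <- expr_pair(8, 6, 64)
  pg <- per_gene_metrics(d$true, d$pred)
  for (g in seq_len(6)) {
    expect_equal(pg$pearson[g],
                 cor(d$true$values[, g], d$pred$values[, g]),
                 tolerance = 1e-12)
    expect_equal(pg$spearman[g],
                 cor(d$true$values[, g], d$pred$values[, g],
                     method = "spearman"), tolerance = 1e-12)
  }
})

test_that("correlations are invariant to positive affine transforms", {
  d <- expr_pair(7, 5, 65)
  base <- per_cell_metrics(d$true, d$pred)
  scaled <- expression_matrix(3.2 * d$pred$values + 4,
                              d$pred$cell_ids, d$pred$target_names)
  m2 <- per_cell_metrics(d$true, scaled)
  expect_equal(m2$per_cell$pearson, base$per_cell$pearson,
               tolerance = 1e-12)
  expect_equal(m2$per_cell$spearman, base$per_cell$spearman,
               tolerance = 1e-12)
})

test_that("per-tree uncertainty: identical trees, hand-worked pair, symmetry", {
  set.seed(66)
  n <- 10; g <- 3; tv <- matrix(rnorm(n * g), n, g,
                                dimnames = list(paste0("c", 1:n),
                                                paste0("g", 1:g)))
  true <- expression_matrix(tv)
  one <- tv + rnorm(n * g)
  pt_same <- array(rep(one, 4), c(n, g, 4),
                   dimnames = list(rownames(tv), colnames(tv), NULL))
  u <- per_tree_uncertainty(pt_same, true)
  expect_true(all(abs(u$sd_pearson) < 1e-14))

  two <- tv + rnorm(n * g, sd = 2)
  pt <- array(c(one, two), c(n, g, 2),
              dimnames = list(rownames(tv), colnames(tv), NULL))
  u2 <- per_tree_uncertainty(pt, true)
  for (j in seq_len(g)) {
    r1 <- cor(tv[, j], one[, j]); r2 <- cor(tv[, j], two[, j])
    hand <- sqrt(((r1 - mean(c(r1, r2)))^2 + (r2 - mean(c(r1, r2)))^2) / 2)
    expect_equal(u2$sd_pearson[j], hand, tolerance = 1e-12)
  }
  # invariant under tree reordering
  u3 <- per_tree_uncertainty(pt[, , c(2, 1)], true)
  expect_equal(u3$sd_pearson, u2$sd_pearson, tolerance = 1e-15)
})

test_that("population profiles are group-by means", {
  set.seed(67)
  x <- matrix(rnorm(30 * 4), 30, 4,
              dimnames = list(paste0("c", 1:30), paste0("g", 1:4)))
  expr <- expression_matrix(x)
  one <- population_profiles(expr, rep("all", 30))
  expect_equal(one["all", ], colMeans(x), tolerance = 1e-14)

  labels <- rep(c("lo", "hi"), 15)
  x2 <- x; x2[labels == "hi", ] <- x2[labels == "hi", ] - x2[labels == "hi", ] + 2
  x2[labels == "lo", ] <- 0
  p2 <- population_profiles(expression_matrix(x2), labels)
  expect_true(all(p2["hi", ] == 2) && all(p2["lo", ] == 0))

  labels3 <- sample(c("a", "b", "c"), 30, replace = TRUE)
  p3 <- population_profiles(expr, labels3)
  for (p in c("a", "b", "c"))
    expect_equal(p3[p, ], colMeans(x[labels3 == p, , drop = FALSE]),
                 tolerance = 1e-14)
})

test_that("population similarity is symmetric pairwise Pearson with unit diagonal", {
  prof <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(2, 4, 6, 8))
  s <- population_similarity(prof, conf = NULL)
  expect_equal(unname(s$r["a", "b"]), 1)
  expect_equal(unname(s$r["a", "c"]), 1)  # affine-identical profiles
  orth <- rbind(u = c(1, -1, 1, -1), v = c(1, 1, -1, -1))
  expect_lt(abs(population_similarity(orth, conf = NULL)$r["u", "v"]),
            1e-14)
  set.seed(68)
  prof3 <- matrix(rnorm(30), 3, 10,
                  dimnames = list(c("x", "y", "z"), NULL))
  s3 <- population_similarity(prof3)
  expect_equal(s3$r, t(s3$r), tolerance = 1e-14)
  expect_true(all(diag(s3$r) == 1))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(s3$r[i, j], cor(prof3[i, ], prof3[j, ]),
                 tolerance = 1e-14)
  expect_true(all(s3$lo <= s3$r + 1e-12 & s3$r <= s3$hi + 1e-12))
})

test_that("fisher intervals match the closed form and monotonicities", {
  ci <- fisher_ci(0, 103)
  expect_equal(unname(ci), c(-tanh(qnorm(0.975) / 10),
                             tanh(qnorm(0.975) / 10)), tolerance = 1e-12)
  expect_equal(unname(ci), c(-0.1935, 0.1935), tolerance = 1e-3)
  ci2 <- fisher_ci(0.5, 100)
  expect_equal(unname(ci2),
               c(tanh(atanh(0.5) - qnorm(0.975) / sqrt(97)),
                 tanh(atanh(0.5) + qnorm(0.975) / sqrt(97))),
               tolerance = 1e-12)
  expect_equal(unname(ci2), c(0.337, 0.634), tolerance = 1e-3)
  # width strictly decreasing in n, increasing in confidence
  widths_n <- vapply(c(10, 50, 200, 1000), function(n)
    diff(fisher_ci(0.4, n)), numeric(1))
  expect_true(all(diff(widths_n) < 0))
  widths_c <- vapply(c(0.5, 0.8, 0.95, 0.99), function(cf)
    diff(fisher_ci(0.4, 50, cf)), numeric(1))
  expect_true(all(diff(widths_c) > 0))
  # near-zero confidence collapses onto r
  expect_equal(unname(fisher_ci(0.3, 50, 1e-12)), c(0.3, 0.3),
               tolerance = 1e-6)
  expect_warning(ci1 <- fisher_ci(1, 10), "degenerate")
  expect_identical(unname(ci1), c(1, 1))
  expect_error(fisher_ci(0.5, 3), "n >= 4")
})

test_that("the similarity comparison helper applies the CI criterion", {
  set.seed(69)
  base <- rnorm(40)
  prof <- rbind(a = base + rnorm(40, sd = 0.1),
                b = base + rnorm(40, sd = 0.1),
                c = rnorm(40))
  s <- population_similarity(prof)
  expect_true(significantly_more_similar(s, "a", "b", "c"))
  expect_false(significantly_more_similar(s, "a", "c", "b"))
})

test_that("bootstrap correlation sd: exact, deterministic, calibrated", {
  x <- rnorm(50)
  res <- bootstrap_corr_std(x, 2 * x + 1, n_boot = 50, seed = 1)
  expect_lt(res$sd, 1e-14)  # every resample has r = 1
  set.seed(70)
  a <- rnorm(60); b <- a + rnorm(60)
  r1 <- bootstrap_corr_std(a, b, n_boot = 200, seed = 2)
  r2 <- bootstrap_corr_std(a, b, n_boot = 200, seed = 2)
  expect_identical(r1$sd, r2$sd)
  ref <- bootstrap_corr_std(a, b, n_boot = 100000, seed = 3)
  mc_err <- ref$sd / sqrt(2 * 200)
  expect_lt(abs(r1$sd - ref$sd), 3 * mc_err)
})
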