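# shared fixture builders; everything is generated in code

random_counts <- function(n_genes, n_cells, seed, lambda = 1.5,
                          gene_prefix = "g", cell_prefix = "c") {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  dimnames(m) <- list(paste0(gene_prefix, seq_len(n_genes)),
                      paste0(cell_prefix, seq_len(n_cells)))
  count_matrix(m)
}

random_markers <- function(n_cells, seed, markers = c("CD3", "CD8")) {
  set.seed(seed)
  m <- matrix(runif(n_cells * length(markers), 0, 100), n_cells,
              length(markers))
  dimnames(m) <- list(paste0("c", seq_len(n_cells)), markers)
  marker_table(m)
}

# small truth for fast pipeline tests
small_truth <- function(...) {
  synthetic_truth(n_marker_genes = 5L, ...)
}

two_gate_set_cd <- function() {
  gate_set(list(hi = list(CD3 = c(0.5, 1), CD8 = c(0.5, 1)),
                lo = list(CD3 = c(0, 0.5), CD8 = c(0, 0.5))))
}

expect_same_expr <- function(a, b, tol = 1e-12) {
  expect_equal(a$cell_ids, b$cell_ids)
  expect_equal(a$target_names, b$target_names)
  expect_lt(max(abs(a$values - b$values)), tol)
}
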