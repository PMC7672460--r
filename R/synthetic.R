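#' Ground-truth parameters for the synthetic paired-modality generator
#'
#' Describes a two-marker system with three populations laid out like the
#' myeloid-progenitor geometry: two well-separated extreme populations and
#' one intermediate population occupying a narrower band of marker space
#' (which is what makes the intermediate population intrinsically harder
#' to resolve). Each population carries planted marker genes; additional
#' marker-coding genes depend monotonically on the marker coordinates.
#' Brightfield-like images encode the first marker as cell (disk) radius
#' and the second as interior speckle (granularity) density.
#'
#' @param centers 3x2 matrix of population centers in \[0, 1\]^2 marker
#'   space (rows named by population).
#' @param spreads per-population Gaussian marker jitter (sd).
#' @param weights mixture weights.
#' @param n_marker_genes planted marker genes per population.
#' @param effect_size log-scale expression boost of a planted gene in its
#'   own population.
#' @param n_coding_per_marker genes whose log-mean increases linearly with
#'   each marker value.
#' @param link_slope log-scale slope of those marker-coding genes.
#' @param base_logmean_range range of baseline log means for all genes.
#' @param nb_size negative-binomial size (inverse dispersion) of counts.
#' @param radius_base,radius_gain disk radius in pixels:
#'   `radius_base + radius_gain * marker1` (validated against the 32-pixel
#'   frame).
#' @param speckle_max maximal interior speckle probability (scaled by
#'   marker2).
#' @param background_level,foreground_level,speckle_level,background_sd
#'   16-bit image intensities and background noise sd.
#' @return a list of class `ifc_truth`.
#' @export
synthetic_truth <- function(
    centers = rbind(lineage1 = c(0.22, 0.25), lineage2 = c(0.80, 0.78),
                    progenitor = c(0.52, 0.50)),
    spreads = c(lineage1 = 0.09, lineage2 = 0.09, progenitor = 0.05),
    weights = c(lineage1 = 0.40, lineage2 = 0.35, progenitor = 0.25),
    n_marker_genes = 10L, effect_size = 2.5,
    n_coding_per_marker = 2L, link_slope = 2.5,
    base_logmean_range = c(-1.5, 0.5), nb_size = 2,
    radius_base = 4, radius_gain = 8, speckle_max = 0.5,
    background_level = 6000, foreground_level = 28000,
    speckle_level = 58000, background_sd = 900) {
  stopifnot(nrow(centers) == length(spreads),
            nrow(centers) == length(weights),
            all(centers >= 0 & centers <= 1), all(spreads >= 0),
            all(weights > 0), effect_size >= 0, nb_size > 0,
            background_sd >= 0)
  if (radius_base + radius_gain > 15)
    stop("synthetic_truth: maximal disk radius ", radius_base + radius_gain,
         " exceeds the 32-pixel frame")
  structure(list(centers = centers, spreads = spreads,
                 weights = weights / sum(weights),
                 populations = rownames(centers),
                 marker_names = c("markerA", "markerB"),
                 n_marker_genes = as.integer(n_marker_genes),
                 effect_size = effect_size,
                 n_coding_per_marker = as.integer(n_coding_per_marker),
                 link_slope = link_slope,
                 base_logmean_range = base_logmean_range,
                 nb_size = nb_size, radius_base = radius_base,
                 radius_gain = radius_gain, speckle_max = speckle_max,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 speckle_level = speckle_level,
                 background_sd = background_sd),
            class = "ifc_truth")
}

#' Default rectangular gates for the synthetic population layout
#'
#' Boxes of half-width `2 * spread` around each population center, clipped
#' to \[0, 1\]; the narrow intermediate population takes precedence where
#' boxes overlap.
#'
#' @param truth an [synthetic_truth()].
#' @return an [gate_set()].
#' @export
truth_gates <- function(truth) {
  stopifnot(inherits(truth, "ifc_truth"))
  g <- lapply(truth$populations, function(p) {
    ctr <- truth$centers[p, ]
    hw <- 2 * truth$spreads[p]
    list(markerA = c(max(0, ctr[1] - hw), min(1, ctr[1] + hw)),
         markerB = c(max(0, ctr[2] - hw), min(1, ctr[2] + hw)))
  })
  names(g) <- truth$populations
  ord <- truth$populations[order(truth$spreads)]  # narrow gates first
  gate_set(g, precedence = ord)
}

# draw population assignments and jittered marker coordinates
draw_cells <- function(truth, n_cells) {
  pop <- sample(truth$populations, n_cells, replace = TRUE,
                prob = truth$weights)
  mk <- truth$centers[pop, , drop = FALSE] +
    matrix(rnorm(2 * n_cells, sd = rep(truth$spreads[pop], 2)),
           ncol = 2)
  mk <- pmin(pmax(mk, 0), 1)
  colnames(mk) <- truth$marker_names
  list(pop = pop, markers = mk)
}

# deterministic (seed-stable) gene model shared by documentation and tests:
# gene 1..n_mk*P are planted population markers, the next blocks are
# marker-coding genes, the rest are background
gene_model <- function(truth, n_genes) {
  P <- length(truth$populations)
  n_planted <- truth$n_marker_genes * P
  n_coding <- truth$n_coding_per_marker * 2
  if (n_genes < n_planted + n_coding)
    stop("need at least ", n_planted + n_coding, " genes")
  base <- runif(n_genes, truth$base_logmean_range[1],
                truth$base_logmean_range[2])
  planted_pop <- rep(truth$populations, each = truth$n_marker_genes)
  coding_marker <- rep(1:2, each = truth$n_coding_per_marker)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  gene_ids[seq_len(n_planted)] <-
    paste0("mk_", planted_pop, "_", sequence(rep(truth$n_marker_genes, P)))
  gene_ids[n_planted + seq_len(n_coding)] <-
    paste0("link_", truth$marker_names[coding_marker], "_",
           sequence(rep(truth$n_coding_per_marker, 2)))
  list(base = base, gene_ids = gene_ids, planted_pop = planted_pop,
       n_planted = n_planted, coding_marker = coding_marker,
       n_coding = n_coding)
}

#' Generate a synthetic SCT experiment with known ground truth
#'
#' Cells are drawn from the population mixture; their marker coordinates
#' are the population center plus Gaussian jitter clipped to \[0, 1\];
#' counts are negative binomial with log-mean = baseline + population
#' effect (planted marker genes) + linear marker link (marker-coding
#' genes). Deterministic under `seed`.
#'
#' @param truth an [synthetic_truth()].
#' @param n_cells,n_genes dataset size.
#' @param seed integer seed.
#' @return list with `counts` ([count_matrix()]), `markers` (raw
#'   [marker_table()]), `labels` (true population per cell), `gene_info`
#'   (data frame: gene, role).
#' @export
generate_sct <- function(truth, n_cells = 2000L, n_genes = 120L,
                         seed = 1L) {
  stopifnot(inherits(truth, "ifc_truth"))
  if (n_cells < length(truth$populations))
    stop("generate_sct: fewer cells than populations")
  with_seed(seed, {
    cs <- draw_cells(truth, n_cells)
    gm <- gene_model(truth, n_genes)
    logmu <- matrix(rep(gm$base, n_cells), nrow = n_genes)  # genes x cells
    for (g in seq_len(gm$n_planted)) {
      boost <- as.numeric(cs$pop == gm$planted_pop[g]) * truth$effect_size
      logmu[g, ] <- logmu[g, ] + boost
    }
    for (k in seq_len(gm$n_coding)) {
      g <- gm$n_planted + k
      logmu[g, ] <- logmu[g, ] +
        truth$link_slope * cs$markers[, gm$coding_marker[k]]
    }
    counts <- matrix(rnbinom(n_genes * n_cells, mu = exp(logmu),
                             size = truth$nb_size), nrow = n_genes)
    cell_ids <- sprintf("sct%05d", seq_len(n_cells))
    dimnames(counts) <- list(gm$gene_ids, cell_ids)
    role <- rep("background", n_genes)
    role[seq_len(gm$n_planted)] <- paste0("marker:", gm$planted_pop)
    role[gm$n_planted + seq_len(gm$n_coding)] <-
      paste0("link:", truth$marker_names[gm$coding_marker])
    list(counts = count_matrix(counts),
         markers = marker_table(cs$markers, cell_ids = cell_ids),
         labels = structure(list(labels = cs$pop, cell_ids = cell_ids),
                            class = "ifc_labels"),
         gene_info = data.frame(gene = gm$gene_ids, role = role,
                                row.names = NULL))
  })
}

# render one 32x32 16-bit brightfield-like frame: disk radius encodes
# marker1, interior speckle density encodes marker2
render_cell_image <- function(truth, m1, m2) {
  r <- truth$radius_base + truth$radius_gain * m1
  ctr <- 16.5
  xy <- expand.grid(y = 1:32, x = 1:32)
  inside <- (xy$x - ctr)^2 + (xy$y - ctr)^2 <= r^2
  img <- rnorm(1024, truth$background_level, truth$background_sd)
  img[inside] <- truth$foreground_level +
    rnorm(sum(inside), 0, truth$background_sd)
  speckle <- inside & (runif(1024) < truth$speckle_max * m2)
  img[speckle] <- truth$speckle_level
  matrix(as.integer(pmin(pmax(round(img), 0), 65535)), 32, 32)
}

#' Generate a synthetic IFC experiment (markers and brightfield images)
#'
#' Marker coordinates are drawn exactly as in [generate_sct()]; when
#' `with_images = TRUE` each cell also gets a 32x32 16-bit image whose
#' disk radius grows with the first marker and whose interior speckle
#' density grows with the second, so morphology encodes both markers.
#'
#' @param truth an [synthetic_truth()].
#' @param n_cells number of IFC cells.
#' @param seed integer seed.
#' @param with_images render the image stack.
#' @return list with `markers` (raw [marker_table()]), `images`
#'   ([image_stack()] or `NULL`), `labels` (true population per cell).
#' @export
generate_ifc <- function(truth, n_cells = 1000L, seed = 2L,
                         with_images = TRUE) {
  stopifnot(inherits(truth, "ifc_truth"))
  if (n_cells < length(truth$populations))
    stop("generate_ifc: fewer cells than populations")
  with_seed(seed, {
    cs <- draw_cells(truth, n_cells)
    cell_ids <- sprintf("ifc%05d", seq_len(n_cells))
    images <- NULL
    if (with_images) {
      px <- array(0L, c(n_cells, 32, 32))
      for (i in seq_len(n_cells))
        px[i, , ] <- render_cell_image(truth, cs$markers[i, 1],
                                       cs$markers[i, 2])
      images <- image_stack(px, cell_ids)
    }
    list(markers = marker_table(cs$markers, cell_ids = cell_ids),
         images = images,
         labels = structure(list(labels = cs$pop, cell_ids = cell_ids),
                            class = "ifc_labels"))
  })
}
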