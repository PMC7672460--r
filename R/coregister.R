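#' Min-max normalize each marker within its modality
#'
#' Co-registration step: every marker column is independently mapped to
#' \[0, 1\] via `(x - min) / (max - min)`, within each modality separately,
#' so SCT and IFC marker values become comparable. The fitted bounds are
#' stored on the result for inversion and for the run manifest.
#'
#' @param markers an [marker_table()] (raw).
#' @return the normalized [marker_table()] (`normalized = TRUE`, bounds
#'   recorded).
#' @export
normalize_markers <- function(markers) {
  stopifnot(inherits(markers, "ifc_markers"))
  lo <- apply(markers$values, 2, min)
  hi <- apply(markers$values, 2, max)
  if (any(hi == lo))
    stop("constant marker column cannot be normalized: ",
         markers$marker_names[which(hi == lo)[1]])
  out <- sweep(sweep(markers$values, 2, lo, "-"), 2, hi - lo, "/")
  marker_table(out, normalized = TRUE,
               bounds = list(min = setNames(lo, markers$marker_names),
                             max = setNames(hi, markers$marker_names)))
}

#' Define rectangular population gates in normalized marker space
#'
#' Each gate is an axis-aligned rectangle over two (normalized) markers.
#' Intervals are half-open `[lo, hi)`, except that an upper bound of 1 is
#' closed so the top edge of marker space is gateable. When gates overlap,
#' the first matching gate in `precedence` wins.
#'
#' @param gates named list; each element is a named list of
#'   `marker = c(lo, hi)` ranges, e.g.
#'   `list(cytotoxic = list(CD3 = c(.5, 1), CD8 = c(.5, 1)))`.
#' @param precedence evaluation order; must cover all gate names. Defaults
#'   to the order of `gates`.
#' @return an object of class `ifc_gates`.
#' @export
gate_set <- function(gates, precedence = names(gates)) {
  if (is.null(names(gates)) || any(names(gates) == ""))
    stop("gate_set: every gate needs a population name")
  if (!setequal(precedence, names(gates)) ||
      length(precedence) != length(gates))
    stop("gate_set: precedence must list every gate name exactly once")
  for (g in names(gates)) {
    for (m in names(gates[[g]])) {
      r <- gates[[g]][[m]]
      if (length(r) != 2 || r[1] > r[2])
        stop("gate_set: bad range for marker ", m, " in gate ", g)
      if (r[1] < 0 || r[2] > 1)
        stop("gate_set: gate ", g, " bounds must lie in [0, 1] ",
             "(gates are defined on normalized markers)")
    }
  }
  structure(list(gates = gates, precedence = precedence),
            class = "ifc_gates")
}

#' @export
print.ifc_gates <- function(x, ...) {
  cat("<ifc_gates> ", paste(x$precedence, collapse = " > "),
      " (ungated -> \"other\")\n", sep = "")
  invisible(x)
}

#' Assign cells to populations with rectangular gates
#'
#' Cells falling in no gate receive the reserved label `"other"`.
#'
#' @param markers a normalized [marker_table()].
#' @param gates an [gate_set()].
#' @return an object of class `ifc_labels` with fields `labels` (one per
#'   cell) and `cell_ids`.
#' @export
apply_gates <- function(markers, gates) {
  stopifnot(inherits(markers, "ifc_markers"), inherits(gates, "ifc_gates"))
  if (!markers$normalized)
    stop("apply_gates: markers must be normalized first")
  used <- unique(unlist(lapply(gates$gates, names)))
  miss <- setdiff(used, markers$marker_names)
  if (length(miss))
    stop("apply_gates: gate markers not in table: ",
         paste(miss, collapse = ", "))
  n <- nrow(markers$values)
  labels <- rep("other", n)
  unassigned <- rep(TRUE, n)
  for (g in gates$precedence) {
    inside <- rep(TRUE, n)
    for (m in names(gates$gates[[g]])) {
      r <- gates$gates[[g]][[m]]
      v <- markers$values[, m]
      hi_ok <- if (r[2] >= 1) v <= r[2] else v < r[2]
      inside <- inside & v >= r[1] & hi_ok
    }
    take <- inside & unassigned
    labels[take] <- g
    unassigned <- unassigned & !take
  }
  structure(list(labels = labels, cell_ids = markers$cell_ids),
            class = "ifc_labels")
}

#' @export
print.ifc_labels <- function(x, ...) {
  tb <- table(x$labels)
  cat("<ifc_labels> ", paste(names(tb), tb, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
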