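# PE x SER threshold grid, cohort AUC surface, and optimal-pair selection.

#' The predefined PE x SER threshold grid
#'
#' PE thresholds run from 0% to 220% in 5% increments (45 values) and SER
#' thresholds from 0 to 2 in 0.05 increments (41 values): 1845 pairs. SER
#' values are stored as integer hundredths internally so every grid value is
#' represented exactly at two decimal places.
#'
#' @return object of class `threshold_grid` with fields `pe` (percent),
#'   `ser` (dimensionless), `ser_hundredths` (integer).
#' @export
build_grid <- function() {
  ser_h <- seq(0L, 200L, by = 5L)
  structure(
    list(pe = as.numeric(seq(0L, 220L, by = 5L)),
         ser_hundredths = ser_h,
         ser = ser_h / 100),
    class = "threshold_grid")
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf("<threshold_grid> %d PE x %d SER = %d pairs (PE %g..%g%%, SER %g..%g)\n",
              length(x$pe), length(x$ser), length(x$pe) * length(x$ser),
              min(x$pe), max(x$pe), min(x$ser), max(x$ser)))
  invisible(x)
}

#' Percent-change grid between a baseline and a later FTV grid
#'
#' Applies [relative_change()] cellwise: cells where the baseline FTV is not
#' strictly positive become `NA` (that patient is dropped from those cells'
#' AUC with a logged count in [auc_surface()]).
#'
#' @param bl_grid,later_grid FTV matrices from [ftv_grid()] on the same
#'   threshold grid.
#' @return matrix of percent changes, `NA` where undefined.
#' @export
change_grid <- function(bl_grid, later_grid) {
  stopifnot(identical(dim(bl_grid), dim(later_grid)))
  out <- matrix(relative_change(as.numeric(bl_grid), as.numeric(later_grid)),
                nrow = nrow(bl_grid), dimnames = dimnames(bl_grid))
  out
}

#' Cohort AUC surface over the threshold grid
#'
#' For every threshold pair, the AUC of the per-patient values (FTV, or
#' percent change in FTV) at that pair for discriminating the two outcome
#' classes. Patients with an undefined value at a pair (zero-baseline
#' percent changes) are dropped from that cell only; cells left with a
#' single class get `NA`. Cells where every patient's value is identical
#' (e.g. all-zero FTV above every voxel) evaluate to 0.5 by the tie
#' convention of the AUC estimator.
#'
#' @param grids list of per-patient matrices (all the same dimensions, from
#'   [ftv_grid()] or [change_grid()]).
#' @param labels 0/1 outcome per patient (1 = positive class), aligned with
#'   `grids`.
#' @param positive_high orientation flag passed to [auc_from_scores()].
#' @param kind label describing the measurement (e.g. `"FTV_1min_C4"`).
#' @return object of class `auc_surface`: `auc` matrix, `kind`,
#'   `optimal_pe`, `optimal_ser`, `max_auc`, `ties` (data frame of all pairs
#'   at the maximum), `n_pos`, `n_neg`, `n_dropped` matrix.
#' @export
auc_surface <- function(grids, labels, positive_high = TRUE, kind = "FTV") {
  stopifnot(length(grids) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("single-class cohort: both pCR and non-pCR patients are required")
  dims <- dim(grids[[1]])
  for (g in grids) stopifnot(identical(dim(g), dims))
  x <- vapply(grids, as.numeric, numeric(prod(dims)))  # cells x patients
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  auc_flat <- apply(x, 1, function(v) {
    ok <- !is.na(v)
    lab <- labels[ok]
    if (length(unique(lab)) < 2L) return(NA_real_)
    auc_from_scores(v[ok], lab, positive_high = positive_high)
  })
  auc <- matrix(auc_flat, nrow = dims[1], dimnames = dimnames(grids[[1]]))
  n_dropped <- matrix(apply(x, 1, function(v) sum(is.na(v))),
                      nrow = dims[1], dimnames = dimnames(grids[[1]]))
  surf <- structure(
    list(auc = auc, kind = kind, n_pos = sum(labels == 1L),
         n_neg = sum(labels == 0L), n_dropped = n_dropped),
    class = "auc_surface")
  opt <- select_optimal(surf)
  surf$optimal_pe <- opt$pe
  surf$optimal_ser <- opt$ser
  surf$max_auc <- opt$auc
  surf$ties <- opt$ties
  surf
}

#' Select the AUC-maximal threshold pair
#'
#' Returns the (PE, SER) pair with maximal AUC. When several pairs tie at
#' the maximum, the pair with the minimum PE and SER is chosen; if the tied
#' set has no componentwise minimum, ties are broken lexicographically (PE
#' first, then SER), which coincides with the componentwise rule whenever
#' one exists. The full tie set is returned for logging.
#'
#' @param surface an [auc_surface()] (or a bare AUC matrix with threshold
#'   dimnames).
#' @return list with `pe`, `ser`, `auc`, and `ties` (data frame of all
#'   maximal pairs).
#' @export
select_optimal <- function(surface) {
  auc <- if (inherits(surface, "auc_surface")) surface$auc else surface
  if (all(is.na(auc))) stop("AUC surface contains no defined cells")
  pe_vals <- as.numeric(rownames(auc))
  ser_vals <- as.numeric(colnames(auc))
  mx <- max(auc, na.rm = TRUE)
  idx <- which(auc == mx, arr.ind = TRUE)
  ties <- data.frame(pe = pe_vals[idx[, 1]], ser = ser_vals[idx[, 2]],
                     auc = mx)
  ties <- ties[order(ties$pe, ties$ser), , drop = FALSE]
  list(pe = ties$pe[1], ser = ties$ser[1], auc = mx, ties = ties)
}

#' @export
print.auc_surface <- function(x, ...) {
  cat(sprintf(
    "<auc_surface> %s: max AUC %.3f at PE %g%%, SER %.2f (%d pos / %d neg%s)\n",
    x$kind, x$max_auc, x$optimal_pe, x$optimal_ser, x$n_pos, x$n_neg,
    if (nrow(x$ties) > 1) sprintf("; %d tied pairs", nrow(x$ties)) else ""))
  invisible(x)
}

#' Long-format export of an AUC surface
#'
#' @param surface an [auc_surface()].
#' @return data frame with columns `pe`, `ser`, `auc`, `n_dropped` (one row
#'   per threshold pair), suitable for CSV export and contour plotting.
#' @export
surface_to_long <- function(surface) {
  stopifnot(inherits(surface, "auc_surface"))
  pe_vals <- as.numeric(rownames(surface$auc))
  ser_vals <- as.numeric(colnames(surface$auc))
  data.frame(
    kind = surface$kind,
    pe = rep(pe_vals, times = length(ser_vals)),
    ser = rep(ser_vals, each = length(pe_vals)),
    auc = as.numeric(surface$auc),
    n_dropped = as.integer(surface$n_dropped))
}

#' Filled-contour plot of an AUC surface
#'
#' Thin base-graphics rendering of the AUC as a function of the PE and SER
#' thresholds, with the selected optimal pair marked.
#'
#' @param x an [auc_surface()].
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.auc_surface <- function(x, ...) {
  pe_vals <- as.numeric(rownames(x$auc))
  ser_vals <- as.numeric(colnames(x$auc))
  graphics::filled.contour(
    pe_vals, ser_vals, x$auc,
    xlab = "PE threshold (%)", ylab = "SER threshold",
    main = sprintf("%s: max AUC %.2f at (%g, %.2f)",
                   x$kind, x$max_auc, x$optimal_pe, x$optimal_ser),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::points(x$optimal_pe, x$optimal_ser, pch = 21, bg = "black")
    }, ...)
  invisible(x)
}
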